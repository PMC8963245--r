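---
title: "Dual-boost accelerated sampling and energetic reweighting at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-boost accelerated sampling and energetic reweighting at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pepgamd)
```

## The model

Gaussian accelerated molecular dynamics adds a harmonic boost to the
potential energy whenever it falls below a threshold:

$$\Delta V(r) = \tfrac{1}{2} k\,(E - V(r))^2 \quad \text{for } V(r) < E,
\qquad \Delta V = 0 \text{ otherwise.}$$

Two requirements pin down the free parameters. Order preservation and
smoothing — for $V_1 < V_2 < E$ the boosted values keep their order and
move closer together — bracket the threshold as
$V_{max} \le E \le V_{min} + 1/k$ and give $k = k_0/(V_{max}-V_{min})$
with $0 < k_0 \le 1$. A narrow boost distribution,
$\sigma_{\Delta V} = k\,(E - V_{avg})\,\sigma_V \le \sigma_0$, then fixes
$k_0$ for either threshold bound (`k0_lower_bound()`,
`k0_upper_bound()`; the upper-bound form falls back to the lower-bound
form outside $(0,1]$ and reports which branch fired).

Two points deserve emphasis because they shape the tests:

* The order/smoothing guarantees are statements about the force scale
  $1 - k(E-V)$, which lies in $[0,1]$ exactly for
  $V \in [V_{min}, E]$ — the bracket over which the statistics were
  collected. Production frames are integrated with *frozen* parameters
  (that is what keeps reweighting valid), so a production frame below
  the recorded $V_{min}$ can, at $k_0 = 1$, damp the force through zero.
  The package counts such frames (`$counters`) rather than refreshing
  parameters, and the invariant checks assert the criteria on the
  bracket where the theory states them.
* The boost SD constraint is exact on the collected statistics by
  construction; on production frames it holds empirically and the suite
  allows a 1.2× slack.

For peptide binding the boost is split: one boost on the essential
peptide energy
$V_L = V_{LL,b} + V_{LL,nb} + V_{PL,nb} + V_{LE,nb}$
(peptide bonded, peptide–peptide, peptide–receptor and
peptide–environment nonbonded terms) and a second on everything else
($V_D$), each with its own running statistics. The staged protocol is
conventional MD (statistics only), equilibration (boost applied,
statistics refreshed every `update_interval` steps, default 50), then
`n_replicas` independent production runs (default 3) with frozen
parameters.

## Reweighting

The canonical probability in reaction-coordinate bin $j$ is recovered
from the biased histogram via the ensemble-averaged Boltzmann factor of
the boost, approximated by cumulant expansion to second order:

$$F(A_j) = F^*(A_j) - C_{1,j} - \tfrac{\beta}{2} C_{2,j} + F_c,$$

with $C_1$ the per-bin mean of $\Delta V$ and $C_2$ its population
variance. The cumulant sum enters as an energy (each term divided by
$\beta$), which is the form implied by
$p \propto p^* \exp(\beta C_1 + \beta^2 C_2/2)$. Cumulants are computed
*per bin*, never globally; truncation at second order is exact when the
boost is Gaussian, and no higher-order or exponential-average variants
are provided. The anchoring constant $F_c$ is chosen so the minimum over
included bins is zero. Bins with fewer than `cutoff_frames` frames
(default 500) are excluded outright — written as `NA`, never
interpolated — and structural clusters are treated as bins under the
same rule, with the same cutoff. Default bin width is 1 coordinate unit,
interpreted as square 1×1 bins in 2D. Replicas are pooled before binning
by default (`production_frames()`); a per-replica mode supports
comparing individual simulations.

How Gaussian is the boost in practice? `anharmonicity()` measures the
entropy deficit $\gamma = \ln\sqrt{2\pi e \sigma^2} - H(\Delta V)$, zero
iff exactly Gaussian (histogram entropy with Scott's-rule bins,
$3.49\,\sigma n^{-1/3}$). Near-Gaussianity of $\Delta V$ is a
many-degree-of-freedom property: on the bead peptide system the
dual-boost total measures $\gamma \approx 0.02$–$0.05$, while on the 1–2
dimensional analytic surfaces the boost is necessarily skewed
($\gamma \approx 0.3$–$1$) because the potential-energy distribution
itself has too few degrees of freedom to be Gaussian. Per-bin cumulants
carry the load in that regime: the surface profiles still agree with the
exact quadrature answer to well under 0.5 kT, which the suite verifies
directly rather than through the Gaussianity proxy.

## Toy systems and oracles

Reduced units are used throughout: $k_B T = 1$ at temperature 1, bead
mass 1, bond rest length 1. An inverse temperature or a kT-valued
`temperature` can be supplied everywhere (`beta` arguments), so columnar
files produced in physical units can be analysed by setting
$\beta = 1/k_B T$ accordingly; the reweighting temperature is always
explicit, never assumed.

* `make_double_well(h, s)` — quartic 1D well, minima at $\pm s/2$,
  barrier exactly $h$: the benchmark for barrier-crossing enhancement
  and reweighting accuracy.
* `make_three_state_landscape()` — inverted Gaussians plus a confining
  quadratic wall; the shipped example plants basins at 8.6, 11.1 and
  15.3 along the first coordinate, echoing the inactive / intermediate /
  active wells of a GPCR activation coordinate. Those positions are
  labels of convenience for a synthetic landscape, not physical claims.
* `make_toy_peptide_system()` — a harmonic bead chain near a fixed
  3-bead receptor pocket, one Gaussian binding well (default depth 6 kT
  at contact distance 1) on the anchor bead, finite soft-core repulsion
  elsewhere, mobile environment beads and a spherical wall. The
  nonbonded form is finite at contact by design — a soft-core bump
  plus Gaussian well rather than a hard Lennard-Jones — so the Langevin
  integrator stays stable at dt = 0.01 with the stiffest bond
  ($k_b = 100$, $\omega\,dt = 0.1$). Receptor beads are fixed,
  mirroring the focus on peptide flexibility. The total energy
  decomposes exactly into the four essential-peptide terms plus the
  remainder; environment–environment, environment–receptor and all wall
  terms belong to $V_D$.

Ground truth comes from `analytic_pmf()`: dense quadrature of
$e^{-\beta V}$ with the $\delta$-function realised as histogram binning
on the *same* grid convention as `reweight_profile()`, so oracle and
estimate share the binning bias. The quadrature uses a bin-aligned
midpoint rule — every histogram bin is tiled by the same number of
quadrature cells — which makes symmetric surfaces produce exactly
symmetric profiles and keeps the closed-form harmonic check at its
stated tolerance.

`synth_weighted_samples()` closes the loop from the other side: it draws
coordinate/boost pairs *constructed* so that reweighting must reproduce
a stated target PMF. A coordinate-independent boost (constant or
Gaussian) leaves the coordinate density untouched and its factor cancels
in the normalisation; a state-dependent boost mean $m(x)$ is compensated
by sampling from
$p^*(x) \propto e^{-\beta F(x)} e^{-\beta m(x) - \beta^2 s^2/2}$,
exactly what the reweighting inverts. Gaussian draws are clamped at zero
to honour boost non-negativity; for coordinate-independent boosts the
clamp shifts every bin equally and still cancels.

What the generator and toy systems emulate: near-Gaussian boost
distributions (bead system), multi-well landscapes with 2–3 planted
minima, repetitive binding and unbinding. What they do not: explicit
solvent and electrostatics, membrane environments, conformational
entropy of real side chains, or the system-size scaling of boost
statistics. A passing suite therefore demonstrates correctness of the
method's machinery against exact references, not force-field realism.

## Numerical choices

* **Integrator** — Langevin BAOAB splitting, fixed time step,
  friction > 0 required (pure NVE is rejected). BAOAB gives the best
  configurational accuracy per step at this scale; the equipartition
  check on a harmonic well passes at the 5% level.
* **Randomness** — a self-contained mt19937_64 plus polar Box–Muller
  stream keyed by (seed, stream); every stage, equilibration chunk and
  production replica has its own stream, so full runs are bit-identical
  for a seed and replicas are independently reproducible.
* **Statistics** — population SD via Welford/Chan moment combination,
  order-invariant to 1e-10; $k_0$ stays undefined until at least two
  spread-out samples exist (the boost is simply off until then). The
  cMD stage's samples seed the statistics by default
  (`include_cmd_in_stats = FALSE` to disable).
* **Binning** — bin index $\lfloor a/w \rfloor$, so edges sit at
  multiples of the width; a value exactly on a state-band edge belongs
  to the upper band (closed-open intervals).
* **Minima** — local minima over included bins (4-neighbourhood in 2D),
  excluded bins do not constrain, plateau ties resolve to the
  lowest-index bin center, and reported minima lie within
  `depth_threshold` (default 3 kT) of the global minimum.
* **Clustering** — dense pairwise superposition-RMSD (Kabsch via SVD,
  unweighted coordinates), average-linkage agglomeration, clusters
  relabelled by descending population, medoid representatives with
  lowest-index tie-breaks. Dense $O(n^2)$ matrices are acceptable at
  the intended $\le 10^4$ strided frames; `stride` is exposed.
* **Overflow** — reweighting factors are handled in log space end to
  end; the integrator aborts with the offending step number if |V|
  exceeds a guard value.

## Defaults and where they come from

| Parameter | Default | Meaning |
|---|---|---|
| `bin_width` | 1.0 coordinate units | profile bin size (1×1 in 2D) |
| `cutoff_frames` | 500 | occupancy cutoff per bin or cluster |
| `n_clusters` | 10 | top-ranked representative conformations |
| `n_replicas` | 3 | independent production runs |
| `update_interval` | 50 steps | statistics refresh cadence |
| `sigma_0` | 10 kT | boost-SD upper limit, per boosted term |
| `bound_mode` | `"lower"` | threshold at $E = V_{max}$ |
| `depth_threshold` | 3 kT | minima reporting window |
| state bands | [0,10), [10,13), [13,∞) | inactive / intermediate / active |
| salt-bridge cutoff | 5 length units | formed vs broken flag |

The state bands separate the planted basin positions (and the
activation-coordinate wells they echo) and are fully configurable —
classification logic never hard-codes them. The salt-bridge flag is a
convenience only. $\sigma_0$ is exposed per boosted term rather than
hard-coded since the appropriate value is system-dependent; the shipped
examples use 4–6 kT, where the adaptive $k_0$ caps at 1.

## Problem sizes

The test suite and the acceptance script run: double-well GaMD with
$2\times10^6$ production steps (PMF error vs quadrature ≈ 0.05–0.1 kT,
asserted < 0.5 kT); three-state runs with 3 × 7×10⁵ steps pooled
(three minima recovered in the correct bins, ΔF error < 0.5 kT); ten
cMD/Pep-GaMD seed pairs at 6×10⁴ matched production steps each
(transition counts enhanced ~3×, Pep-GaMD ≥ cMD in ≥ 9/10 pairs);
convergence monotonicity across 8×-spaced lengths. These sizes were
chosen as the smallest at which the stochastic assertions are stable,
and the whole suite completes in about a minute.

## Limitations

* The engines integrate only the built-in surface kinds and the bead
  model; `make_custom_surface()` closures feed the quadrature oracle,
  not the dynamics.
* No barostat, constraints, replica exchange, PME or GPU paths; no
  WHAM/MBAR or Maclaurin-series reweighting variants.
* Trajectory I/O is multi-frame XYZ plus TSV sidecars (with a 3-column
  legacy weights export); binary MD formats are out of scope.
* Which residue pairs to monitor is user input (`distance_spec`);
  nothing is auto-detected.
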