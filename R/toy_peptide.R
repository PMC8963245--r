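# Coarse bead model of a flexible peptide binding a rigid receptor pocket,
# with the total energy split exactly into the essential-peptide terms
#   V_L = V_LL,b + V_LL,nb + V_PL,nb + V_LE,nb
# and the remainder V_rest (= V_D): environment-environment and
# environment-receptor interactions plus the confining wall. Receptor
# beads are fixed (infinite-mass contract); the peptide anchor bead feels
# a Gaussian binding well at the central receptor bead, soft-core
# repulsion everywhere else, so bound and unbound configurations both
# occur and transitions between them are activated events.
#
# Reduced units throughout: k_B T = 1 at temperature 1, bead mass 1,
# bond rest length 1.

#' Build the toy peptide-receptor system
#'
#' A harmonic bead chain (the peptide) near a fixed 3-bead receptor with
#' one attractive anchor-pocket pairing (binding funnel, Gaussian well of
#' depth 6 kT at contact distance 1) and finite soft-core repulsion
#' elsewhere, plus mobile environment beads and a spherical confining
#' wall. Initial coordinates are a seeded self-avoiding-ish random coil in
#' the bound pose; construction is deterministic for a given seed.
#'
#' @param n_peptide_beads Number of peptide beads (2..10).
#' @param seed Integer seed for the initial configuration.
#' @param n_env_beads Mobile environment beads (default 4).
#' @param temperature Reduced temperature (kT; default 1).
#' @param binding_depth Depth of the anchor binding well (kT; default 6).
#' @param wall_radius Confining sphere radius (default 4).
#' @return A `toy_peptide_system`.
#' @export
make_toy_peptide_system <- function(n_peptide_beads, seed,
                                    n_env_beads = 4L, temperature = 1,
                                    binding_depth = 6, wall_radius = 4) {
  check_scalar(n_peptide_beads, "n_peptide_beads", integerish = TRUE)
  if (n_peptide_beads < 2 || n_peptide_beads > 10)
    stop_invalid("n_peptide_beads must be between 2 and 10")
  check_scalar(seed, "seed", integerish = TRUE)
  check_scalar(temperature, "temperature", positive = TRUE)
  np <- as.integer(n_peptide_beads)
  ne <- as.integer(n_env_beads)

  receptor <- rbind(c(0, 0, 0),        # pocket center (binding site)
                    c(1.5, 0, -0.4),   # flanking beads shape the pocket
                    c(-1.5, 0, -0.4))
  type <- c(rep(0L, np), rep(1L, 3L), rep(2L, ne)) # 0 L, 1 P, 2 E
  n <- length(type)

  # seeded deterministic initial configuration (restore caller RNG state)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  coords <- matrix(0, n, 3)
  coords[1, ] <- c(0, 0, 1)                     # anchor in the bound pose
  for (i in seq_len(np)[-1]) {                  # random coil, bond length 1
    step <- stats::rnorm(3)
    step[3] <- abs(step[3])                     # grow away from the pocket
    coords[i, ] <- coords[i - 1, ] + step / sqrt(sum(step^2))
  }
  coords[np + 1:3, ] <- receptor
  if (ne > 0) {
    for (i in seq_len(ne)) {                    # environment shell
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      coords[np + 3 + i, ] <- u * stats::runif(1, 2.2, wall_radius - 0.5)
    }
  }

  bonds <- if (np >= 2) cbind(seq_len(np - 1), seq_len(np - 1) + 1) else
    matrix(integer(), 0, 2)
  bond_k <- rep(100, nrow(bonds))
  bond_r0 <- rep(1, nrow(bonds))

  # nonbonded pair list: all pairs except bonded neighbours and
  # receptor-receptor (rigid)
  pairs <- t(utils::combn(n, 2))
  bonded <- paste(bonds[, 1], bonds[, 2])
  keep <- !(paste(pairs[, 1], pairs[, 2]) %in% bonded) &
    !(type[pairs[, 1]] == 1L & type[pairs[, 2]] == 1L)
  pairs <- pairs[keep, , drop = FALSE]
  ti <- type[pairs[, 1]]; tj <- type[pairs[, 2]]
  is_anchor_site <- (pairs[, 1] == 1L & pairs[, 2] == np + 1L)
  rep_A <- ifelse(ti + tj == 1L | is_anchor_site, 10, 2) # stiffer at pocket
  rep_rc <- ifelse(is_anchor_site, 0.6, 0.9)
  att_eps <- ifelse(is_anchor_site, binding_depth, 0)
  att_r0 <- rep(1, nrow(pairs))
  att_w <- rep(0.35, nrow(pairs))

  model <- list(type = type, bonds = pairs_as_int(bonds - 1L),
                bond_k = bond_k, bond_r0 = bond_r0,
                pair_i = as.integer(pairs[, 1] - 1L),
                pair_j = as.integer(pairs[, 2] - 1L),
                rep_A = rep_A, rep_rc = rep_rc, att_eps = att_eps,
                att_r0 = att_r0, att_w = att_w,
                wall_R = wall_radius, wall_k = 5)

  structure(list(coords = coords, type = type,
                 n_peptide = np, n_env = ne, n_beads = n,
                 masses = rep(1, n), temperature = temperature,
                 model = model, seed = as.integer(seed),
                 binding_depth = binding_depth,
                 anchor = 1L, site = np + 1L),
            class = "toy_peptide_system")
}

pairs_as_int <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  m
}

#' @export
print.toy_peptide_system <- function(x, ...) {
  cat(sprintf(paste0("Toy peptide-receptor system: %d peptide beads, ",
                     "3 fixed receptor beads, %d environment beads\n"),
              x$n_peptide, x$n_env))
  cat(sprintf("  kT = %g, binding-well depth = %g kT, wall radius = %g\n",
              x$temperature, x$binding_depth, x$model$wall_R))
  invisible(x)
}

#' Peptide / receptor / environment coordinate accessors
#'
#' @param system A `toy_peptide_system`.
#' @return Coordinate matrix of the corresponding bead class.
#' @export
peptide_coords <- function(system) system$coords[system$type == 0L, , drop = FALSE]

#' @rdname peptide_coords
#' @export
receptor_coords <- function(system) system$coords[system$type == 1L, , drop = FALSE]

#' @rdname peptide_coords
#' @export
environment_coords <- function(system) system$coords[system$type == 2L, , drop = FALSE]

#' Energy decomposition of the toy system
#'
#' Evaluates the five named energy components at the given (or stored)
#' coordinates. `v_peptide` is the essential peptide energy
#' `ll_b + ll_nb + pl_nb + le_nb`; `v_rest` is everything else;
#' `v_total` is their sum exactly.
#'
#' @param system A `toy_peptide_system`.
#' @param coords Optional coordinate matrix (defaults to the stored ones).
#' @return List with `components` (named length-5 vector), `v_peptide`,
#'   `v_rest`, `v_total`.
#' @export
toy_energy <- function(system, coords = NULL) {
  x <- coords %||% system$coords
  e <- cpp_bead_energy(system$model, as_coords(x, system$n_beads))
  comps <- e$components
  vl <- sum(comps[c("ll_b", "ll_nb", "pl_nb", "le_nb")])
  list(components = comps, v_peptide = vl, v_rest = comps[["rest"]],
       v_total = vl + comps[["rest"]])
}

as_coords <- function(x, n) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != n || ncol(x) != 3)
    stop_invalid("coords must be a ", n, " x 3 matrix")
  x
}

#' Anchor-site distance and binding transitions
#'
#' `binding_distance` extracts the anchor-bead-to-pocket distance per
#' frame; `count_transitions` counts bound/unbound interconversions with a
#' two-threshold hysteresis rule (a transition is registered only when the
#' distance fully crosses from below `bound_below` to above
#' `unbound_above` or back), so barrier-top recrossings are not counted.
#'
#' @param traj A trajectory from [run_cmd()] / [run_pep_gamd()] on a toy
#'   peptide system (or a frames array).
#' @param system The `toy_peptide_system`.
#' @return `binding_distance`: numeric vector of distances per frame.
#' @export
binding_distance <- function(traj, system) {
  fr <- trajectory_frames(traj)
  sqrt(rowSums((fr[, system$anchor, ] - fr[, system$site, ])^2))
}

#' @rdname binding_distance
#' @param d Distance series.
#' @param bound_below Distance below which the peptide counts as bound.
#' @param unbound_above Distance above which it counts as unbound.
#' @return `count_transitions`: integer number of state changes.
#' @export
count_transitions <- function(d, bound_below = 1.6, unbound_above = 2.8) {
  state <- if (d[1] < bound_below) 1L else 0L
  n <- 0L
  for (di in d) {
    if (state == 1L && di > unbound_above) { state <- 0L; n <- n + 1L }
    else if (state == 0L && di < bound_below) { state <- 1L; n <- n + 1L }
  }
  n
}
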