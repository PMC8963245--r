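# Deterministic desk-scale fixture bundle: one GaMD double-well run, one
# three-state-landscape run, one dual-boost toy-peptide run with three
# production replicas, and synthetic weighted-sample sets, each written
# alongside the oracle quantities the analysis should recover. Step
# counts are kept small (tens of thousands) so the bundle builds in
# seconds; convergence-grade runs are the caller's choice of protocol.

#' Generate the fixture bundle
#'
#' @param seed Master seed; the bundle is deterministic given it.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a manifest list with paths, oracle values and the
#'   in-memory run objects.
#' @export
make_fixtures <- function(seed, dir = tempfile("pepgamd_fixtures_")) {
  check_scalar(seed, "seed", integerish = TRUE)
  seed <- as.integer(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(...))

  # 1. double well, total boost
  dw <- make_double_well(barrier_height = 5, well_separation = 2)
  dw_protocol <- protocol_spec(2000L, 10000L, 20000L, n_replicas = 1L,
                               dt = 0.01, seed = seed)
  dw_run <- run_gamd(dw, dw_protocol, sigma_0 = 4)
  write_trajectory(dw_run$production[[1]], p("double_well_prod"))
  write_weights_legacy(dw_run$production[[1]], p("double_well_weights.tsv"))

  # 2. three-state activation landscape, total boost
  ts <- make_three_state_landscape(
    rbind(c(8.6, 8), c(11.1, 4), c(15.3, 5)),
    depths = c(6, 5, 5.5), widths = c(0.8, 0.8, 0.8))
  ts_protocol <- protocol_spec(2000L, 10000L, 20000L, n_replicas = 1L,
                               dt = 0.01, seed = seed + 1L)
  ts_run <- run_gamd(ts, ts_protocol, sigma_0 = 6)
  write_trajectory(ts_run$production[[1]], p("three_state_prod"))

  # 3. toy peptide, dual boost, three production replicas
  pep <- make_toy_peptide_system(3L, seed = seed)
  pep_protocol <- protocol_spec(2000L, 10000L, 10000L, n_replicas = 3L,
                                dt = 0.01, seed = seed + 2L,
                                record_stride = 5L)
  pep_run <- run_pep_gamd(pep, pep_protocol, sigma_0_L = 6, sigma_0_D = 6)
  for (r in seq_len(3L))
    write_trajectory(pep_run$production[[r]],
                     p("peptide_prod_rep", r), system = pep)

  # 4. synthetic weighted samples against a double-well target PMF
  target <- function(x) 2 * (x - 5)^2 * ((x - 5)^2 - 2) / 4 + 2
  synth_const <- synth_weighted_samples(target, boost_constant(3),
                                        n = 20000L, seed = seed + 3L,
                                        range = c(2, 8))
  synth_gauss <- synth_weighted_samples(target, boost_gaussian(6, 2),
                                        n = 20000L, seed = seed + 4L,
                                        range = c(2, 8))
  write_samples_tsv(synth_const, p("synth_constant.tsv"))
  write_samples_tsv(synth_gauss, p("synth_gaussian.tsv"))

  manifest <- list(
    dir = dir, seed = seed,
    paths = list(
      double_well = p("double_well_prod"),
      double_well_weights = p("double_well_weights.tsv"),
      three_state = p("three_state_prod"),
      peptide = vapply(1:3, function(r) p("peptide_prod_rep", r), ""),
      synth_constant = p("synth_constant.tsv"),
      synth_gaussian = p("synth_gaussian.tsv")),
    oracles = list(
      double_well_minima = as.vector(dw$minima),
      double_well_barrier = 5,
      three_state_minima = ts$minima),
    runs = list(double_well = dw_run, three_state = ts_run,
                peptide = pep_run),
    systems = list(double_well = dw, three_state = ts, peptide = pep))
  writeLines(jsonlite::toJSON(manifest[c("seed")], auto_unbox = TRUE),
             p("manifest.json"))
  invisible(manifest)
}
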