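# Staged simulation driver. Stage 1: conventional MD collecting potential
# statistics with no boost. Stage 2: equilibration applying the boost
# while refreshing the statistics (and hence E, k) every update_interval
# steps. Stage 3: n_replicas independent production runs with frozen
# parameters. The integrator is Langevin BAOAB with fixed time step; the
# compiled kernel is called in chunks so boost parameters are piecewise
# constant.

OVERFLOW_GUARD <- 1e8

#' Simulation protocol
#'
#' Step counts, integrator settings and seeding for the staged
#' cMD -> equilibration -> production protocol.
#'
#' @param n_cmd_steps,n_equil_steps,n_prod_steps Steps per stage (>= 0).
#' @param n_replicas Independent production runs (>= 1; default 3).
#' @param dt Time step. Must resolve the stiffest bond: for bond force
#'   constant kb and mass m, stability requires `dt << 2 / sqrt(kb / m)`
#'   (default 0.01 with kb = 100, m = 1, i.e. omega dt = 0.1).
#' @param friction Langevin friction (1/time, > 0; pure NVE unsupported).
#' @param temperature Reduced temperature kT (> 0).
#' @param seed Master seed; replica r uses a derived stream so replicas
#'   are independently reproducible.
#' @param update_interval Statistics refresh cadence during equilibration
#'   (steps; default 50).
#' @param record_stride Record every this-many steps (default 1).
#' @param include_cmd_in_stats Seed the boost statistics with the cMD
#'   stage's potential samples (default TRUE).
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(n_cmd_steps, n_equil_steps, n_prod_steps,
                          n_replicas = 3L, dt = 0.01, friction = 1,
                          temperature = 1, seed = 1L,
                          update_interval = 50L, record_stride = 1L,
                          include_cmd_in_stats = TRUE) {
  for (nm in c("n_cmd_steps", "n_equil_steps", "n_prod_steps")) {
    v <- get(nm)
    check_scalar(v, nm, integerish = TRUE)
    if (v < 0) stop_invalid(nm, " must be >= 0")
  }
  check_scalar(n_replicas, "n_replicas", positive = TRUE, integerish = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  if (!is.numeric(friction) || length(friction) != 1L || friction <= 0)
    stop_invalid("friction must be > 0 (pure NVE is not supported)")
  check_scalar(temperature, "temperature", positive = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  check_scalar(update_interval, "update_interval", positive = TRUE,
               integerish = TRUE)
  check_scalar(record_stride, "record_stride", positive = TRUE,
               integerish = TRUE)
  structure(list(n_cmd_steps = as.integer(n_cmd_steps),
                 n_equil_steps = as.integer(n_equil_steps),
                 n_prod_steps = as.integer(n_prod_steps),
                 n_replicas = as.integer(n_replicas),
                 dt = dt, friction = friction, temperature = temperature,
                 seed = as.integer(seed),
                 update_interval = as.integer(update_interval),
                 record_stride = as.integer(record_stride),
                 include_cmd_in_stats = isTRUE(include_cmd_in_stats)),
            class = "protocol_spec")
}

#' Pair of boost-parameter states for the dual boost
#'
#' @param peptide `gamd_params` for the essential peptide energy V_L.
#' @param rest `gamd_params` for the remaining system energy V_D.
#' @return A `dual_boost_params` list.
#' @export
dual_boost_params <- function(peptide, rest) {
  stopifnot(inherits(peptide, "gamd_params"), inherits(rest, "gamd_params"))
  structure(list(peptide = peptide, rest = rest),
            class = "dual_boost_params")
}

# ---- trajectory container ----------------------------------------------

new_trajectory <- function(step, dt, v_total, v_peptide, v_rest,
                           dv_peptide, dv_rest, coords, kind) {
  df <- data.frame(step = step, time = step * dt, v_total = v_total,
                   v_peptide = v_peptide, v_rest = v_rest,
                   dv_peptide = dv_peptide, dv_rest = dv_rest,
                   dv_total = dv_peptide + dv_rest)
  attr(df, "coords") <- coords
  attr(df, "system_kind") <- kind
  class(df) <- c("gamd_trajectory", "data.frame")
  df
}

#' Per-frame coordinates of a trajectory
#'
#' @param traj A `gamd_trajectory` (or an array already).
#' @return For bead systems an array `frames x beads x 3`; for surface
#'   systems a matrix `frames x dim`.
#' @export
trajectory_frames <- function(traj) {
  if (is.array(traj) && is.null(attr(traj, "coords"))) return(traj)
  attr(traj, "coords")
}

#' @export
print.gamd_trajectory <- function(x, ...) {
  cat(sprintf("GaMD trajectory: %d frames (%s system)\n", nrow(x),
              attr(x, "system_kind")))
  cat(sprintf("  <V> = %.4f, <dV> = %.4f, max dV = %.4f\n",
              mean(x$v_total), mean(x$dv_total), max(x$dv_total)))
  invisible(x)
}

# ---- surface engine -----------------------------------------------------

surface_start <- function(surface) {
  if (!is.null(surface$minima)) surface$minima[1, ]
  else colMeans(surface$domain_bounds)
}

run_surface_chunk <- function(surface, x, vel, nsteps, protocol, params,
                              stream) {
  boost_on <- !is.null(params) && boost_ready(params)
  cpp_run_surface(surface_kind_code(surface), surface$pars,
                  x, vel, nsteps, protocol$dt, protocol$friction,
                  protocol$temperature,
                  if (boost_on) params$threshold_E else 0,
                  if (boost_on) params$k else 0, boost_on,
                  protocol$seed, stream, protocol$record_stride,
                  OVERFLOW_GUARD)
}

surface_traj <- function(res, protocol) {
  stride <- protocol$record_stride
  nrec <- length(res$V)
  new_trajectory(step = seq_len(nrec) * stride, dt = protocol$dt,
                 v_total = res$V, v_peptide = res$V, v_rest = 0,
                 dv_peptide = res$dV, dv_rest = 0,
                 coords = res$X, kind = "surface")
}

#' Conventional MD
#'
#' Unboosted Langevin (BAOAB) dynamics at the protocol temperature;
#' every boost column of the returned trajectory is zero. Deterministic
#' given the protocol seed.
#'
#' @param system A `potential_surface` or `toy_peptide_system`.
#' @param protocol A [protocol_spec()]; `n_prod_steps` is the run length.
#' @return A `gamd_trajectory`.
#' @export
run_cmd <- function(system, protocol) UseMethod("run_cmd")

#' @export
run_cmd.potential_surface <- function(system, protocol) {
  x <- surface_start(system)
  res <- run_surface_chunk(system, x, rep(0, length(x)),
                           protocol$n_prod_steps, protocol, NULL,
                           stream_id("cmd"))
  surface_traj(res, protocol)
}

#' @export
run_cmd.toy_peptide_system <- function(system, protocol) {
  res <- run_beads_chunk(system, system$coords,
                         matrix(0, system$n_beads, 3),
                         protocol$n_prod_steps, protocol, NULL, NULL,
                         stream_id("cmd"))
  beads_traj(res, system, protocol)
}

#' GaMD on a potential surface (total boost)
#'
#' Staged protocol with a single boost on the total potential energy:
#' cMD statistics collection, boosted equilibration with statistics
#' refreshed every `update_interval` steps, then `n_replicas` production
#' runs with frozen E and k.
#'
#' @param surface A `potential_surface`.
#' @param protocol A [protocol_spec()].
#' @param sigma_0 Boost-SD upper limit (kT units).
#' @param bound_mode `"lower"` or `"upper"` threshold bound.
#' @return A `pepgamd_run`: list with `cmd`, `equil`, `production` (list
#'   of trajectories), the frozen `params`, and `log` (stage summaries).
#' @export
run_gamd <- function(surface, protocol, sigma_0 = 10,
                     bound_mode = c("lower", "upper")) {
  bound_mode <- match.arg(bound_mode)
  stopifnot(inherits(surface, "potential_surface"))
  params <- gamd_params(sigma_0, bound_mode)
  x <- surface_start(surface)
  vel <- rep(0, length(x))

  res <- run_surface_chunk(surface, x, vel, protocol$n_cmd_steps, protocol,
                           NULL, stream_id("cmd"))
  cmd <- surface_traj(res, protocol)
  x <- res$x; vel <- res$v
  if (protocol$include_cmd_in_stats)
    params <- update_statistics(params, res$Vall)

  eq <- run_equilibration(function(nsteps, p, stream) {
    r <- run_surface_chunk(surface, x, vel, nsteps, protocol, p, stream)
    x <<- r$x; vel <<- r$v
    r
  }, params, protocol)
  params <- eq$params
  equil <- surface_traj(eq$res, protocol)

  production <- lapply(seq_len(protocol$n_replicas), function(r) {
    res <- run_surface_chunk(surface, x, vel, protocol$n_prod_steps,
                             protocol, params, stream_id("prod", r))
    surface_traj(res, protocol)
  })
  finish_run(system = surface, protocol = protocol, params = params,
             cmd = cmd, equil = equil, production = production,
             kind = "surface")
}

# generic equilibration loop: `chunk_fn(nsteps, params, stream)` advances
# the state and returns the chunk result; statistics refresh per chunk
run_equilibration <- function(chunk_fn, params, protocol) {
  n_left <- protocol$n_equil_steps
  pieces <- list()
  i <- 0L
  while (n_left > 0L) {
    i <- i + 1L
    nstep <- min(protocol$update_interval, n_left)
    r <- chunk_fn(nstep, params, stream_id("equil", i))
    params <- if (is.list(r$params_update)) r$params_update else
      update_statistics(params, r$Vall)
    pieces[[i]] <- r
    n_left <- n_left - nstep
  }
  res <- if (length(pieces)) combine_chunks(pieces) else NULL
  list(params = params, res = res)
}

combine_chunks <- function(pieces) {
  out <- pieces[[length(pieces)]]
  out$V <- unlist(lapply(pieces, `[[`, "V"))
  out$dV <- unlist(lapply(pieces, `[[`, "dV"))
  out$Vall <- unlist(lapply(pieces, `[[`, "Vall"))
  out$X <- do.call(rbind, lapply(pieces, `[[`, "X"))
  if (!is.null(out$frames)) {
    out$frames <- do.call(rbind, lapply(pieces, `[[`, "frames"))
    out$components <- do.call(rbind, lapply(pieces, `[[`, "components"))
    for (nm in c("VL", "VD", "dVL", "dVD", "VLall", "VDall"))
      out[[nm]] <- unlist(lapply(pieces, `[[`, nm))
  }
  out
}

finish_run <- function(system, protocol, params, cmd, equil, production,
                       kind, counters = NULL) {
  log <- if (inherits(params, "gamd_params")) {
    list(total = params_summary(params))
  } else {
    list(peptide = params_summary(params$peptide),
         rest = params_summary(params$rest))
  }
  structure(list(system = system, protocol = protocol, params = params,
                 cmd = cmd, equil = equil, production = production,
                 log = log, counters = counters),
            class = "pepgamd_run")
}

params_summary <- function(p) {
  c(v_max = p$v_max, v_min = p$v_min, v_avg = p$v_avg,
    sigma_v = p$sigma_v, k0 = p$k0, k = p$k, E = p$threshold_E,
    sigma_dv = sigma_dv(p))
}

#' @export
print.pepgamd_run <- function(x, ...) {
  cat(sprintf("Staged GaMD run: %d cMD + %d equil + %d x %d production steps\n",
              x$protocol$n_cmd_steps, x$protocol$n_equil_steps,
              x$protocol$n_replicas, x$protocol$n_prod_steps))
  for (nm in names(x$log)) {
    s <- x$log[[nm]]
    cat(sprintf("  [%s] Vmax=%.3f Vmin=%.3f Vavg=%.3f sigmaV=%.3f k0=%.3f E=%.3f sigma_dV=%.3f\n",
                nm, s["v_max"], s["v_min"], s["v_avg"], s["sigma_v"],
                s["k0"], s["E"], s["sigma_dv"]))
  }
  invisible(x)
}

#' Pooled production frames of a staged run
#'
#' @param run A `pepgamd_run`.
#' @param replica Optional single replica index; default pools all
#'   replicas (frames from all production runs combined).
#' @return A `gamd_trajectory`.
#' @export
production_frames <- function(run, replica = NULL) {
  trajs <- if (is.null(replica)) run$production else run$production[replica]
  df <- do.call(rbind, lapply(trajs, function(t) as.data.frame(t)))
  coords <- trajectory_frames(trajs[[1]])
  if (length(trajs) > 1L) {
    if (length(dim(coords)) == 3L)
      coords <- do.call(abind3, lapply(trajs, trajectory_frames))
    else
      coords <- do.call(rbind, lapply(trajs, trajectory_frames))
  }
  attr(df, "coords") <- coords
  attr(df, "system_kind") <- attr(trajs[[1]], "system_kind")
  class(df) <- c("gamd_trajectory", "data.frame")
  df
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1], 0L)),
                           d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

# ---- bead engine --------------------------------------------------------

run_beads_chunk <- function(system, x, vel, nsteps, protocol, pL, pD,
                            stream) {
  onL <- !is.null(pL) && boost_ready(pL)
  onD <- !is.null(pD) && boost_ready(pD)
  cpp_run_beads(system$model, x, vel, system$masses, nsteps,
                protocol$dt, protocol$friction, system$temperature,
                if (onL) pL$threshold_E else 0, if (onL) pL$k else 0, onL,
                if (onD) pD$threshold_E else 0, if (onD) pD$k else 0, onD,
                protocol$seed, stream, protocol$record_stride,
                OVERFLOW_GUARD)
}

beads_traj <- function(res, system, protocol) {
  stride <- protocol$record_stride
  nrec <- length(res$VL)
  coords <- array(t(res$frames), c(3, system$n_beads, nrec))
  coords <- aperm(coords, c(3, 2, 1))
  new_trajectory(step = seq_len(nrec) * stride, dt = protocol$dt,
                 v_total = res$VL + res$VD, v_peptide = res$VL,
                 v_rest = res$VD, dv_peptide = res$dVL, dv_rest = res$dVD,
                 coords = coords, kind = "beads")
}

#' Dual-boost Pep-GaMD on the toy peptide system
#'
#' One boost on the essential peptide energy V_L and a second on the
#' remaining system energy V_D, each with its own adaptive statistics.
#' Stage 1 cMD collects both statistics unboosted; stage 2 equilibration
#' boosts while refreshing every `update_interval` steps; stage 3 runs
#' `n_replicas` independent productions with frozen parameters (frames
#' whose V exceeds the recorded Vmax are counted, not refreshed, so
#' reweighting stays valid).
#'
#' @param system A `toy_peptide_system`.
#' @param protocol A [protocol_spec()].
#' @param sigma_0_L,sigma_0_D Boost-SD limits for the peptide and rest
#'   terms (kT units).
#' @param bound_mode `"lower"` or `"upper"`.
#' @return A `pepgamd_run`; `$params` is a `dual_boost_params`, and
#'   `$counters` reports production frames above the recorded Vmax.
#' @export
run_pep_gamd <- function(system, protocol, sigma_0_L = 10, sigma_0_D = 10,
                         bound_mode = c("lower", "upper")) {
  bound_mode <- match.arg(bound_mode)
  stopifnot(inherits(system, "toy_peptide_system"))
  pL <- gamd_params(sigma_0_L, bound_mode)
  pD <- gamd_params(sigma_0_D, bound_mode)
  x <- system$coords
  vel <- matrix(0, system$n_beads, 3)

  res <- run_beads_chunk(system, x, vel, protocol$n_cmd_steps, protocol,
                         NULL, NULL, stream_id("cmd"))
  cmd <- beads_traj(res, system, protocol)
  x <- res$x; vel <- res$v
  if (protocol$include_cmd_in_stats) {
    pL <- update_statistics(pL, res$VLall)
    pD <- update_statistics(pD, res$VDall)
  }

  n_left <- protocol$n_equil_steps
  pieces <- list()
  i <- 0L
  while (n_left > 0L) {
    i <- i + 1L
    nstep <- min(protocol$update_interval, n_left)
    r <- run_beads_chunk(system, x, vel, nstep, protocol, pL, pD,
                         stream_id("equil", i))
    x <- r$x; vel <- r$v
    pL <- update_statistics(pL, r$VLall)
    pD <- update_statistics(pD, r$VDall)
    pieces[[i]] <- r
    n_left <- n_left - nstep
  }
  equil <- if (length(pieces))
    beads_traj(combine_chunks(pieces), system, protocol) else NULL

  above_vmax <- 0L
  production <- lapply(seq_len(protocol$n_replicas), function(r) {
    res <- run_beads_chunk(system, x, vel, protocol$n_prod_steps, protocol,
                           pL, pD, stream_id("prod", r))
    above_vmax <<- above_vmax +
      sum(res$VLall > pL$v_max) + sum(res$VDall > pD$v_max)
    beads_traj(res, system, protocol)
  })
  finish_run(system = system, protocol = protocol,
             params = dual_boost_params(pL, pD),
             cmd = cmd, equil = equil, production = production,
             kind = "beads",
             counters = c(frames_above_vmax = above_vmax))
}
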