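# Boost-potential state for one boosted energy term: running statistics of
# V (max, min, mean, population SD via Welford moments) and the derived
# boost parameters E, k, k0.
#
# Boost law:      dV(r) = k (E - V)^2 / 2  when V < E, else 0.
# Threshold:      Vmax <= E <= Vmin + 1/k, with k = k0 / (Vmax - Vmin).
# Lower bound     E = Vmax:      k0' = min(1, (s0/sV) (Vmax-Vmin)/(Vmax-Vavg))
# Upper bound     E = Vmin+1/k:  k0" = (1 - s0/sV) (Vmax-Vmin)/(Vavg-Vmin),
#                 used if 0 < k0" <= 1, otherwise fall back to k0'.
# The SD constraint sigma_dV = k (E - Vavg) sigma_V <= sigma_0 is then
# satisfied by construction for the lower bound.

#' Create boost-parameter state for one boosted energy term
#'
#' @param sigma_0 Upper limit on the boost-potential SD (energy; the usual
#'   working value is 10 kT).
#' @param bound_mode `"lower"` (threshold E at Vmax, the common default) or
#'   `"upper"` (E at Vmin + 1/k with fallback).
#' @return A `gamd_params` object with empty statistics.
#' @export
gamd_params <- function(sigma_0 = 10, bound_mode = c("lower", "upper")) {
  if (sigma_0 < 0) stop_invalid("sigma_0 must be >= 0")
  bound_mode <- match.arg(bound_mode)
  structure(list(v_max = -Inf, v_min = Inf, v_avg = NA_real_,
                 m2 = 0, n_samples = 0L, sigma_v = NA_real_,
                 sigma_0 = sigma_0, bound_mode = bound_mode,
                 k0 = NA_real_, k = NA_real_, threshold_E = NA_real_,
                 k0_branch = NA_character_),
            class = "gamd_params")
}

#' @export
print.gamd_params <- function(x, ...) {
  cat(sprintf("GaMD boost parameters (%s bound, sigma_0 = %g)\n",
              x$bound_mode, x$sigma_0))
  cat(sprintf("  n = %d  Vmax = %.4f  Vmin = %.4f  Vavg = %.4f  sigmaV = %.4f\n",
              x$n_samples, x$v_max, x$v_min, x$v_avg, x$sigma_v))
  cat(sprintf("  k0 = %.4f (%s)  k = %.6g  E = %.4f\n",
              x$k0, x$k0_branch, x$k, x$threshold_E))
  invisible(x)
}

#' Update running potential-energy statistics
#'
#' Accumulates `v` (scalar or vector of samples) into the running max, min,
#' mean and population SD using numerically stable (Welford/Chan) moment
#' combination, then recomputes k0, k and E for the current `bound_mode`.
#' k0 stays undefined until at least two samples with spread have been
#' seen.
#'
#' @param params A `gamd_params` object.
#' @param v New potential-energy sample(s).
#' @return Updated `gamd_params`.
#' @export
update_statistics <- function(params, v) {
  v <- as.numeric(v)
  nb <- length(v)
  if (nb == 0L) return(params)
  mb <- mean(v)
  m2b <- sum((v - mb)^2)
  n1 <- params$n_samples
  if (n1 == 0L) {
    params$v_avg <- mb
    params$m2 <- m2b
  } else {
    delta <- mb - params$v_avg
    n <- n1 + nb
    params$v_avg <- params$v_avg + delta * nb / n
    params$m2 <- params$m2 + m2b + delta^2 * n1 * nb / n
  }
  params$n_samples <- n1 + nb
  params$v_max <- max(params$v_max, v)
  params$v_min <- min(params$v_min, v)
  params$sigma_v <- if (params$n_samples >= 2L)
    sqrt(params$m2 / params$n_samples) else 0
  refresh_boost(params)
}

refresh_boost <- function(params) {
  ok <- params$n_samples >= 2L &&
    params$v_max > params$v_min && params$sigma_v > 0
  if (!ok) { # degenerate or warming up: boost stays off
    params$k0 <- NA_real_
    params$k <- NA_real_
    params$threshold_E <- NA_real_
    params$k0_branch <- NA_character_
    return(params)
  }
  if (params$bound_mode == "lower") {
    params$k0 <- k0_lower_bound(params$v_max, params$v_min, params$v_avg,
                                params$sigma_v, params$sigma_0)
    params$k0_branch <- "lower"
  } else {
    k0 <- k0_upper_bound(params$v_max, params$v_min, params$v_avg,
                         params$sigma_v, params$sigma_0)
    params$k0_branch <- attr(k0, "branch")
    params$k0 <- as.numeric(k0)
  }
  params$k <- params$k0 / (params$v_max - params$v_min)
  params$threshold_E <- if (identical(params$k0_branch, "upper"))
    params$v_min + 1 / params$k else params$v_max
  params
}

check_stats <- function(v_max, v_min, v_avg, sigma_v) {
  if (sigma_v <= 0 || v_max <= v_min || v_max <= v_avg)
    stop(structure(class = c("pepgamd_degenerate_statistics", "error",
                             "condition"),
                   list(message = paste0(
                     "degenerate statistics: need sigma_v > 0, ",
                     "v_max > v_min and v_max > v_avg"), call = NULL)))
}

#' k0 for the lower threshold bound (E = Vmax)
#'
#' `min(1, (sigma_0 / sigma_v) * (v_max - v_min) / (v_max - v_avg))`.
#'
#' @param v_max,v_min,v_avg Max, min and mean potential energy.
#' @param sigma_v Population SD of the potential energy (> 0).
#' @param sigma_0 User limit on the boost SD.
#' @return k0 in (0, 1].
#' @export
k0_lower_bound <- function(v_max, v_min, v_avg, sigma_v, sigma_0) {
  check_stats(v_max, v_min, v_avg, sigma_v)
  min(1, (sigma_0 / sigma_v) * (v_max - v_min) / (v_max - v_avg))
}

#' k0 for the upper threshold bound (E = Vmin + 1/k)
#'
#' `(1 - sigma_0 / sigma_v) * (v_max - v_min) / (v_avg - v_min)` when that
#' value lies in (0, 1]; otherwise falls back to the lower-bound formula.
#' The attribute `"branch"` records `"upper"` or `"fallback_lower"`.
#'
#' @inheritParams k0_lower_bound
#' @return k0 in (0, 1] with attribute `"branch"`.
#' @export
k0_upper_bound <- function(v_max, v_min, v_avg, sigma_v, sigma_0) {
  check_stats(v_max, v_min, v_avg, sigma_v)
  if (v_avg <= v_min)
    stop(structure(class = c("pepgamd_degenerate_statistics", "error",
                             "condition"),
                   list(message = "degenerate statistics: need v_avg > v_min",
                        call = NULL)))
  k0dd <- (1 - sigma_0 / sigma_v) * (v_max - v_min) / (v_avg - v_min)
  if (k0dd > 0 && k0dd <= 1)
    structure(k0dd, branch = "upper")
  else
    structure(k0_lower_bound(v_max, v_min, v_avg, sigma_v, sigma_0),
              branch = "fallback_lower")
}

boost_ready <- function(params) {
  is.finite(params$k) && is.finite(params$threshold_E) && params$k > 0
}

#' Harmonic boost potential
#'
#' \eqn{\Delta V = k (E - V)^2 / 2} when `V < E`, else 0.
#'
#' @param v Potential energy (vectorized).
#' @param params A `gamd_params` with defined `k` and `threshold_E`, or a
#'   list with elements `k` and `threshold_E`.
#' @return Boost potential, never negative.
#' @export
boost_potential <- function(v, params) {
  if (!boost_ready(params)) return(rep(0, length(v)))
  ifelse(v < params$threshold_E,
         0.5 * params$k * (params$threshold_E - v)^2, 0)
}

#' Force-scaling factor on the boosted surface
#'
#' The gradient of \eqn{V^* = V + \Delta V} rescales forces by
#' \eqn{1 - k (E - V)} below the threshold and 1 above it. Within the
#' threshold bracket `E <= Vmin + 1/k` the factor stays in (0, 1]: forces
#' are damped, never inverted — the smoothing criterion made operational.
#'
#' @inheritParams boost_potential
#' @return Dimensionless scale factor(s).
#' @export
boosted_force_scale <- function(v, params) {
  if (!boost_ready(params)) return(rep(1, length(v)))
  ifelse(v < params$threshold_E,
         1 - params$k * (params$threshold_E - v), 1)
}

#' Predicted boost-potential SD from the statistics
#'
#' \eqn{\sigma_{\Delta V} = k (E - V_{avg}) \sigma_V}; by construction
#' `<= sigma_0` under the lower-bound parameter choice.
#'
#' @param params A `gamd_params`.
#' @return Energy-valued scalar (0 while the boost is undefined).
#' @export
sigma_dv <- function(params) {
  if (!boost_ready(params)) return(0)
  params$k * (params$threshold_E - params$v_avg) * params$sigma_v
}
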