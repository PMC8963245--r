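# Synthetic weighted samples: coordinate draws paired with boost values
# constructed so that cumulant reweighting must reproduce a known target
# PMF. Construction:
#
#   * constant(c) and gaussian(mean, sd): the boost is independent of the
#     coordinate, so the biased coordinate density equals the target
#     density and the per-bin reweighting factor is bin-independent; it
#     cancels in the Eq-8 normalization and the anchored profile must
#     match the target.
#   * state_dependent(mean_fn, sd): the boost mean m(x) varies with x.
#     The per-bin factor is exp(beta m(x) + beta^2 sd^2 / 2), so the
#     coordinates are drawn from the compensated density
#     p*(x) propto exp(-beta F(x)) * exp(-beta m(x) - beta^2 sd^2 / 2),
#     which is exactly what reweighting inverts.
#
# Sampling is inverse-CDF on a fine grid (cell choice by categorical draw,
# uniform within the cell), so the construction is exact up to the grid
# resolution. Gaussian boost draws are clamped at zero to honour the
# non-negativity of a boost potential; for a coordinate-independent boost
# the clamping shifts every bin's factor equally and still cancels.

#' Boost models for the synthetic generator
#'
#' @param c,mean,sd Constant value / Gaussian moments (energy units).
#' @param mean_fn Function of the coordinate giving the boost mean.
#' @return A boost-model descriptor.
#' @export
boost_constant <- function(c) {
  check_scalar(c, "c")
  if (c < 0) stop_invalid("constant boost must be >= 0")
  structure(list(kind = "constant", c = c), class = "boost_model")
}

#' @rdname boost_constant
#' @export
boost_gaussian <- function(mean, sd) {
  check_scalar(mean, "mean")
  check_scalar(sd, "sd")
  if (sd < 0) stop_invalid("sd must be >= 0")
  structure(list(kind = "gaussian", mean = mean, sd = sd),
            class = "boost_model")
}

#' @rdname boost_constant
#' @export
boost_state_dependent <- function(mean_fn, sd) {
  stopifnot(is.function(mean_fn))
  check_scalar(sd, "sd")
  if (sd < 0) stop_invalid("sd must be >= 0")
  structure(list(kind = "state_dependent", mean_fn = mean_fn, sd = sd),
            class = "boost_model")
}

#' Draw coordinate/boost pairs consistent with a target PMF
#'
#' @param target_pmf Function `F(x)` (energy) over the coordinate range.
#' @param boost_model A [boost_constant()], [boost_gaussian()] or
#'   [boost_state_dependent()] descriptor.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @param range Coordinate interval `c(lo, hi)` to sample over.
#' @param beta Inverse temperature (default 1).
#' @param n_grid Grid cells for the inverse-CDF construction.
#' @return A `synthetic_weighted_sample` with `coordinate_values`,
#'   `boost_values` (non-negative, same length), `generating_pmf`, `seed`.
#' @export
synth_weighted_samples <- function(target_pmf, boost_model, n, seed,
                                   range = c(0, 10), beta = 1,
                                   n_grid = 2001L) {
  check_scalar(n, "n", integerish = TRUE)
  if (n < 1) stop_invalid("n must be >= 1")
  check_scalar(seed, "seed", integerish = TRUE)
  check_scalar(beta, "beta", positive = TRUE)
  stopifnot(is.function(target_pmf), inherits(boost_model, "boost_model"))

  edges <- seq(range[1], range[2], length.out = n_grid + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  f <- vapply(mid, target_pmf, 0.0)
  logw <- -beta * (f - min(f))
  if (boost_model$kind == "state_dependent") {
    m <- vapply(mid, boost_model$mean_fn, 0.0)
    if (any(m < 0)) stop_invalid("state-dependent boost mean must be >= 0")
    logw <- logw - beta * m - beta^2 * boost_model$sd^2 / 2
  }
  p <- exp(logw - max(logw))
  p <- p / sum(p)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  cell <- sample.int(n_grid, n, replace = TRUE, prob = p)
  xs <- edges[cell] + stats::runif(n) * diff(edges)[1]
  dv <- switch(boost_model$kind,
    constant = rep(boost_model$c, n),
    gaussian = pmax(0, stats::rnorm(n, boost_model$mean, boost_model$sd)),
    state_dependent = pmax(0, vapply(xs, boost_model$mean_fn, 0.0) +
                             stats::rnorm(n, 0, boost_model$sd)))
  structure(list(coordinate_values = xs, boost_values = dv,
                 generating_pmf = target_pmf, seed = as.integer(seed),
                 beta = beta, boost_model = boost_model),
            class = "synthetic_weighted_sample")
}

#' @export
print.synthetic_weighted_sample <- function(x, ...) {
  cat(sprintf("Synthetic weighted sample: n = %d, boost model '%s', seed %d\n",
              length(x$coordinate_values), x$boost_model$kind, x$seed))
  invisible(x)
}
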