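# Energetic reweighting: recover canonical free-energy profiles from
# boosted trajectories by cumulant expansion to second order. Per bin j,
#   p(A_j) = p*(A_j) <exp(beta dV)>_j / norm,
#   <exp(beta dV)>_j ~= exp(beta C1_j + beta^2 C2_j / 2),
#   F(A_j) = F*(A_j) - C1_j - (beta/2) C2_j + Fc,
# with C1 the per-bin mean of the boost and C2 its population variance.
# Bins with fewer frames than the occupancy cutoff are excluded, never
# interpolated; the minimum over included bins is anchored to zero.

#' First two cumulants of the boost potential
#'
#' @param dv_samples Numeric vector of boost-potential values (>= 2).
#' @return Named vector `c(c1 = mean, c2 = population variance)`.
#' @export
cumulants <- function(dv_samples) {
  dv_samples <- as.numeric(dv_samples)
  if (length(dv_samples) < 2L)
    stop("insufficient samples: cumulants need at least 2 values")
  m <- mean(dv_samples)
  c(c1 = m, c2 = mean((dv_samples - m)^2))
}

#' Second-order cumulant reweighting factor
#'
#' \eqn{\exp(\beta C_1 + \beta^2 C_2 / 2)}, the Gaussian-exact
#' approximation to the ensemble-averaged \eqn{e^{\beta \Delta V}}.
#' The log-scale value is kept as attribute `"log"`; downstream profile
#' arithmetic uses logs throughout so large boosts cannot overflow.
#'
#' @param c1 First cumulant (energy).
#' @param c2 Second cumulant (energy^2, >= 0).
#' @param beta Inverse temperature.
#' @return The factor, with attribute `"log"`.
#' @export
reweighting_factor <- function(c1, c2, beta) {
  if (any(c2 < 0)) stop_invalid("c2 must be >= 0")
  lf <- beta * c1 + beta^2 * c2 / 2
  structure(exp(lf), log = lf)
}

# ---- free_energy_profile ------------------------------------------------

# dense arrays over the bounding box of occupied bins; idx0 holds the
# integer bin index (floor(a / width)) of the first array element per dim
new_profile <- function(f, f_star, c1, c2, counts, idx0, bin_width, beta,
                        cutoff_frames) {
  d <- length(idx0)
  centers <- lapply(seq_len(d), function(j) {
    n <- if (d == 1L) length(f) else dim(f)[j]
    (idx0[j] + seq_len(n) - 1 + 0.5) * bin_width[j]
  })
  edges <- lapply(seq_len(d), function(j)
    c(centers[[j]] - bin_width[j] / 2, max(centers[[j]]) + bin_width[j] / 2))
  structure(list(dim = d, f = f, f_star = f_star, c1 = c1, c2 = c2,
                 counts = counts, idx0 = idx0, bin_width = bin_width,
                 centers = centers, bin_edges = edges, beta = beta,
                 cutoff_frames = cutoff_frames),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  inc <- sum(is.finite(x$f))
  cat(sprintf("Free-energy profile (%dD): %d bins (%d included), bin width %s\n",
              x$dim, length(x$f), inc,
              paste(format(x$bin_width), collapse = " x ")))
  cat(sprintf("  beta = %g, occupancy cutoff = %g frames\n",
              x$beta, x$cutoff_frames))
  if (inc > 0)
    cat(sprintf("  F range over included bins: [0, %.3f]\n",
                max(x$f, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.free_energy_profile <- function(x, ...) {
  if (x$dim == 1L) {
    data.frame(bin_center = x$centers[[1]], F = as.vector(x$f),
               counts = as.vector(x$counts), c1 = as.vector(x$c1),
               c2 = as.vector(x$c2))
  } else {
    g <- expand.grid(x_center = x$centers[[1]], y_center = x$centers[[2]])
    data.frame(g, F = as.vector(x$f), counts = as.vector(x$counts))
  }
}

#' Normalized Boltzmann probabilities of a profile
#'
#' `exp(-beta F)` over included bins, normalized to sum to one.
#'
#' @param profile A `free_energy_profile`.
#' @return Array shaped like the profile; excluded bins are `NA`.
#' @export
profile_probabilities <- function(profile) {
  p <- exp(-profile$beta * profile$f)
  p / sum(p, na.rm = TRUE)
}

# shared binning: integer bin index floor(a / width) per dimension
bin_indices <- function(a, bin_width) {
  d <- ncol(a)
  idx <- matrix(0L, nrow(a), d)
  for (j in seq_len(d)) idx[, j] <- as.integer(floor(a[, j] / bin_width[j]))
  idx
}

# build a profile from weighted points (quadrature oracle path: weights are
# Boltzmann factors, no cumulant correction)
profile_from_weights <- function(a, w, bin_width, beta, cutoff_frames,
                                 weight_total) {
  d <- ncol(a)
  bin_width <- rep_len(bin_width, d)
  idx <- bin_indices(a, bin_width)
  idx0 <- apply(idx, 2, min)
  dims <- apply(idx, 2, max) - idx0 + 1L
  lin <- (idx[, 1] - idx0[1]) + 1L
  if (d == 2L) lin <- lin + dims[1] * (idx[, 2] - idx0[2])
  ws <- vapply(split(w, lin), sum, 0.0)
  counts <- array(0, dim = if (d == 1L) dims else dims)
  counts[as.integer(names(ws))] <- ws
  f <- -log(counts / weight_total) / beta
  f[!is.finite(f)] <- NA_real_
  if (cutoff_frames > 0) f[counts < cutoff_frames] <- NA_real_
  if (!any(is.finite(f))) stop("empty profile: no bin meets the occupancy cutoff")
  f <- f - min(f, na.rm = TRUE)
  zero <- array(NA_real_, dim = dim(counts) %||% length(counts))
  new_profile(f, f_star = f, c1 = zero, c2 = zero, counts = counts,
              idx0 = idx0, bin_width = bin_width, beta = beta,
              cutoff_frames = cutoff_frames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reweight a boosted trajectory into a free-energy profile
#'
#' Bins the reaction-coordinate series, computes per-bin boost cumulants,
#' and applies the second-order cumulant correction to the biased
#' histogram free energy. Bins with fewer than `cutoff_frames` frames are
#' excluded (NA), and the minimum over included bins is anchored to 0.
#'
#' @param coords Numeric vector (1D) or 2-column matrix (2D) of
#'   reaction-coordinate values, one row per frame.
#' @param dv Boost potential per frame (same length).
#' @param bin_width Bin width(s); default 1 coordinate unit.
#' @param cutoff_frames Minimum frames per included bin; default 500.
#' @param beta Inverse temperature; default 1 (reduced units).
#' @return A `free_energy_profile`.
#' @export
reweight_profile <- function(coords, dv, bin_width = 1, cutoff_frames = 500,
                             beta = 1) {
  a <- if (is.null(dim(coords))) matrix(coords, ncol = 1) else as.matrix(coords)
  d <- ncol(a)
  if (!d %in% c(1L, 2L)) stop_invalid("coords must be 1D or a 2-column matrix")
  dv <- as.numeric(dv)
  if (nrow(a) != length(dv))
    stop("input shape: coords has ", nrow(a), " frames but dv has ",
         length(dv))
  bin_width <- rep_len(as.numeric(bin_width), d)
  if (any(bin_width <= 0)) stop_invalid("bin_width must be > 0")
  check_scalar(cutoff_frames, "cutoff_frames")
  check_scalar(beta, "beta", positive = TRUE)

  n <- nrow(a)
  idx <- bin_indices(a, bin_width)
  idx0 <- apply(idx, 2, min)
  dims <- apply(idx, 2, max) - idx0 + 1L
  lin <- (idx[, 1] - idx0[1]) + 1L
  if (d == 2L) lin <- lin + dims[1] * (idx[, 2] - idx0[2])

  grp <- split(dv, lin)
  counts <- array(0, dim = dims)
  c1 <- c2 <- array(NA_real_, dim = dims)
  at <- as.integer(names(grp))
  counts[at] <- lengths(grp)
  c1[at] <- vapply(grp, mean, 0.0)
  c2[at] <- vapply(grp, function(z) mean((z - mean(z))^2), 0.0)

  f_star <- -log(counts / n) / beta
  f_star[counts == 0] <- NA_real_
  log_factor <- beta * c1 + beta^2 * c2 / 2
  f <- f_star - log_factor / beta
  f[counts < cutoff_frames] <- NA_real_
  if (!any(is.finite(f)))
    stop("empty profile: no bin meets the occupancy cutoff of ",
         cutoff_frames, " frames")
  f <- f - min(f, na.rm = TRUE)
  new_profile(f, f_star = f_star, c1 = c1, c2 = c2, counts = counts,
              idx0 = idx0, bin_width = bin_width, beta = beta,
              cutoff_frames = cutoff_frames)
}

#' Anharmonicity of a boost-potential distribution
#'
#' Entropy deficit \eqn{\gamma = \ln\sqrt{2\pi e\,\sigma^2} - H(\Delta V)}
#' of the empirical distribution relative to a Gaussian of equal variance;
#' zero iff exactly Gaussian, positive otherwise. H is a histogram
#' differential-entropy estimate with Scott's-rule bin width
#' \eqn{3.49\,\sigma n^{-1/3}}. Small values justify truncating the
#' cumulant expansion at second order.
#'
#' @param dv_samples Boost-potential values (>= 100).
#' @return Non-negative scalar (up to estimator noise).
#' @export
anharmonicity <- function(dv_samples) {
  dv_samples <- as.numeric(dv_samples)
  n <- length(dv_samples)
  if (n < 100L) stop("insufficient samples: anharmonicity needs >= 100 values")
  s <- sqrt(mean((dv_samples - mean(dv_samples))^2))
  if (s == 0) return(Inf) # degenerate point mass: maximally non-Gaussian
  h <- 3.49 * s * n^(-1 / 3)
  idx <- floor(dv_samples / h)
  p <- tabulate(idx - min(idx) + 1L) / n
  p <- p[p > 0]
  H <- -sum(p * log(p / h))
  log(sqrt(2 * pi * exp(1)) * s) - H
}
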