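# Analytic model potentials. Each surface carries closures for energy and
# gradient plus a descriptor the compiled integrator can evaluate directly.

new_potential_surface <- function(dimensionality, energy, gradient,
                                  domain_bounds, name, kind, pars,
                                  minima = NULL) {
  structure(list(dimensionality = dimensionality,
                 energy = energy, gradient = gradient,
                 domain_bounds = domain_bounds, name = name,
                 kind = kind, pars = pars, minima = minima),
            class = "potential_surface")
}

#' @export
print.potential_surface <- function(x, ...) {
  cat(sprintf("Potential surface \"%s\" (%dD)\n", x$name, x$dimensionality))
  b <- x$domain_bounds
  for (j in seq_len(x$dimensionality))
    cat(sprintf("  dim %d bounds: [%.3f, %.3f]\n", j, b[1, j], b[2, j]))
  if (!is.null(x$minima)) {
    cat("  analytic minima:\n")
    for (i in seq_len(nrow(x$minima)))
      cat("   ", paste(sprintf("%.3f", x$minima[i, ]), collapse = ", "), "\n")
  }
  invisible(x)
}

surface_kind_code <- function(surface) {
  switch(surface$kind, harmonic = 1L, double_well = 2L, three_state = 3L,
         stop_invalid("surface kind '", surface$kind,
                      "' has no compiled evaluator"))
}

#' User-defined analytic surface
#'
#' Wraps arbitrary energy/gradient closures as a `potential_surface` for
#' the quadrature routines ([analytic_pmf()]); the dynamics engines
#' require the built-in (compiled) surface kinds.
#'
#' @param energy Function of a point (numeric vector) returning energy.
#' @param gradient Function returning the gradient vector (optional).
#' @param domain_bounds 2 x d matrix of lower/upper bounds.
#' @param name Label.
#' @return A `potential_surface` of kind `"custom"`.
#' @export
make_custom_surface <- function(energy, gradient = NULL, domain_bounds,
                                name = "custom") {
  stopifnot(is.function(energy))
  domain_bounds <- as.matrix(domain_bounds)
  new_potential_surface(ncol(domain_bounds), energy, gradient,
                        domain_bounds, name, kind = "custom", pars = NULL)
}

#' Evaluate a potential surface
#'
#' @param surface A `potential_surface`.
#' @param pts Numeric vector (one point) or matrix with one point per row.
#' @return Energies (or gradients, one row per point) at the given points.
#' @export
surface_energy <- function(surface, pts) {
  pts <- as_points(pts, surface$dimensionality)
  if (surface$kind == "custom")
    return(apply(pts, 1, surface$energy))
  cpp_surface_energy(surface_kind_code(surface), surface$pars, pts)
}

#' @rdname surface_energy
#' @export
surface_gradient <- function(surface, pts) {
  pts <- as_points(pts, surface$dimensionality)
  if (surface$kind == "custom") {
    if (is.null(surface$gradient))
      stop_invalid("custom surface has no gradient function")
    return(t(apply(pts, 1, surface$gradient)))
  }
  cpp_surface_gradient(surface_kind_code(surface), surface$pars, pts)
}

as_points <- function(pts, d) {
  if (is.null(dim(pts))) {
    if (d == 1L) pts <- matrix(pts, ncol = 1L)
    else pts <- matrix(pts, ncol = d, byrow = TRUE)
  }
  storage.mode(pts) <- "double"
  if (ncol(pts) != d) stop_invalid("points have ", ncol(pts),
                                   " columns; surface is ", d, "D")
  pts
}

#' Harmonic well surface
#'
#' \eqn{V(x) = \kappa |x|^2 / 2}; its PMF and equipartition moments are
#' known in closed form, which makes it the sharpest oracle for the
#' integrator and the reweighting chain.
#'
#' @param kappa Force constant (energy / length^2).
#' @param dimensionality 1 or 2.
#' @param half_width Half-width of the reported domain (lengths).
#' @return A `potential_surface`.
#' @export
make_harmonic_well <- function(kappa, dimensionality = 1L, half_width = 6) {
  check_scalar(kappa, "kappa", positive = TRUE)
  d <- as.integer(dimensionality)
  if (!d %in% c(1L, 2L)) stop_invalid("dimensionality must be 1 or 2")
  bounds <- matrix(c(-half_width, half_width), nrow = 2, ncol = d)
  new_potential_surface(
    d,
    energy = function(x) 0.5 * kappa * sum(x^2),
    gradient = function(x) kappa * x,
    domain_bounds = bounds, name = "harmonic",
    kind = "harmonic", pars = kappa,
    minima = matrix(0, nrow = 1, ncol = d))
}

#' Symmetric quartic double well
#'
#' \eqn{V(x) = h (x^2 - a^2)^2 / a^4} with minima at \eqn{\pm a} (where
#' \eqn{a} is half the well separation) and barrier height exactly `h` at
#' the origin. A desk-scale stand-in for a rugged landscape whose barrier
#' the boost is meant to flatten.
#'
#' @param barrier_height Barrier height `h` (energy, > 0).
#' @param well_separation Distance between the two minima (> 0).
#' @return A 1D `potential_surface`; `$minima` holds the analytic minima.
#' @export
make_double_well <- function(barrier_height, well_separation) {
  check_scalar(barrier_height, "barrier_height", positive = TRUE)
  check_scalar(well_separation, "well_separation", positive = TRUE)
  a <- well_separation / 2
  h <- barrier_height
  bounds <- matrix(c(-2.5 * a, 2.5 * a), nrow = 2, ncol = 1)
  new_potential_surface(
    1L,
    energy = function(x) h * (x[1]^2 - a^2)^2 / a^4,
    gradient = function(x) 4 * h * x[1] * (x[1]^2 - a^2) / a^4,
    domain_bounds = bounds, name = "double_well",
    kind = "double_well", pars = c(h, a),
    minima = matrix(c(-a, a), ncol = 1))
}

#' Multi-basin landscape from inverted Gaussians
#'
#' Sum of inverted Gaussian wells plus a confining quadratic wall outside
#' the padded bounding box of the minima. With minima planted along an
#' activation-like coordinate it emulates the Inactive / Intermediate /
#' Active basins of a GPCR activation landscape.
#'
#' @param minima_positions Matrix (rows = minima) or list of 2D points.
#' @param depths Well depths (energy, > 0), one per minimum.
#' @param widths Gaussian widths (lengths), one per minimum. Minima must be
#'   pairwise separated by more than twice the largest width.
#' @param wall_k Wall stiffness (energy / length^2).
#' @return A 2D `potential_surface`.
#' @export
make_three_state_landscape <- function(minima_positions, depths, widths,
                                       wall_k = 2) {
  if (is.list(minima_positions))
    minima_positions <- do.call(rbind, minima_positions)
  minima_positions <- as.matrix(minima_positions)
  nmin <- nrow(minima_positions)
  if (nmin < 2L) stop_invalid("need at least 2 minima")
  if (ncol(minima_positions) != 2L) stop_invalid("minima must be 2D points")
  depths <- rep_len(as.numeric(depths), nmin)
  widths <- rep_len(as.numeric(widths), nmin)
  if (any(depths <= 0)) stop_invalid("all depths must be > 0")
  if (any(widths <= 0)) stop_invalid("all widths must be > 0")
  dmin <- min(dist(minima_positions))
  if (dmin <= 2 * max(widths))
    stop_invalid("overlapping minima: pairwise separation ", format(dmin),
                 " is not > 2 x max width ", format(2 * max(widths)))
  pad <- 3 * max(widths)
  lo <- apply(minima_positions, 2, min) - pad
  hi <- apply(minima_positions, 2, max) + pad
  pars <- c(nmin,
            as.vector(t(cbind(minima_positions, depths, widths))),
            lo[1], hi[1], lo[2], hi[2], wall_k)
  bounds <- rbind(lo - 2, hi + 2)
  surf <- new_potential_surface(
    2L, energy = NULL, gradient = NULL,
    domain_bounds = bounds, name = "three_state",
    kind = "three_state", pars = pars,
    minima = minima_positions)
  surf$energy <- function(x) as.numeric(surface_energy(surf, matrix(x, 1)))
  surf$gradient <- function(x) as.numeric(surface_gradient(surf, matrix(x, 1)))
  surf
}

#' Potential of mean force by dense numerical quadrature
#'
#' Ground-truth PMF \eqn{F(A) = -\beta^{-1} \ln \int e^{-\beta V(r)}
#' \delta(A(r) - A)\, dr}, evaluated by quadrature over the surface domain
#' with the delta function realised as histogram binning on the same grid
#' convention used by [reweight_profile()], so oracle and estimate share
#' the binning bias. The global minimum over included bins is anchored to
#' zero.
#'
#' @param surface A `potential_surface`.
#' @param coordinate_fn Function mapping a point matrix (rows = points) to
#'   reaction-coordinate values; default takes the first coordinate.
#' @param beta Inverse temperature (1/energy).
#' @param bin_width Reaction-coordinate bin width.
#' @param n_grid Quadrature points per dimension (>= 200).
#' @return A `free_energy_profile` (counts hold quadrature weights and the
#'   occupancy cutoff is disabled).
#' @export
analytic_pmf <- function(surface, coordinate_fn = NULL, beta = 1,
                         bin_width = 1, n_grid = 601L) {
  check_scalar(beta, "beta", positive = TRUE)
  check_scalar(bin_width, "bin_width", positive = TRUE)
  n_grid <- as.integer(n_grid)
  if (n_grid < 200L) stop_invalid("n_grid must be >= 200 per dimension")
  d <- surface$dimensionality
  # bin-aligned midpoint rule: every histogram bin is tiled by the same
  # number of quadrature cells, so no bin is over- or under-represented
  # and symmetric surfaces yield exactly symmetric profiles
  axes <- lapply(seq_len(d), function(j) {
    lo <- surface$domain_bounds[1, j]
    hi <- surface$domain_bounds[2, j]
    b0 <- floor(lo / bin_width)
    b1 <- ceiling(hi / bin_width)
    m <- max(1L, ceiling(n_grid / (b1 - b0)))
    h <- bin_width / m
    seq(b0 * bin_width + h / 2, b1 * bin_width - h / 2,
        length.out = (b1 - b0) * m)
  })
  pts <- as.matrix(do.call(expand.grid, axes))
  colnames(pts) <- NULL
  v <- surface_energy(surface, pts)
  w <- exp(-beta * (v - min(v)))
  if (!all(is.finite(w))) stop("unnormalizable integrand: overflow in exp(-beta V)")
  a <- if (is.null(coordinate_fn)) pts[, 1] else coordinate_fn(pts)
  a <- as.matrix(a)
  profile_from_weights(a, w, bin_width = bin_width, beta = beta,
                       cutoff_frames = 0, weight_total = sum(w))
}
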