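# Independent oracles used across the suite.

# Pure-R re-evaluation of the bead-model total energy, independent of the
# compiled kernel and of the component classification.
bead_energy_R <- function(model, x) {
  v <- 0
  b <- model$bonds
  for (k in seq_len(nrow(b))) {
    r <- sqrt(sum((x[b[k, 1] + 1, ] - x[b[k, 2] + 1, ])^2))
    v <- v + 0.5 * model$bond_k[k] * (r - model$bond_r0[k])^2
  }
  for (q in seq_along(model$pair_i)) {
    i <- model$pair_i[q] + 1L; j <- model$pair_j[q] + 1L
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    rc <- model$rep_rc[q]
    if (r < rc) v <- v + model$rep_A[q] * (1 - (r / rc)^2)^2
    if (model$att_eps[q] > 0)
      v <- v - model$att_eps[q] *
        exp(-(r - model$att_r0[q])^2 / (2 * model$att_w[q]^2))
  }
  for (i in seq_along(model$type)) {
    if (model$type[i] == 1L) next
    r <- sqrt(sum(x[i, ]^2))
    if (r > model$wall_R) v <- v + 0.5 * model$wall_k * (r - model$wall_R)^2
  }
  v
}

# proper random rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

euler_rot <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# brute-force minimum RMSD over rotations: coarse Euler-angle grid then
# Nelder-Mead refinement of the best grid cell (independent of Kabsch)
rmsd_grid_oracle <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(ang) {
    R <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  }
  grid <- seq(0, 2 * pi, by = pi / 12)
  bgrid <- seq(0, pi, by = pi / 12)
  best <- c(0, 0, 0); bval <- Inf
  for (a in grid) for (b in bgrid) for (cc in grid) {
    v <- obj(c(a, b, cc))
    if (v < bval) { bval <- v; best <- c(a, b, cc) }
  }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  opt$value
}

# Boltzmann occupancy of each basin by dense quadrature: grid points are
# assigned to the nearest planted minimum
basin_occupancy <- function(surface, beta = 1, n_grid = 401L) {
  axes <- lapply(seq_len(surface$dimensionality), function(j)
    seq(surface$domain_bounds[1, j], surface$domain_bounds[2, j],
        length.out = n_grid))
  pts <- as.matrix(do.call(expand.grid, axes))
  w <- exp(-beta * surface_energy(surface, pts))
  ctr <- surface$minima
  d2 <- sapply(seq_len(nrow(ctr)), function(m)
    rowSums(sweep(pts, 2, ctr[m, ])^2))
  assign <- max.col(-d2)
  occ <- vapply(seq_len(nrow(ctr)), function(m) sum(w[assign == m]), 0.0)
  occ / sum(occ)
}

# Boltzmann occupancy of x-axis slabs (split at basin midpoints) by
# direct 2D quadrature on its own grid
basin_occupancy_x <- function(surface, beta = 1, splits, n_grid = 801L) {
  axes <- lapply(1:2, function(j) {
    lo <- surface$domain_bounds[1, j]; hi <- surface$domain_bounds[2, j]
    h <- (hi - lo) / n_grid
    seq(lo + h / 2, hi - h / 2, length.out = n_grid)
  })
  pts <- as.matrix(do.call(expand.grid, axes))
  w <- exp(-beta * surface_energy(surface, pts))
  occ <- vapply(seq_len(length(splits) - 1L), function(b)
    sum(w[pts[, 1] >= splits[b] & pts[, 1] < splits[b + 1]]), 0.0)
  occ / sum(occ)
}

# small deterministic frame set: three well-separated rigid conformers,
# each observed several times under random rigid motion plus tiny jitter
planted_conformers <- function(n_each = 8, jitter = 0.01, seed = 42) {
  set.seed(seed)
  base <- list(
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0.5, 1, 1), c(0, 0.5, 1.5)),
    rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0.2, 0), c(3, 0.4, 0.2), c(4, 0.2, 0)),
    rbind(c(0, 0, 0), c(0.4, 0.9, 0), c(1.3, 1, 0.4), c(1.5, 0.1, 0.8),
          c(0.7, -0.5, 1.2)))
  frames <- array(NA_real_, c(3 * n_each, 5, 3))
  truth <- integer(3 * n_each)
  k <- 0L
  for (m in 1:3) for (r in seq_len(n_each)) {
    k <- k + 1L
    frames[k, , ] <- base[[m]] %*% random_rotation() +
      matrix(rep(rnorm(3, sd = 2), each = 5), 5, 3) +
      matrix(rnorm(15, sd = jitter), 5, 3)
    truth[k] <- m
  }
  list(frames = frames, truth = truth, base = base)
}

# agreement of two partitions up to label permutation
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
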