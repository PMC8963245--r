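# Conformational analysis: reaction-coordinate extraction, least-squares
# superposition RMSD, hierarchical agglomerative clustering with medoid
# representatives and per-cluster reweighted free energies, low-energy
# state identification and activation-state classification.

#' Reaction-coordinate distance specification
#'
#' Names two bead/atom selections whose (single-atom or centroid)
#' separation defines a reaction coordinate, e.g. the intracellular
#' TM3-TM6 Calpha pair that indexes GPCR activation, or side-chain charge
#' centers for a salt bridge.
#'
#' @param label Text label.
#' @param selection_a,selection_b Non-empty, disjoint index vectors.
#' @param mode `"single-atom"` (selections of length 1) or `"centroid"`.
#' @return A `distance_spec`.
#' @export
distance_spec <- function(label, selection_a, selection_b,
                          mode = c("single-atom", "centroid")) {
  mode <- match.arg(mode)
  selection_a <- as.integer(selection_a)
  selection_b <- as.integer(selection_b)
  if (length(selection_a) == 0L || length(selection_b) == 0L)
    stop_invalid("selections must be non-empty")
  if (length(intersect(selection_a, selection_b)) > 0L)
    stop_invalid("selections must be disjoint")
  if (mode == "single-atom" &&
      (length(selection_a) != 1L || length(selection_b) != 1L))
    stop_invalid("single-atom mode needs length-1 selections")
  structure(list(label = label, selection_a = selection_a,
                 selection_b = selection_b, mode = mode),
            class = "distance_spec")
}

#' Distance reaction-coordinate series
#'
#' Euclidean distance between the two selection points (atoms or
#' centroids) per frame.
#'
#' @param frames A `gamd_trajectory` of a bead system, or an array
#'   `frames x beads x 3`.
#' @param spec A [distance_spec()].
#' @return Numeric vector, one distance per frame.
#' @export
distance_series <- function(frames, spec) {
  fr <- trajectory_frames(frames)
  stopifnot(length(dim(fr)) == 3L)
  nb <- dim(fr)[2]
  bad <- c(spec$selection_a, spec$selection_b)
  bad <- bad[bad < 1L | bad > nb]
  if (length(bad))
    stop("selection error: index ", bad[1], " out of range for frames with ",
         nb, " beads")
  pt <- function(sel) {
    if (length(sel) == 1L) fr[, sel, , drop = TRUE]
    else apply(fr[, sel, , drop = FALSE], c(1, 3), mean)
  }
  a <- pt(spec$selection_a)
  b <- pt(spec$selection_b)
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  sqrt(rowSums((a - b)^2))
}

#' Salt-bridge indicator
#'
#' Convenience flag: a charge-center distance below `cutoff` (default 5
#' length units) counts as a formed salt bridge, larger as broken.
#'
#' @param d Distance series.
#' @param cutoff Formation cutoff.
#' @return Logical vector.
#' @export
salt_bridge_formed <- function(d, cutoff = 5) d < cutoff

# ---- superposition RMSD -------------------------------------------------

kabsch_rotation <- function(P, Q) {
  # optimal rotation R (proper) such that P %*% R best matches Q;
  # both inputs already centered
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' RMSD after optimal rigid-body superposition
#'
#' Least-squares (Kabsch) superposition of `frame` onto `reference` over
#' the index subset, then the root-mean-square deviation over that
#' subset. Symmetric in its two arguments and zero for any
#' rotated-plus-translated copy.
#'
#' @param frame,reference Coordinate matrices `n x 3`.
#' @param index_subset Indices to superpose and measure over (default
#'   all); needs >= 3 non-collinear points.
#' @return RMSD (length units).
#' @export
rmsd_after_superposition <- function(frame, reference, index_subset = NULL) {
  frame <- as.matrix(frame); reference <- as.matrix(reference)
  idx <- index_subset %||% seq_len(nrow(frame))
  P <- frame[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  if (nrow(P) < 3L)
    stop("superposition degeneracy: need at least 3 points")
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  if (svd(Pc)$d[2] < 1e-9 * max(svd(Pc)$d[1], 1) ||
      svd(Qc)$d[2] < 1e-9 * max(svd(Qc)$d[1], 1))
    stop("superposition degeneracy: collinear point set")
  R <- kabsch_rotation(Pc, Qc)
  sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
}

# ---- hierarchical clustering -------------------------------------------

#' Hierarchical agglomerative clustering of frames by pairwise RMSD
#'
#' Average-linkage agglomeration on the dense pairwise
#' superposition-RMSD matrix, cut at `n_clusters`. Clusters are relabeled
#' by descending population (cluster 1 is top-ranked; population ties
#' keep the original merge order), and each cluster's representative is
#' its medoid (minimal mean RMSD to the other members, ties to the lowest
#' frame index). Deterministic for a given input order.
#'
#' @param frames A `gamd_trajectory` or array `frames x beads x 3`.
#' @param reference Optional reference structure; representatives get an
#'   `rmsd_to_reference` column in the summary when provided.
#' @param n_clusters Number of clusters (1..frame count).
#' @param index_subset Bead indices used for the RMSD (default all).
#' @param stride Keep every `stride`-th frame before clustering.
#' @return A `cluster_result` with `assignments` (per kept frame),
#'   `representatives`, `populations`, `delta_f` (NA until
#'   [cluster_free_energies()]), `linkage`, `frame_index`.
#' @export
hierarchical_cluster <- function(frames, reference = NULL, n_clusters,
                                 index_subset = NULL, stride = 1L) {
  fr <- trajectory_frames(frames)
  stopifnot(length(dim(fr)) == 3L)
  keep <- seq(1L, dim(fr)[1], by = as.integer(stride))
  fr <- fr[keep, , , drop = FALSE]
  n <- dim(fr)[1]
  check_scalar(n_clusters, "n_clusters", positive = TRUE, integerish = TRUE)
  if (n_clusters > n)
    stop_invalid("n_clusters (", n_clusters, ") exceeds frame count (", n, ")")
  if (n < 2L) stop_invalid("too few frames to cluster")

  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <-
        rmsd_after_superposition(fr[i, , ], fr[j, , ], index_subset)
    }
  }
  hc <- hclust(as.dist(D), method = "average")
  raw <- cutree(hc, k = n_clusters)

  pops <- tabulate(raw, nbins = n_clusters)
  ord <- order(-pops, seq_len(n_clusters)) # descending population, stable
  relabel <- integer(n_clusters)
  relabel[ord] <- seq_len(n_clusters)
  assignments <- relabel[raw]
  populations <- pops[ord]

  representatives <- vapply(seq_len(n_clusters), function(cl) {
    members <- which(assignments == cl)
    if (length(members) == 1L) return(members)
    msum <- rowSums(D[members, members, drop = FALSE])
    members[which.min(msum)]
  }, 0L)

  res <- structure(list(assignments = assignments,
                        representatives = representatives,
                        populations = populations,
                        delta_f = rep(NA_real_, n_clusters),
                        linkage = "average",
                        frame_index = keep),
                   class = "cluster_result")
  if (!is.null(reference)) {
    res$rmsd_to_reference <- vapply(representatives, function(i)
      rmsd_after_superposition(fr[i, , ], as.matrix(reference),
                               index_subset), 0.0)
  }
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster result: %d clusters over %d frames (%s linkage)\n",
              length(x$populations), length(x$assignments), x$linkage))
  df <- data.frame(cluster = seq_along(x$populations),
                   population = x$populations,
                   representative = x$representatives,
                   delta_f = round(x$delta_f, 4))
  print(utils::head(df, 10), row.names = FALSE)
  invisible(x)
}

#' Reweighted free energies per structural cluster
#'
#' Treats clusters as bins of the reweighting formula: each cluster with
#' population >= `cutoff_frames` gets
#' \eqn{\Delta F = -\beta^{-1}\ln(pop/N) - C_1 - \beta C_2 / 2}, anchored
#' so the minimum included value is 0; smaller clusters are excluded (NA).
#'
#' @param result A `cluster_result`.
#' @param dv Boost potential per clustered frame (same length and order
#'   as `result$assignments`).
#' @param beta Inverse temperature.
#' @param cutoff_frames Minimum cluster population (default 500).
#' @return The `cluster_result` with `delta_f` filled in.
#' @export
cluster_free_energies <- function(result, dv, beta = 1,
                                  cutoff_frames = 500) {
  stopifnot(inherits(result, "cluster_result"))
  dv <- as.numeric(dv)
  if (length(dv) != length(result$assignments))
    stop("input shape: dv must have one value per clustered frame")
  n <- length(dv)
  k <- length(result$populations)
  f <- rep(NA_real_, k)
  for (cl in seq_len(k)) {
    pop <- result$populations[cl]
    if (pop < max(cutoff_frames, 2)) next
    z <- dv[result$assignments == cl]
    cc <- cumulants(z)
    f[cl] <- -log(pop / n) / beta - cc["c1"] - beta * cc["c2"] / 2
  }
  if (!any(is.finite(f)))
    stop("empty profile: no cluster meets the occupancy cutoff of ",
         cutoff_frames, " frames")
  result$delta_f <- f - min(f, na.rm = TRUE)
  result
}

# ---- minima and state classification -----------------------------------

#' Local minima of a free-energy profile
#'
#' Local minima over included bins (two neighbours in 1D, 4-neighbourhood
#' in 2D; excluded bins do not constrain), retained when no more than
#' `depth_threshold` above the global minimum. Plateau ties are resolved
#' to the lowest-index bin center. Sorted by free energy.
#'
#' @param profile A `free_energy_profile`.
#' @param depth_threshold Retention window above the global minimum
#'   (energy; default 3 kT).
#' @return Data frame with position column(s) and `f_value`.
#' @export
find_minima <- function(profile, depth_threshold = 3) {
  stopifnot(inherits(profile, "free_energy_profile"))
  f <- profile$f
  d <- profile$dim
  dims <- if (d == 1L) length(f) else dim(f)
  is_min <- array(FALSE, dim = dims)
  getf <- function(i, j = NULL) {
    if (d == 1L) { if (i < 1 || i > dims[1]) return(Inf); v <- f[i] }
    else { if (i < 1 || i > dims[1] || j < 1 || j > dims[2]) return(Inf)
           v <- f[i, j] }
    if (is.na(v)) Inf else v
  }
  if (d == 1L) {
    for (i in seq_len(dims[1])) {
      if (is.na(f[i])) next
      is_min[i] <- f[i] <= getf(i - 1) && f[i] <= getf(i + 1)
    }
  } else {
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
      if (is.na(f[i, j])) next
      is_min[i, j] <- f[i, j] <= getf(i - 1, j) && f[i, j] <= getf(i + 1, j) &&
        f[i, j] <= getf(i, j - 1) && f[i, j] <= getf(i, j + 1)
    }
  }
  idx <- which(is_min, arr.ind = d == 2L)
  if (length(idx) == 0L) return(minima_frame(profile, integer(0)))
  if (d == 1L) {
    fv <- f[idx]
    # plateau ties: keep the lowest-index bin of each contiguous run
    keep <- !(seq_along(idx) > 1 & c(FALSE, diff(idx) == 1 & diff(fv) == 0))
    idx <- idx[keep]; fv <- fv[keep]
  } else {
    fv <- f[idx]
    o <- order(fv, idx[, 1], idx[, 2])
    idx <- idx[o, , drop = FALSE]; fv <- fv[o]
    # drop plateau duplicates adjacent to an already-kept equal minimum
    kept <- rep(TRUE, length(fv))
    for (a in seq_along(fv)) {
      if (!kept[a]) next
      for (b in seq_along(fv)) {
        if (a == b || !kept[b]) next
        if (fv[a] == fv[b] &&
            sum(abs(idx[a, ] - idx[b, ])) == 1L &&
            (idx[b, 1] > idx[a, 1] ||
             (idx[b, 1] == idx[a, 1] && idx[b, 2] > idx[a, 2])))
          kept[b] <- FALSE
      }
    }
    idx <- idx[kept, , drop = FALSE]; fv <- fv[kept]
  }
  sel <- fv <= min(f, na.rm = TRUE) + depth_threshold
  out <- minima_frame(profile, idx, fv, sel)
  out[order(out$f_value), , drop = FALSE]
}

minima_frame <- function(profile, idx, fv = numeric(0), sel = TRUE) {
  d <- profile$dim
  if (length(idx) == 0L) {
    return(if (d == 1L) data.frame(position = numeric(0), f_value = numeric(0))
           else data.frame(x = numeric(0), y = numeric(0),
                           f_value = numeric(0)))
  }
  if (d == 1L) {
    df <- data.frame(position = profile$centers[[1]][idx], f_value = fv)
  } else {
    df <- data.frame(x = profile$centers[[1]][idx[, 1]],
                     y = profile$centers[[2]][idx[, 2]], f_value = fv)
  }
  df[sel, , drop = FALSE]
}

#' Activation-coordinate state bands
#'
#' Ordered, disjoint, closed-open intervals covering the coordinate
#' range, each named for a conformational state. The defaults separate
#' the Inactive (about 8-9), Intermediate (about 10.7-11.1) and Active
#' (about 13-15.3) wells reported along a GPCR TM3-TM6 activation
#' distance.
#'
#' @param state_names State labels, in coordinate order.
#' @param breaks Interval breakpoints, length `length(state_names) + 1`,
#'   strictly increasing (last may be `Inf`).
#' @return A `state_bands` data frame with columns state, lo, hi.
#' @export
state_bands <- function(state_names, breaks) {
  if (length(breaks) != length(state_names) + 1L)
    stop_invalid("breaks must have one more element than state_names")
  if (any(diff(breaks) <= 0)) stop_invalid("breaks must be increasing")
  structure(data.frame(state = as.character(state_names),
                       lo = breaks[-length(breaks)], hi = breaks[-1]),
            class = c("state_bands", "data.frame"))
}

#' @rdname state_bands
#' @export
default_state_bands <- function() {
  state_bands(c("Inactive", "Intermediate", "Active"), c(0, 10, 13, Inf))
}

#' Classify free-energy minima into conformational states
#'
#' Labels each minimum by the band whose closed-open interval `[lo, hi)`
#' contains its activation-coordinate value (the first position column);
#' minima outside every band get `"unassigned"`. A value exactly on a
#' band edge belongs to the upper band.
#'
#' @param minima Data frame from [find_minima()].
#' @param bands A [state_bands()] table.
#' @return The minima with a `state` column prepended.
#' @export
classify_states <- function(minima, bands = default_state_bands()) {
  stopifnot(inherits(bands, "state_bands"))
  coordv <- minima[[1]]
  state <- vapply(coordv, function(v) {
    hit <- which(v >= bands$lo & v < bands$hi)
    if (length(hit)) bands$state[hit[1]] else "unassigned"
  }, "")
  cbind(data.frame(state = state), minima)
}
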