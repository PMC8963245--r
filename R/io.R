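# File formats: multi-frame XYZ for coordinates, '#'-headed TSV sidecars
# for per-frame energies ("weights files"), a 3-column legacy weights
# dialect, TSV profile and sample exports. All floats are written %.6f so
# round-trips are stable.

fmt6 <- function(x) sprintf("%.6f", x)

#' Write / read a multi-frame XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' `element x y z` record per bead, repeated per frame. Bead classes are
#' encoded as element symbols (peptide C, receptor O, environment N).
#'
#' @param coords Array `frames x beads x 3` (or a single `beads x 3`
#'   matrix).
#' @param elements Element symbol per bead.
#' @param path Output file.
#' @param comment Comment-line prefix (frame index is appended).
#' @export
write_xyz <- function(coords, elements, path, comment = "frame") {
  if (length(dim(coords)) == 2L)
    coords <- array(coords, c(1L, dim(coords)))
  nfr <- dim(coords)[1]; nb <- dim(coords)[2]
  stopifnot(length(elements) == nb)
  con <- file(path, "w")
  on.exit(close(con))
  for (fidx in seq_len(nfr)) {
    writeLines(c(as.character(nb), paste(comment, fidx)), con)
    writeLines(paste(elements, fmt6(coords[fidx, , 1]),
                     fmt6(coords[fidx, , 2]), fmt6(coords[fidx, , 3])), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @return `read_xyz`: list with `coords` (frames x beads x 3) and
#'   `elements`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  elements <- NULL
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("malformed XYZ at line ", i, ": expected atom-count line")
    nb <- as.integer(lines[i])
    if (i + 1L + nb > length(lines))
      stop("malformed XYZ at line ", i, ": ", nb,
           " atoms declared but file ends early")
    rec <- lines[(i + 2L):(i + 1L + nb)]
    parts <- strsplit(trimws(rec), "\\s+")
    if (any(lengths(parts) != 4L))
      stop("malformed XYZ at line ", i + 1L + which(lengths(parts) != 4L)[1],
           ": expected 'element x y z'")
    el <- vapply(parts, `[[`, "", 1L)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nb
  }
  coords <- array(NA_real_, c(length(frames), length(elements), 3))
  for (fidx in seq_along(frames)) coords[fidx, , ] <- frames[[fidx]]
  list(coords = coords, elements = elements)
}

bead_elements <- function(system) {
  c("C", "O", "N")[system$type + 1L]
}

sidecar_cols <- c("step", "time", "v_total", "v_peptide", "v_rest",
                  "dv_peptide", "dv_rest", "dv_total")

#' Write / read a trajectory (XYZ + energy sidecar)
#'
#' `<prefix>.xyz` holds coordinates; `<prefix>_energies.tsv` is the
#' tab-separated sidecar `step time v_total v_peptide v_rest dv_peptide
#' dv_rest dv_total` with a `#`-prefixed header — the weights file that
#' reweighting consumes.
#'
#' @param traj A `gamd_trajectory`.
#' @param prefix Output path prefix.
#' @param system The system the trajectory came from (for bead element
#'   symbols); surfaces need none.
#' @export
write_trajectory <- function(traj, prefix, system = NULL) {
  coords <- trajectory_frames(traj)
  if (length(dim(coords)) == 2L) { # surface: pad to 3D bead-like records
    nfr <- nrow(coords)
    arr <- array(0, c(nfr, 1L, 3L))
    arr[, 1, seq_len(ncol(coords))] <- coords
    coords <- arr
    elements <- "C"
  } else {
    elements <- if (!is.null(system)) bead_elements(system)
      else rep("C", dim(coords)[2])
  }
  write_xyz(coords, elements, paste0(prefix, ".xyz"))
  df <- as.data.frame(traj)[, sidecar_cols]
  con <- file(paste0(prefix, "_energies.tsv"), "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(sidecar_cols, collapse = "\t")), con)
  body <- apply(cbind(df$step, sapply(df[, -1], fmt6)), 1, paste,
                collapse = "\t")
  writeLines(body, con)
  invisible(prefix)
}

#' @rdname write_trajectory
#' @return `read_trajectory`: a `gamd_trajectory` with coordinates
#'   attached.
#' @export
read_trajectory <- function(prefix) {
  xyz <- read_xyz(paste0(prefix, ".xyz"))
  df <- read_sidecar(paste0(prefix, "_energies.tsv"))
  if (nrow(df) != dim(xyz$coords)[1])
    stop("trajectory consistency error: sidecar has ", nrow(df),
         " rows but XYZ has ", dim(xyz$coords)[1], " frames")
  attr(df, "coords") <- xyz$coords
  attr(df, "system_kind") <- "beads"
  attr(df, "elements") <- xyz$elements
  class(df) <- c("gamd_trajectory", "data.frame")
  df
}

#' Read a '#'-headed TSV energy sidecar
#'
#' @param path Sidecar path.
#' @return Data frame with the header's columns.
#' @export
read_sidecar <- function(path) {
  header <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#\\s*", "", header), "\t")[[1]]
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = cols)
  df
}

#' Export the legacy 3-column weights dialect
#'
#' Row i holds `dv_i  beta*dv_i  step_i` (tab-separated), the columnar
#' form consumed by PyReweighting-style reweighting tools.
#'
#' @param traj A `gamd_trajectory` (its `dv_total` and `step` are used).
#' @param path Output file.
#' @param beta Inverse temperature.
#' @export
write_weights_legacy <- function(traj, path, beta = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(c("dv", "beta_dv", "timestep"),
                                collapse = "\t")), con)
  writeLines(paste(fmt6(traj$dv_total), fmt6(beta * traj$dv_total),
                   traj$step, sep = "\t"), con)
  invisible(path)
}

#' Write / read synthetic weighted samples as TSV
#'
#' Two columns `coord deltaV` (three with a second coordinate), with a
#' `#`-prefixed header line.
#'
#' @param sample A `synthetic_weighted_sample` (or list with
#'   `coordinate_values`, `boost_values`).
#' @param path File path.
#' @export
write_samples_tsv <- function(sample, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coord\tdeltaV", con)
  writeLines(paste(fmt6(sample$coordinate_values),
                   fmt6(sample$boost_values), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_samples_tsv
#' @return `read_samples_tsv`: list with `coordinate_values` (vector or
#'   2-column matrix) and `boost_values`.
#' @export
read_samples_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#")
  nc <- ncol(df)
  if (!nc %in% c(2L, 3L))
    stop("samples TSV must have 2 or 3 columns, found ", nc)
  list(coordinate_values = if (nc == 2L) df[[1]] else as.matrix(df[, 1:2]),
       boost_values = df[[nc]])
}

#' Write a free-energy profile as TSV
#'
#' 1D: `bin_center F counts c1 c2`; 2D (long format):
#' `x_center y_center F counts`. Excluded bins are written `NA`.
#'
#' @param profile A `free_energy_profile`.
#' @param path Output file.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- as.data.frame(profile)
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (j in which(num))
    out[[j]] <- ifelse(is.na(df[[j]]), "NA", fmt6(df[[j]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
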