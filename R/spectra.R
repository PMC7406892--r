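#' The canonical tear-SERS wavenumber grid
#'
#' The full spectral window used throughout the pipeline: 400 to 1900 cm-1
#' inclusive at 2 cm-1 spacing (751 points), matching the spectral
#' resolution of the acquisition setup the package models.
#'
#' @return Numeric vector of wavenumbers (cm-1).
#' @export
#' @examples
#' length(canonical_grid())
canonical_grid <- function() {
  seq(400, 1900, by = 2)
}

#' Build a tidy spectra table
#'
#' `sers_spectra` is the unit every pipeline stage consumes and produces: a
#' long tibble with one row per (spectrum, wavenumber) pair and columns
#' `subject_id`, `replicate_id`, `class_label`, `wavenumber`, `intensity`.
#' All member spectra must share one common, strictly increasing, uniformly
#' spaced wavenumber grid. A `provenance` attribute records the ordered
#' processing steps applied so far; stages only ever append to it.
#'
#' @param x A data frame with columns `wavenumber` and `intensity`, plus
#'   optional `subject_id`, `replicate_id`, `class_label`. Missing identity
#'   columns are filled with defaults (`"S1"`, `"r1"`, `"UNKNOWN"`).
#' @param provenance Character vector of processing-step tags.
#' @return A `sers_spectra` tibble.
#' @export
#' @examples
#' s <- as_spectra(data.frame(wavenumber = canonical_grid(),
#'                            intensity = rnorm(751)))
#' provenance(s)
as_spectra <- function(x, provenance = character()) {
  stopifnot(is.data.frame(x))
  if (!all(c("wavenumber", "intensity") %in% names(x))) {
    abort("`x` must have columns `wavenumber` and `intensity`.")
  }
  x <- as_tibble(x)
  if (!"subject_id" %in% names(x)) x$subject_id <- "S1"
  if (!"replicate_id" %in% names(x)) x$replicate_id <- "r1"
  if (!"class_label" %in% names(x)) x$class_label <- "UNKNOWN"
  x$subject_id <- as.character(x$subject_id)
  x$replicate_id <- as.character(x$replicate_id)
  x$class_label <- validate_class_labels(x$class_label)
  x <- x[, c("subject_id", "replicate_id", "class_label", "wavenumber", "intensity")]
  out <- new_spectra(x, provenance = provenance)
  validate_spectra(out)
}

new_spectra <- function(x, provenance = character()) {
  structure(x,
    provenance = as.character(provenance),
    class = c("sers_spectra", class(as_tibble(x)))
  )
}

validate_class_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .CLASS_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown class label(s): %s. Allowed labels: %s.",
      paste(bad, collapse = ", "), paste(.CLASS_LEVELS, collapse = ", ")
    ))
  }
  factor(labels, levels = .CLASS_LEVELS)
}

#' Validate a spectra table
#'
#' Checks the container invariants: a shared grid across all member spectra,
#' strictly increasing wavenumbers with at least 16 points and uniform
#' spacing (within 1% relative tolerance), and finite intensities.
#'
#' @param s A `sers_spectra` object.
#' @return `s`, invisibly unchanged, or an error.
#' @export
validate_spectra <- function(s) {
  grid <- spectra_grid(s)
  if (length(grid) < 16) abort("Spectra must have at least 16 grid points.")
  d <- diff(grid)
  if (any(d <= 0)) abort("Wavenumbers must be strictly increasing with no duplicates.")
  if ((max(d) - min(d)) / mean(d) > 0.01) {
    abort("Wavenumber spacing must be uniform within 1% relative tolerance.")
  }
  if (!all(is.finite(s$intensity))) abort("Intensities must all be finite.")
  key <- paste(s$subject_id, s$replicate_id, sep = "\r")
  n_per <- table(key)
  if (length(unique(n_per)) != 1) {
    abort("All member spectra must share one common wavenumber grid.")
  }
  wn_ok <- tapply(s$wavenumber, key, function(w) identical(unname(w), unname(grid)))
  if (!all(unlist(wn_ok))) {
    abort("All member spectra must share one common wavenumber grid.")
  }
  cls <- tapply(as.character(s$class_label), key, function(x) length(unique(x)))
  if (any(unlist(cls) != 1)) abort("Each spectrum must carry a single class label.")
  s
}

#' @export
print.sers_spectra <- function(x, ...) {
  grid <- spectra_grid(x)
  n <- n_spectra(x)
  cls <- spectra_meta(x)$class_label
  cat(sprintf(
    "<sers_spectra: %d spectrum/spectra, %d points, %.6g..%.6g cm-1>\n",
    n, length(grid), min(grid), max(grid)
  ))
  if (n > 0) {
    cat("  classes:", paste(sprintf("%s=%d", names(table(droplevels(cls))),
      table(droplevels(cls))), collapse = " "), "\n")
  }
  if (length(provenance(x)) > 0) {
    cat("  provenance:", paste(provenance(x), collapse = " -> "), "\n")
  }
  NextMethod()
}

#' Processing provenance of a spectra table
#'
#' @param s A `sers_spectra` object.
#' @return Character vector of ordered step tags.
#' @export
provenance <- function(s) {
  as.character(attr(s, "provenance") %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

add_provenance <- function(s, tag) {
  attr(s, "provenance") <- c(provenance(s), tag)
  s
}

#' Shared wavenumber grid of a spectra table
#'
#' @param s A `sers_spectra` object (or compatible long data frame).
#' @return Numeric vector of wavenumbers.
#' @export
spectra_grid <- function(s) {
  first <- paste(s$subject_id[1], s$replicate_id[1], sep = "\r")
  key <- paste(s$subject_id, s$replicate_id, sep = "\r")
  s$wavenumber[key == first]
}

#' Number of member spectra
#' @param s A `sers_spectra` object.
#' @return Integer count of (subject, replicate) spectra.
#' @export
n_spectra <- function(s) {
  length(unique(paste(s$subject_id, s$replicate_id, sep = "\r")))
}

#' Per-spectrum metadata
#'
#' @param s A `sers_spectra` object.
#' @return A tibble with one row per spectrum: `subject_id`, `replicate_id`,
#'   `class_label`, in first-appearance order.
#' @export
spectra_meta <- function(s) {
  m <- tibble(
    subject_id = s$subject_id, replicate_id = s$replicate_id,
    class_label = s$class_label
  )
  m[!duplicated(paste(m$subject_id, m$replicate_id, sep = "\r")), ]
}

# Internal wide view: rows = spectra (in spectra_meta order), cols = grid.
spectra_matrix <- function(s) {
  grid <- spectra_grid(s)
  meta <- spectra_meta(s)
  key <- paste(s$subject_id, s$replicate_id, sep = "\r")
  mkey <- paste(meta$subject_id, meta$replicate_id, sep = "\r")
  m <- matrix(s$intensity[order(match(key, mkey))],
    nrow = nrow(meta), ncol = length(grid), byrow = TRUE
  )
  list(grid = grid, meta = meta, m = m)
}

# Inverse of spectra_matrix
matrix_to_spectra <- function(grid, meta, m, provenance = character()) {
  n <- nrow(meta)
  out <- tibble(
    subject_id = rep(meta$subject_id, each = length(grid)),
    replicate_id = rep(meta$replicate_id, each = length(grid)),
    class_label = rep(meta$class_label, each = length(grid)),
    wavenumber = rep(grid, times = n),
    intensity = as.vector(t(m))
  )
  new_spectra(out, provenance = provenance)
}

# Apply f (numeric grid intensities -> numeric) to every member spectrum.
map_spectra <- function(s, f, tag = NULL) {
  w <- spectra_matrix(s)
  w$m <- t(apply(w$m, 1, f))
  prov <- provenance(s)
  if (!is.null(tag)) prov <- c(prov, tag)
  matrix_to_spectra(w$grid, w$meta, w$m, provenance = prov)
}

#' Interpolate spectra onto a new wavenumber grid
#'
#' Linear interpolation of every member spectrum onto `grid`. The target
#' grid must lie inside the source wavenumber range; extrapolation is
#' refused. Exact for intensities that are affine functions of wavenumber.
#'
#' @param s A `sers_spectra` object.
#' @param grid Target wavenumber grid (strictly increasing, cm-1).
#' @return A `sers_spectra` on `grid`, with a `"resampled"` provenance tag
#'   (omitted when `grid` is identical to the current grid).
#' @export
resample_to_grid <- function(s, grid) {
  src <- spectra_grid(s)
  if (identical(unname(as.numeric(grid)), unname(as.numeric(src)))) {
    return(s)
  }
  if (min(grid) < min(src) || max(grid) > max(src)) {
    abort(sprintf(
      "Target grid [%g, %g] extends beyond the source range [%g, %g]; refusing to extrapolate.",
      min(grid), max(grid), min(src), max(src)
    ))
  }
  w <- spectra_matrix(s)
  m2 <- t(apply(w$m, 1, function(y) approx(src, y, xout = grid)$y))
  matrix_to_spectra(grid, w$meta, m2,
    provenance = c(provenance(s), sprintf("resampled:%g:%g:%g", min(grid), max(grid), grid[2] - grid[1]))
  )
}

#' Average replicate spectra within subjects
#'
#' Collapses each subject's replicate spectra to a single pointwise-mean
#' spectrum (replicate id `"avg"`). This is the subject-level unit the
#' class comparison and classification stages operate on.
#'
#' @param s A `sers_spectra` object.
#' @return A `sers_spectra` with one spectrum per subject.
#' @export
average_replicates <- function(s) {
  w <- spectra_matrix(s)
  subj <- unique(w$meta$subject_id)
  rows <- lapply(subj, function(id) {
    colMeans(w$m[w$meta$subject_id == id, , drop = FALSE])
  })
  meta <- w$meta[match(subj, w$meta$subject_id), ]
  meta$replicate_id <- "avg"
  matrix_to_spectra(w$grid, meta, do.call(rbind, rows),
    provenance = c(provenance(s), "replicates-averaged")
  )
}
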