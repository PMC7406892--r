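# The 22 fixed i-PCA windows (cm-1, closed intervals). Integer-adjacent
# boundaries partition the full 400-1900 window.
.INTERVALS_22 <- matrix(
  c(
    400, 455, 456, 553, 554, 706, 707, 755, 756, 834, 835, 907,
    908, 969, 970, 1031, 1032, 1092, 1093, 1136, 1137, 1201, 1202, 1307,
    1308, 1353, 1354, 1383, 1384, 1457, 1458, 1529, 1530, 1551, 1552, 1582,
    1583, 1639, 1640, 1712, 1713, 1800, 1801, 1900
  ),
  ncol = 2, byrow = TRUE
)

#' The 22 standard i-PCA spectral intervals
#'
#' The fixed, non-overlapping closed intervals that partition the
#' 400-1900 cm-1 window for interval PCA. A grid point `nu` belongs to
#' interval `[lo, hi]` iff `lo <= nu <= hi`; because adjacent boundaries
#' are consecutive integers, every point of the canonical 2 cm-1 grid falls
#' in exactly one interval.
#'
#' @return A tibble with columns `interval` (label `"lo-hi"`), `lo`, `hi`.
#' @export
#' @examples
#' nrow(default_intervals()) # 22
default_intervals <- function() {
  tibble(
    interval = sprintf("%d-%d", .INTERVALS_22[, 1], .INTERVALS_22[, 2]),
    lo = .INTERVALS_22[, 1], hi = .INTERVALS_22[, 2]
  )
}

#' The seven model intervals of the final classifier
#'
#' The subset of [default_intervals()] whose PC3-PC6 scores feed the
#' shipped naive-Bayes disease-class model.
#'
#' @return Character vector of seven interval labels.
#' @export
model_intervals <- function() {
  c(
    "456-553", "707-755", "1202-1307", "1308-1353",
    "1354-1383", "1552-1582", "1583-1639"
  )
}

# membership of grid points in an interval; half-open [lo, hi + 1) so that
# odd (non-integer-boundary) grids still partition cleanly
interval_points <- function(grid, lo, hi) {
  which(grid >= lo & grid < hi + 1)
}

#' Covariance-matrix principal component analysis of a spectral window
#'
#' Mean-centers the intensities restricted to the window's grid points and
#' eigendecomposes their covariance matrix. Loadings follow a deterministic
#' sign convention (each loading's largest-magnitude element is positive);
#' the number of components is `min(n_spectra - 1, n_points)`.
#'
#' @param s A `sers_spectra` set (>= 2 spectra).
#' @param interval `NULL` for the full window, an interval label from
#'   [default_intervals()], or `c(lo, hi)` in cm-1.
#' @return A `sers_pca` list: `mean_vector`, `loadings` (points x
#'   components), `explained_variance`, `scores` (spectra x components),
#'   `wavenumbers`, `meta`.
#' @export
spectra_pca <- function(s, interval = NULL) {
  w <- spectra_matrix(s)
  if (nrow(w$m) < 2) abort("PCA needs at least 2 spectra.")
  idx <- resolve_interval(w$grid, interval)
  if (length(idx) < 2) abort("The interval must contain at least 2 grid points.")
  x <- w$m[, idx, drop = FALSE]
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  n_comp <- min(nrow(x) - 1, ncol(x))
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  loadings <- pr$rotation[, seq_len(n_comp), drop = FALSE]
  scores <- pr$x[, seq_len(n_comp), drop = FALSE]
  # sign convention: largest-|.| element of each loading is positive
  for (j in seq_len(n_comp)) {
    piv <- which.max(abs(loadings[, j]))
    if (loadings[piv, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(
      mean_vector = mu,
      loadings = loadings,
      explained_variance = pr$sdev[seq_len(n_comp)]^2,
      scores = scores,
      wavenumbers = w$grid[idx],
      meta = w$meta
    ),
    class = "sers_pca"
  )
}

resolve_interval <- function(grid, interval) {
  if (is.null(interval)) {
    return(seq_along(grid))
  }
  if (is.character(interval)) {
    tab <- default_intervals()
    row <- match(interval, tab$interval)
    if (is.na(row)) abort(sprintf("Unknown interval label '%s'.", interval))
    return(interval_points(grid, tab$lo[row], tab$hi[row]))
  }
  stopifnot(is.numeric(interval), length(interval) == 2)
  interval_points(grid, interval[1], interval[2])
}

#' @export
print.sers_pca <- function(x, ...) {
  cat(sprintf(
    "<sers_pca: %d spectra, %d points (%g..%g cm-1), %d components>\n",
    nrow(x$scores), length(x$wavenumbers), min(x$wavenumbers),
    max(x$wavenumbers), ncol(x$scores)
  ))
  invisible(x)
}

#' @describeIn spectra_pca Eigenvalue summary, one row per component.
#' @param x A `sers_pca` object.
#' @param ... Unused.
#' @method tidy sers_pca
#' @export
tidy.sers_pca <- function(x, ...) {
  ev <- x$explained_variance
  tibble(
    component = seq_along(ev),
    variance = ev,
    prop_variance = if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  )
}

#' Pooled i-PCA score table
#'
#' Runs [spectra_pca()] on every interval and pools the first `n_pcs` score
#' columns of each into one feature table keyed `"lo-hi.PCk"`. Rows are the
#' member spectra (use subject-level averages), each carrying its class
#' label.
#'
#' @param s A `sers_spectra` set.
#' @param intervals An interval tibble (default [default_intervals()]).
#' @param n_pcs Scores kept per interval (default 7).
#' @return A `sers_scores` tibble: `subject_id`, `replicate_id`,
#'   `class_label`, then one numeric column per (interval, PC) feature.
#' @export
build_score_table <- function(s, intervals = default_intervals(), n_pcs = 7) {
  w <- spectra_matrix(s)
  feasible <- vapply(seq_len(nrow(intervals)), function(i) {
    min(nrow(w$m) - 1, length(interval_points(w$grid, intervals$lo[i], intervals$hi[i])))
  }, 1)
  if (any(feasible < n_pcs)) {
    worst <- which.min(feasible)
    abort(sprintf(
      "n_pcs = %d is infeasible: interval %s supports at most %d components.",
      n_pcs, intervals$interval[worst], feasible[worst]
    ))
  }
  out <- spectra_meta(s)
  for (i in seq_len(nrow(intervals))) {
    p <- spectra_pca(s, c(intervals$lo[i], intervals$hi[i]))
    sc <- p$scores[, seq_len(n_pcs), drop = FALSE]
    colnames(sc) <- sprintf("%s.PC%d", intervals$interval[i], seq_len(n_pcs))
    out <- cbind(out, as_tibble(sc))
  }
  out <- as_tibble(out)
  class(out) <- c("sers_scores", class(out))
  out
}

#' Feature keys for (interval, PC) pairs
#'
#' @param intervals Character vector of interval labels.
#' @param pcs Integer vector of principal component indices (1-based).
#' @return Character vector of feature keys `"lo-hi.PCk"`.
#' @export
#' @examples
#' length(feature_keys(model_intervals(), 3:6)) # 28
feature_keys <- function(intervals = model_intervals(), pcs = 3:6) {
  as.vector(t(outer(intervals, pcs, function(i, k) sprintf("%s.PC%d", i, k))))
}

score_feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "replicate_id", "class_label"))
}

#' Univariate screening of class-separating spectral regions
#'
#' For every wavenumber, computes the pooled-variance two-sample
#' t-statistic between each pair of classes and combines the pairs by the
#' maximum absolute value; ranks wavenumbers by that criterion and merges
#' contiguous top-quantile runs into candidate regions with positions and
#' widths.
#'
#' @param s A `sers_spectra` set with spectra from at least two classes.
#' @param top_frac Fraction of wavenumbers labelled top-ranked when merging
#'   regions (default 0.1).
#' @return A tibble `wavenumber`, `stat`, `rank` (1 = most separating) with
#'   attribute `regions`: a tibble `lo`, `hi`, `width`, `max_stat`.
#' @export
screen_features <- function(s, top_frac = 0.1) {
  w <- spectra_matrix(s)
  labs <- as.character(w$meta$class_label)
  classes <- unique(labs)
  if (length(classes) < 2) abort("Feature screening needs at least two classes.")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  stat <- rep(0, ncol(w$m))
  for (pr in pairs) {
    a <- w$m[labs == pr[1], , drop = FALSE]
    b <- w$m[labs == pr[2], , drop = FALSE]
    na <- nrow(a)
    nb <- nrow(b)
    if (na < 2 || nb < 2) next
    sp2 <- ((na - 1) * apply(a, 2, var) + (nb - 1) * apply(b, 2, var)) / (na + nb - 2)
    t_abs <- abs(colMeans(a) - colMeans(b)) / sqrt(pmax(sp2, .Machine$double.eps) * (1 / na + 1 / nb))
    stat <- pmax(stat, t_abs)
  }
  out <- tibble(
    wavenumber = w$grid, stat = stat,
    rank = rank(-stat, ties.method = "first")
  )
  thr <- quantile(stat, 1 - top_frac)
  top <- stat >= thr
  r <- rle(top)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  attr(out, "regions") <- tibble(
    lo = w$grid[starts[keep]], hi = w$grid[ends[keep]],
    width = w$grid[ends[keep]] - w$grid[starts[keep]],
    max_stat = vapply(which(keep), function(i) max(stat[starts[i]:ends[i]]), 1)
  ) |> arrange(desc(.data$max_stat))
  out
}
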