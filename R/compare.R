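#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: between/within mean-square F with
#' (k - 1, N - k) degrees of freedom and the upper-tail p value of the F
#' distribution. When the within-group variance is exactly zero but group
#' means differ, `F = Inf` and `p = 0` are returned with a note.
#'
#' @param groups A list of two or more numeric vectors, each with at least
#'   two values.
#' @return A one-row tibble: `F`, `p`, `df_between`, `df_within`, `note`.
#' @export
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("`groups` must be a list of at least two groups.")
  }
  n <- vapply(groups, length, 1L)
  if (any(n < 2)) abort("Every group needs at least two values.")
  k <- length(groups)
  N <- sum(n)
  means <- vapply(groups, mean, 1)
  grand <- sum(n * means) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- k - 1
  df2 <- N - k
  note <- NA_character_
  if (ss_within == 0) {
    if (ss_between == 0) {
      f <- 0
      p <- 1
    } else {
      f <- Inf
      p <- 0
      note <- "zero within-group variance"
    }
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  tibble(F = f, p = p, df_between = df1, df_within = df2, note = note)
}

# Vectorised two-or-more-group one-way ANOVA across the columns of per-group
# matrices (rows = subjects, cols = wavenumbers). Returns list(F, p).
anova_oneway_cols <- function(mats) {
  n <- vapply(mats, nrow, 1L)
  k <- length(mats)
  N <- sum(n)
  means <- vapply(mats, colMeans, numeric(ncol(mats[[1]])))
  grand <- as.vector(means %*% n) / N
  ss_between <- as.vector(((means - grand)^2) %*% n)
  ss_within <- Reduce(`+`, lapply(mats, function(m) {
    colSums((m - rep(colMeans(m), each = nrow(m)))^2)
  }))
  df1 <- k - 1
  df2 <- N - k
  f <- ifelse(ss_within > 0, (ss_between / df1) / (ss_within / df2),
    ifelse(ss_between > 0, Inf, 0)
  )
  p <- ifelse(is.finite(f), pf(f, df1, df2, lower.tail = FALSE),
    ifelse(f > 0, 0, 1)
  )
  p[ss_within == 0 & ss_between == 0] <- 1
  list(F = f, p = p)
}

#' Class-average spectrum with pointwise dispersion
#'
#' Pointwise mean and standard deviation over all spectra carrying a class
#' label, plus the summary relative dispersion (grid mean of `sd / |mean|`)
#' used to compare synthetic cohorts against the reported class dispersions.
#'
#' @param s A `sers_spectra` set (typically subject-level averages).
#' @param label Class label to average.
#' @return A tibble `wavenumber`, `mean`, `sd` with attributes
#'   `class_label`, `n` and `rel_dispersion`.
#' @export
class_average <- function(s, label) {
  w <- spectra_matrix(s)
  rows <- which(as.character(w$meta$class_label) == label)
  if (length(rows) < 2) {
    abort(sprintf("Need at least 2 spectra labelled '%s'; found %d.", label, length(rows)))
  }
  m <- w$m[rows, , drop = FALSE]
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  out <- tibble(wavenumber = w$grid, mean = mu, sd = sdv)
  attr(out, "class_label") <- label
  attr(out, "n") <- length(rows)
  attr(out, "rel_dispersion") <- mean(sdv / pmax(abs(mu), .Machine$double.eps))
  out
}

#' Per-wavenumber class difference map
#'
#' Reconstructs the difference-spectrum analysis between a disease class and
#' the control class: at every wavenumber, the difference of class means,
#' the reference dispersion band (+/- 0.68 standard deviations of the
#' reference class), a one-way ANOVA F test between the two groups, and a
#' joint significance flag requiring both `p < alpha` and the difference to
#' fall outside the dispersion band. Contiguous significant runs are
#' summarised as signed regions.
#'
#' @param s A `sers_spectra` set (one spectrum per subject; average
#'   replicates first).
#' @param target_label Disease class compared against the reference.
#' @param ref_label Reference class (default `"Ctr"`).
#' @param alpha Significance level (default 0.05).
#' @param band_k Half-width of the dispersion band in reference-class
#'   standard deviations (default 0.68).
#' @param p_adjust Optional multiple-testing correction across wavenumbers
#'   (`"none"`, default, or `"BH"`).
#' @return A `sers_diffmap` tibble: `wavenumber`, `delta`, `band_lo`,
#'   `band_hi`, `F`, `p`, `sig_anova`, `outside_band`, `significant`,
#'   `sign`; attributes `alpha`, `class_pair` and `regions` (a tibble of
#'   contiguous significant runs with their sign).
#' @export
difference_map <- function(s, target_label, ref_label = "Ctr", alpha = 0.05,
                           band_k = 0.68, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  w <- spectra_matrix(s)
  it <- which(as.character(w$meta$class_label) == target_label)
  ir <- which(as.character(w$meta$class_label) == ref_label)
  if (length(it) < 2 || length(ir) < 2) {
    abort("Both classes need at least two spectra.")
  }
  mt <- w$m[it, , drop = FALSE]
  mr <- w$m[ir, , drop = FALSE]
  delta <- colMeans(mt) - colMeans(mr)
  sd_ref <- apply(mr, 2, sd)
  an <- anova_oneway_cols(list(mt, mr))
  p <- if (p_adjust == "BH") stats::p.adjust(an$p, "BH") else an$p
  sig_anova <- p < alpha
  outside <- abs(delta) > band_k * sd_ref
  significant <- sig_anova & outside
  out <- tibble(
    wavenumber = w$grid, delta = delta,
    band_lo = -band_k * sd_ref, band_hi = band_k * sd_ref,
    F = an$F, p = p,
    sig_anova = sig_anova, outside_band = outside,
    significant = significant,
    sign = ifelse(significant, ifelse(delta > 0, "+", "-"), "")
  )
  attr(out, "alpha") <- alpha
  attr(out, "class_pair") <- sprintf("%s vs %s", target_label, ref_label)
  attr(out, "regions") <- significant_regions(w$grid, significant, delta)
  class(out) <- c("sers_diffmap", class(out))
  out
}

significant_regions <- function(grid, significant, delta) {
  key <- paste0(significant, ifelse(delta > 0, "+", "-"))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- grepl("^TRUE", r$values)
  tibble(
    lo = grid[starts[keep]], hi = grid[ends[keep]],
    sign = sub("^TRUE", "", r$values[keep]),
    n_points = r$lengths[keep]
  )
}

#' Contiguous significant regions of a difference map
#'
#' @param dm A `sers_diffmap` from [difference_map()].
#' @return A tibble with columns `lo`, `hi`, `sign`, `n_points`.
#' @export
diff_regions <- function(dm) {
  attr(dm, "regions")
}
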