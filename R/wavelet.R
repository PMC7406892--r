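# Bior6.8 biorthogonal spline filter bank (18 taps). Decomposition /
# reconstruction low- and high-pass coefficients; the analysis high-pass has
# vanishing moments up to the spline order, so smooth polynomial backgrounds
# land almost entirely in the approximation branch.
.BIOR68 <- list(
  dec_lo = c(
    0, 0.0019088317364812906, -0.0019142861290887667, -0.016990639867602342,
    0.01193456527972926, 0.04973290349094079, -0.07726317316720414,
    -0.09405920349573646, 0.4207962846098268, 0.8259229974584023,
    0.4207962846098268, -0.09405920349573646, -0.07726317316720414,
    0.04973290349094079, 0.01193456527972926, -0.016990639867602342,
    -0.0019142861290887667, 0.0019088317364812906
  ),
  dec_hi = c(
    0, 0, 0, 0.014426282505624435, -0.014467504896790148,
    -0.07872200106262882, 0.04036797903033992, 0.41784910915027457,
    -0.7589077294536541, 0.41784910915027457, 0.04036797903033992,
    -0.07872200106262882, -0.014467504896790148, 0.014426282505624435,
    0, 0, 0, 0
  ),
  rec_lo = c(
    0, 0, 0, 0.014426282505624435, 0.014467504896790148,
    -0.07872200106262882, -0.04036797903033992, 0.41784910915027457,
    0.7589077294536541, 0.41784910915027457, -0.04036797903033992,
    -0.07872200106262882, 0.014467504896790148, 0.014426282505624435,
    0, 0, 0, 0
  ),
  rec_hi = c(
    0, -0.0019088317364812906, -0.0019142861290887667, 0.016990639867602342,
    0.01193456527972926, -0.04973290349094079, -0.07726317316720414,
    0.09405920349573646, 0.4207962846098268, -0.8259229974584023,
    0.4207962846098268, 0.09405920349573646, -0.07726317316720414,
    -0.04973290349094079, 0.01193456527972926, 0.016990639867602342,
    -0.0019142861290887667, -0.0019088317364812906
  )
)

wavelet_filters <- function(family) {
  if (!identical(family, "bior6.8")) {
    abort(sprintf("Unsupported wavelet family '%s'; only 'bior6.8' is provided.", family))
  }
  .BIOR68
}

# symmetric (half-sample) signal extension by e samples on each side
sym_extend <- function(x, e) {
  n <- length(x)
  j <- seq(1 - e, n + e)
  m <- (j - 1) %% (2 * n)
  x[ifelse(m < n, m + 1, 2 * n - m)]
}

conv_full <- function(x, f) {
  n <- length(x)
  out <- numeric(n + length(f) - 1)
  for (j in seq_along(f)) {
    if (f[j] != 0) out[j:(j + n - 1)] <- out[j:(j + n - 1)] + f[j] * x
  }
  out
}

# one analysis step: symmetric extension, filter, dyadic downsample
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  f <- length(lo)
  ext <- sym_extend(x, f - 1)
  olen <- (n + f - 1) %/% 2
  idx <- seq(f + 1, by = 2, length.out = olen)
  list(A = conv_full(ext, lo)[idx], D = conv_full(ext, hi)[idx])
}

# one synthesis step; out_len = 2*length(cA) - filter_len + 2
idwt_step <- function(cA, cD, lo, hi, out_len) {
  f <- length(lo)
  up <- function(cc) {
    u <- numeric(2 * length(cc))
    u[seq(1, by = 2, length.out = length(cc))] <- cc
    u
  }
  s <- conv_full(up(cA), lo) + conv_full(up(cD), hi)
  s[seq(f - 1, length.out = out_len)]
}

# multilevel decomposition; returns list(cA_L, cD_L, ..., cD_1)
wavedec <- function(x, flt, level) {
  details <- vector("list", level)
  a <- x
  for (k in seq_len(level)) {
    r <- dwt_step(a, flt$dec_lo, flt$dec_hi)
    details[[k]] <- r$D
    a <- r$A
  }
  c(list(a), rev(details))
}

waverec <- function(coeffs, flt, n) {
  a <- coeffs[[1]]
  for (k in seq_along(coeffs)[-1]) {
    d <- coeffs[[k]]
    if (length(a) == length(d) + 1) a <- a[-length(a)]
    a <- idwt_step(a, d, flt$rec_lo, flt$rec_hi, 2 * length(a) - length(flt$rec_lo) + 2)
  }
  a[seq_len(n)]
}

#' Wavelet background/noise removal settings
#'
#' Configures the multilevel bior6.8 decomposition used by
#' [wavelet_correct()]. The background is carried by the coarsest
#' approximation; non-correlated noise by the finest detail level(s). The
#' default depth is chosen from the grid spacing so that one approximation
#' coefficient spans well over 200 cm-1 (about 500 cm-1 at 2 cm-1 spacing):
#' deep enough that the slowly varying fluorescence background is isolated
#' from Raman bands a few tens of cm-1 wide, with a dyadic margin that keeps
#' Lorentzian tail energy out of the discarded approximation.
#'
#' @param family Wavelet family identifier; only `"bior6.8"` is available.
#' @param n_levels Decomposition depth. `NULL` picks the default depth for
#'   the canonical 2 cm-1 grid (8 levels).
#' @param background_levels Approximation level(s) whose coefficients are
#'   zeroed as background; default the final approximation. Use `integer(0)`
#'   to keep the background.
#' @param noise_levels Detail level(s) zeroed as noise (1 = finest);
#'   default level 1. Use `integer(0)` to keep all detail.
#' @param boundary Signal extension rule at the edges; only `"symmetric"`
#'   is provided (it minimises edge ringing on smooth baselines).
#' @return A `wavelet_settings` list.
#' @export
wavelet_settings <- function(family = "bior6.8", n_levels = NULL,
                             background_levels = NULL, noise_levels = 1L,
                             boundary = "symmetric") {
  wavelet_filters(family)
  if (!identical(boundary, "symmetric")) {
    abort("Only 'symmetric' boundary extension is provided.")
  }
  if (is.null(n_levels)) n_levels <- 8L
  n_levels <- as.integer(n_levels)
  if (n_levels < 1) abort("`n_levels` must be >= 1.")
  if (is.null(background_levels)) background_levels <- n_levels
  background_levels <- as.integer(background_levels)
  noise_levels <- as.integer(noise_levels)
  if (length(background_levels) > 0 &&
    (any(background_levels < 1) || any(background_levels > n_levels))) {
    abort("`background_levels` must lie in 1..n_levels.")
  }
  if (length(noise_levels) > 0 &&
    (any(noise_levels < 1) || any(noise_levels > n_levels))) {
    abort("`noise_levels` must lie in 1..n_levels.")
  }
  if (length(intersect(background_levels, noise_levels)) > 0) {
    abort("`background_levels` and `noise_levels` must be disjoint.")
  }
  structure(
    list(
      family = family, n_levels = n_levels,
      background_levels = background_levels, noise_levels = noise_levels,
      boundary = boundary
    ),
    class = "wavelet_settings"
  )
}

#' @export
print.wavelet_settings <- function(x, ...) {
  cat(sprintf(
    "<wavelet_settings: %s, %d levels, background rm {%s}, noise rm {%s}, %s extension>\n",
    x$family, x$n_levels, paste(x$background_levels, collapse = ","),
    paste(x$noise_levels, collapse = ","), x$boundary
  ))
  invisible(x)
}

#' Wavelet background and noise removal
#'
#' Decomposes each spectrum with the bior6.8 biorthogonal filter bank,
#' zeroes the coarse approximation (slowly varying fluorescence background)
#' and the finest detail level(s) (non-correlated noise), and reconstructs.
#' With empty removal sets this is the identity up to floating-point error
#' (the filter bank satisfies perfect reconstruction).
#'
#' @param s A `sers_spectra` object.
#' @param settings A [wavelet_settings()] list.
#' @return The corrected `sers_spectra`, with a provenance tag recording the
#'   settings.
#' @export
#' @examples
#' cfg <- default_profiles(n_subjects = c(Ctr = 2, MCI = 2, AD = 2))
#' s <- simulate_tears(cfg, seed = 1)$spectra
#' sc <- wavelet_correct(s, wavelet_settings())
wavelet_correct <- function(s, settings = wavelet_settings()) {
  flt <- wavelet_filters(settings$family)
  grid <- spectra_grid(s)
  n <- length(grid)
  if (n < 2^settings$n_levels) {
    max_feasible <- floor(log2(n))
    abort(sprintf(
      "Spectrum of %d points is too short for a depth-%d decomposition; maximum feasible depth is %d.",
      n, settings$n_levels, max_feasible
    ))
  }
  L <- settings$n_levels
  rm_approx <- length(settings$background_levels) > 0
  tag <- sprintf(
    "wavelet:%s:L%d:bg{%s}:noise{%s}", settings$family, L,
    paste(settings$background_levels, collapse = ","),
    paste(settings$noise_levels, collapse = ",")
  )
  map_spectra(s, function(y) {
    co <- wavedec(y, flt, L)
    if (rm_approx) co[[1]][] <- 0
    for (lev in settings$noise_levels) {
      # coefficient list is (cA_L, cD_L, ..., cD_1): detail level k sits at
      # position length(co) + 1 - k
      co[[length(co) + 1 - lev]][] <- 0
    }
    waverec(co, flt, n)
  }, tag = tag)
}

#' Standard normal variate scaling
#'
#' Scales each spectrum to zero mean and unit standard deviation:
#' `(I - mean(I)) / sd(I)`. The population standard deviation convention
#' (divide by n) is used. Idempotent, and invariant under affine transforms
#' of the intensities.
#'
#' @param s A `sers_spectra` object.
#' @return The scaled `sers_spectra` with an `"snv"` provenance tag.
#' @export
snv_normalize <- function(s) {
  map_spectra(s, function(y) {
    mu <- mean(y)
    sdev <- sqrt(mean((y - mu)^2))
    if (sdev == 0) {
      abort("Cannot SNV-scale a constant spectrum (zero intensity standard deviation).")
    }
    (y - mu) / sdev
  }, tag = "snv")
}

#' Full spectral pretreatment
#'
#' The standard pretreatment chain applied to every spectrum, in order:
#' wavelet background/noise removal, then standard-normal-variate scaling.
#'
#' @param s A `sers_spectra` object.
#' @param settings A [wavelet_settings()] list.
#' @param snv Apply SNV scaling after the wavelet step? Default `TRUE`.
#' @return The pretreated `sers_spectra`.
#' @export
preprocess_spectra <- function(s, settings = wavelet_settings(), snv = TRUE) {
  out <- wavelet_correct(s, settings)
  if (snv) out <- snv_normalize(out)
  out
}
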