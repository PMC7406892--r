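#' Detect candidate bands in a spectral region
#'
#' Local maxima of a lightly smoothed (5-point running mean) copy of the
#' spectrum whose topographic prominence is at least
#' `min_prominence * (max - min)` of the region become initial band
#' estimates. The initial width is the distance between the half-prominence
#' crossings, clamped to the fit bounds; the initial height is the peak
#' value above the region minimum. Fully deterministic.
#'
#' @param s A `sers_spectra` holding a single spectrum.
#' @param region Length-2 numeric, `c(lo, hi)` in cm-1; default the whole
#'   grid.
#' @param min_prominence Prominence threshold as a fraction of the region's
#'   intensity range (default 0.05).
#' @return A tibble of seeds (`label`, `center`, `fwhm`, `height`); empty
#'   (zero rows) when no peak qualifies.
#' @export
seed_peaks <- function(s, region = NULL, min_prominence = 0.05) {
  one <- require_single_spectrum(s)
  grid <- one$grid
  if (is.null(region)) region <- range(grid)
  check_region(region, grid)
  sel <- grid >= region[1] & grid <= region[2]
  x <- grid[sel]
  y <- smooth5(one$y[sel])
  rng <- max(y) - min(y)
  empty <- tibble(
    label = character(), center = numeric(),
    fwhm = numeric(), height = numeric()
  )
  if (rng == 0) return(empty)
  n <- length(y)
  peaks <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(peaks) == 0) return(empty)
  keep <- list()
  for (p in peaks) {
    h <- y[p]
    left <- if (any(y[seq_len(p - 1)] > h)) max(which(y[seq_len(p - 1)] > h)) else 1L
    right_cand <- which(y[seq(p + 1, n)] > h)
    right <- if (length(right_cand) > 0) p + min(right_cand) else n
    prom <- h - max(min(y[left:p]), min(y[p:right]))
    if (prom >= min_prominence * rng) {
      half <- h - prom / 2
      li <- p
      while (li > 1 && y[li] > half) li <- li - 1L
      ri <- p
      while (ri < n && y[ri] > half) ri <- ri + 1L
      fw <- max(4, min(120, x[ri] - x[li]))
      keep[[length(keep) + 1L]] <- tibble(
        label = sprintf("peak%g", x[p]), center = x[p],
        fwhm = fw, height = h - min(y)
      )
    }
  }
  if (length(keep) == 0) return(empty)
  do.call(rbind, keep)
}

smooth5 <- function(y) {
  n <- length(y)
  if (n < 5) return(y)
  k <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  k <- as.numeric(k)
  k[1:2] <- y[1:2]
  k[(n - 1):n] <- y[(n - 1):n]
  k
}

#' Template band seeds from the tear band table
#'
#' Seeds the deconvolution with the known control-class band centers that
#' fall inside `region`, with initial heights read off the spectrum.
#'
#' @inheritParams seed_peaks
#' @return A tibble of seeds (`label`, `center`, `fwhm`, `height`).
#' @export
template_seeds <- function(s, region) {
  one <- require_single_spectrum(s)
  check_region(region, one$grid)
  tab <- ctr_band_table()
  tab <- tab[tab$center >= region[1] & tab$center <= region[2], ]
  sel <- one$grid >= region[1] & one$grid <= region[2]
  ymin <- min(one$y[sel])
  tab$height <- vapply(tab$center, function(cc) {
    max(one$y[sel][which.min(abs(one$grid[sel] - cc))] - ymin, 1e-3)
  }, 1)
  tab
}

# seed_peaks seeds, augmented with template centers no detected peak sits
# within `merge_tol` of
auto_seeds <- function(s, region, min_prominence = 0.05, merge_tol = 12) {
  found <- seed_peaks(s, region, min_prominence)
  tmpl <- template_seeds(s, region)
  extra <- tmpl[!vapply(tmpl$center, function(cc) {
    any(abs(found$center - cc) <= merge_tol)
  }, TRUE), ]
  out <- rbind(found, extra)
  out[order(out$center), ]
}

require_single_spectrum <- function(s) {
  if (n_spectra(s) != 1) {
    abort("This operation takes a single spectrum; subset or average the set first.")
  }
  list(grid = s$wavenumber, y = s$intensity, meta = spectra_meta(s))
}

check_region <- function(region, grid) {
  if (length(region) != 2 || region[1] >= region[2]) {
    abort("`region` must be c(lo, hi) with lo < hi.")
  }
  if (region[1] < min(grid) || region[2] > max(grid)) {
    abort(sprintf(
      "Region [%g, %g] lies outside the grid [%g, %g].",
      region[1], region[2], min(grid), max(grid)
    ))
  }
  invisible(region)
}

#' Fit a spectral region as a sum of Lorentzian bands
#'
#' Damped (Levenberg-Marquardt) nonlinear least squares over all band
#' centers, widths and peak heights simultaneously, plus a local low-order
#' baseline that absorbs any residual smooth background left by
#' preprocessing (default quadratic). Bounds: heights >= 0, widths in
#' [4, 120] cm-1, centers inside the region.
#'
#' @param s A `sers_spectra` holding a single spectrum.
#' @param region Length-2 numeric `c(lo, hi)`, cm-1.
#' @param seeds Initial bands: a tibble with columns `center`, `fwhm`,
#'   `height` (e.g. from [seed_peaks()] or [template_seeds()]), or
#'   `"auto"` (default: detected peaks augmented with template centers).
#' @param baseline `"quadratic"` (default), `"linear"`, `"constant"` or
#'   `"none"`.
#' @param center_bound Maximum distance (cm-1) each fitted center may move
#'   from its seed. Default `Inf` (centers free within the region); a
#'   finite value gives template-guided deconvolution, which keeps band
#'   identities in crowded regions.
#' @param fwhm_bound Maximum factor by which each fitted width may differ
#'   from its seed (default `Inf`; widths always stay in [4, 120] cm-1).
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return A `sers_deconv` object: fitted `bands` (with standard errors),
#'   `region`, `residual_rms`, `fitted` curve, `baseline` coefficients,
#'   `converged` flag and `n_iterations`. Non-convergence is reported via
#'   `converged = FALSE`, not an error.
#' @export
#' @examples
#' grid <- canonical_grid()
#' y <- lorentzian(grid, 1000, 20, 2)
#' s <- as_spectra(data.frame(wavenumber = grid, intensity = y))
#' fit <- fit_lorentzians(s, c(900, 1100))
#' tidy(fit)
fit_lorentzians <- function(s, region, seeds = "auto",
                            baseline = c("quadratic", "linear", "constant", "none"),
                            center_bound = Inf, fwhm_bound = Inf,
                            max_iter = 200) {
  baseline <- match.arg(baseline)
  one <- require_single_spectrum(s)
  check_region(region, one$grid)
  if (identical(seeds, "auto")) {
    seeds <- auto_seeds(s, region)
  } else if (identical(seeds, "peaks")) {
    seeds <- seed_peaks(s, region)
  } else if (identical(seeds, "template")) {
    seeds <- template_seeds(s, region)
  }
  stopifnot(is.data.frame(seeds))
  if (nrow(seeds) < 1) abort("Need at least one seed band.")
  if (any(seeds$center < region[1] | seeds$center > region[2])) {
    abort("All seed centers must lie inside the fit region.")
  }
  sel <- one$grid >= region[1] & one$grid <= region[2]
  x <- one$grid[sel]
  y <- one$y[sel]
  k <- nrow(seeds)
  if (3 * k >= length(x)) {
    abort(sprintf("Too many bands (%d) for %d grid points in the region.", k, length(x)))
  }
  nb <- switch(baseline, none = 0L, constant = 1L, linear = 2L, quadratic = 3L)
  xc <- mean(range(x))
  xs <- diff(range(x)) / 2
  model <- function(p) {
    out <- numeric(length(x))
    if (nb >= 1) out <- out + p[1]
    if (nb >= 2) out <- out + p[2] * (x - xc) / xs
    if (nb >= 3) out <- out + p[3] * ((x - xc) / xs)^2
    for (i in seq_len(k)) {
      j <- nb + 3 * (i - 1)
      out <- out + lorentzian(x, p[j + 2], p[j + 3], p[j + 1])
    }
    out
  }
  p0 <- c(
    rep(0, nb),
    as.vector(rbind(pmax(seeds$height, 1e-6), seeds$center, pmin(pmax(seeds$fwhm, 4), 120)))
  )
  if (nb >= 1) p0[1] <- min(y)
  lower <- c(rep(-Inf, nb), rep(c(0, region[1], 4), k))
  upper <- c(rep(Inf, nb), rep(c(Inf, region[2], 120), k))
  if (is.finite(center_bound)) {
    ic <- nb + 3 * (seq_len(k) - 1) + 2
    lower[ic] <- pmax(lower[ic], seeds$center - center_bound)
    upper[ic] <- pmin(upper[ic], seeds$center + center_bound)
  }
  if (is.finite(fwhm_bound)) {
    iw <- nb + 3 * (seq_len(k) - 1) + 3
    lower[iw] <- pmax(lower[iw], seeds$fwhm / fwhm_bound)
    upper[iw] <- pmin(upper[iw], seeds$fwhm * fwhm_bound)
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper,
    fn = function(p) y - model(p),
    control = minpack.lm::nls.lm.control(maxiter = max_iter)
  )
  p <- fit$par
  se <- rep(NA_real_, length(p))
  cov <- tryCatch(
    {
      dof <- max(length(x) - length(p), 1)
      s2 <- fit$deviance / dof
      s2 * solve(fit$hessian)
    },
    error = function(e) NULL
  )
  if (!is.null(cov)) {
    dg <- diag(cov)
    se[dg > 0] <- sqrt(dg[dg > 0])
  }
  ord <- order(p[nb + 3 * (seq_len(k) - 1) + 2])
  bands <- tibble(
    label = seeds$label %||% sprintf("band%d", seq_len(k)),
    height = p[nb + 3 * (seq_len(k) - 1) + 1],
    center = p[nb + 3 * (seq_len(k) - 1) + 2],
    fwhm = p[nb + 3 * (seq_len(k) - 1) + 3],
    height_se = se[nb + 3 * (seq_len(k) - 1) + 1],
    center_se = se[nb + 3 * (seq_len(k) - 1) + 2],
    fwhm_se = se[nb + 3 * (seq_len(k) - 1) + 3]
  )[ord, ]
  structure(
    list(
      bands = bands,
      region = region,
      residual_rms = sqrt(mean(fit$fvec^2)),
      fitted = tibble(wavenumber = x, observed = y, fitted = model(p)),
      baseline = if (nb > 0) p[seq_len(nb)] else numeric(),
      baseline_kind = baseline,
      converged = fit$info %in% 1:4,
      n_iterations = fit$niter,
      meta = one$meta
    ),
    class = "sers_deconv"
  )
}

#' @export
print.sers_deconv <- function(x, ...) {
  cat(sprintf(
    "<sers_deconv: %d bands on [%g, %g] cm-1, rms %.4g, %s after %d iterations>\n",
    nrow(x$bands), x$region[1], x$region[2], x$residual_rms,
    if (x$converged) "converged" else "NOT converged", x$n_iterations
  ))
  print(x$bands)
  invisible(x)
}

#' @describeIn fit_lorentzians Tidy the fitted band table (one row per band).
#' @param x A `sers_deconv` object.
#' @param ... Unused.
#' @method tidy sers_deconv
#' @export
tidy.sers_deconv <- function(x, ...) {
  x$bands
}

#' @describeIn fit_lorentzians One-row fit summary.
#' @method glance sers_deconv
#' @export
glance.sers_deconv <- function(x, ...) {
  tibble(
    n_bands = nrow(x$bands), residual_rms = x$residual_rms,
    converged = x$converged, n_iterations = x$n_iterations,
    region_lo = x$region[1], region_hi = x$region[2]
  )
}

#' Band-intensity ratio from a deconvolution
#'
#' Ratio of the fitted Lorentzian peak heights of the bands nearest two
#' target centers (ties broken toward the lower center). "Intensity" is the
#' fitted peak height, not the raw counts at the target wavenumber nor the
#' band area. The default targets give the I1342/I1243 marker ratio of the
#' Trp C-H deformation band to the amide III beta-sheet band. The ratio is
#' invariant under global rescaling of the input spectrum.
#'
#' @param fit A `sers_deconv` from [fit_lorentzians()].
#' @param num_target,den_target Target centers, cm-1 (defaults 1342, 1243).
#' @param tol Maximum |fitted center - target| allowed (default 15 cm-1).
#' @param n_boot Residual-bootstrap refits used for the uncertainty
#'   (default 200; 0 skips the bootstrap and returns `NA` uncertainty).
#' @param seed Optional seed for the bootstrap resampling.
#' @return A one-row tibble: `value`, `uncertainty`, `numerator_center`,
#'   `denominator_center`.
#' @export
band_ratio <- function(fit, num_target = 1342, den_target = 1243, tol = 15,
                       n_boot = 200, seed = NULL) {
  stopifnot(inherits(fit, "sers_deconv"))
  pick <- function(target) {
    d <- abs(fit$bands$center - target)
    if (min(d) > tol) {
      abort(sprintf("No fitted band within %g cm-1 of target %g cm-1.", tol, target))
    }
    cand <- which(d == min(d))
    cand[which.min(fit$bands$center[cand])]
  }
  inum <- pick(num_target)
  iden <- pick(den_target)
  value <- fit$bands$height[inum] / fit$bands$height[iden]
  uncertainty <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    res <- fit$fitted$observed - fit$fitted$fitted
    base <- fit$fitted$fitted
    x <- fit$fitted$wavenumber
    vals <- vapply(seq_len(n_boot), function(b) {
      yb <- base + sample(res, length(res), replace = TRUE)
      sb <- as_spectra(tibble(wavenumber = x, intensity = yb))
      fb <- tryCatch(
        fit_lorentzians(sb, fit$region,
          seeds = fit$bands[, c("label", "center", "fwhm", "height")],
          baseline = fit$baseline_kind
        ),
        error = function(e) NULL
      )
      if (is.null(fb)) return(NA_real_)
      fb$bands$height[pick_nearest(fb$bands$center, num_target)] /
        fb$bands$height[pick_nearest(fb$bands$center, den_target)]
    }, 1)
    uncertainty <- sd(vals, na.rm = TRUE)
  }
  tibble(
    value = value, uncertainty = uncertainty,
    numerator_center = fit$bands$center[inum],
    denominator_center = fit$bands$center[iden]
  )
}

pick_nearest <- function(centers, target) {
  d <- abs(centers - target)
  cand <- which(d == min(d))
  cand[which.min(centers[cand])]
}

#' Deconvolve every spectrum of a set
#'
#' Maps [fit_lorentzians()] over the member spectra of a set and returns one
#' row per spectrum with the fit stored in a list-column. Use
#' `tidyr::unnest()` on `tidy(fit)` results, or extract ratios with
#' [band_ratio()] over the `fit` column.
#'
#' @param s A `sers_spectra` set.
#' @inheritParams fit_lorentzians
#' @return A tibble: `subject_id`, `replicate_id`, `class_label`,
#'   `converged`, `residual_rms`, `fit` (list of `sers_deconv`).
#' @export
deconvolve_spectra <- function(s, region, seeds = "auto",
                               baseline = c("quadratic", "linear", "constant", "none"),
                               center_bound = Inf, fwhm_bound = Inf,
                            max_iter = 200) {
  baseline <- match.arg(baseline)
  meta <- spectra_meta(s)
  fits <- lapply(seq_len(nrow(meta)), function(i) {
    one <- s[s$subject_id == meta$subject_id[i] & s$replicate_id == meta$replicate_id[i], ]
    one <- new_spectra(one, provenance = provenance(s))
    fit_lorentzians(one, region,
      seeds = seeds, baseline = baseline,
      center_bound = center_bound, fwhm_bound = fwhm_bound, max_iter = max_iter
    )
  })
  meta$converged <- vapply(fits, function(f) f$converged, TRUE)
  meta$residual_rms <- vapply(fits, function(f) f$residual_rms, 1)
  meta$fit <- fits
  meta
}
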