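#' @importFrom ggplot2 ggplot aes geom_line geom_ribbon geom_point geom_hline
#'   labs facet_wrap theme_minimal autoplot scale_colour_manual geom_rug
NULL

.CLASS_COLOURS <- c(Ctr = "#2a9d34", MCI = "#1f5fb4", AD = "#c02424", UNKNOWN = "grey50")

#' Plot class-average spectra
#'
#' One line per class (pointwise mean over that class's spectra) with a
#' +/- 1 SD ribbon, in the conventional class colours (Ctr green, MCI blue,
#' AD red).
#'
#' @param object A `sers_spectra` set.
#' @param ribbon Draw the +/- 1 SD dispersion ribbon (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sers_spectra
#' @export
autoplot.sers_spectra <- function(object, ribbon = TRUE, ...) {
  labs_present <- unique(as.character(spectra_meta(object)$class_label))
  df <- purrr::map_dfr(labs_present, function(cl) {
    rows <- object[as.character(object$class_label) == cl, ]
    rows |>
      group_by(.data$wavenumber) |>
      summarise(
        mean = mean(.data$intensity), sd = sd(.data$intensity),
        .groups = "drop"
      ) |>
      mutate(class_label = cl)
  })
  p <- ggplot(df, aes(.data$wavenumber, .data$mean, colour = .data$class_label))
  if (ribbon) {
    p <- p + geom_ribbon(
      aes(
        ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd,
        fill = .data$class_label
      ),
      alpha = 0.2, colour = NA
    ) +
      ggplot2::scale_fill_manual(values = .CLASS_COLOURS, name = "class")
  }
  p + geom_line() +
    scale_colour_manual(values = .CLASS_COLOURS, name = "class") +
    labs(
      x = expression("Raman shift (cm"^-1 * ")"),
      y = "intensity (arb. units)"
    ) +
    theme_minimal()
}

#' Plot a class difference map
#'
#' The difference spectrum against the reference class, the +/- 0.68 SD
#' reference dispersion band, and rug marks at jointly significant
#' wavenumbers.
#'
#' @param object A `sers_diffmap` from [difference_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sers_diffmap
#' @export
autoplot.sers_diffmap <- function(object, ...) {
  df <- as_tibble(object)
  sig <- df[df$significant, ]
  ggplot(df, aes(.data$wavenumber, .data$delta)) +
    geom_ribbon(aes(ymin = .data$band_lo, ymax = .data$band_hi),
      fill = "#2a9d34", alpha = 0.25
    ) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line(colour = "#c02424") +
    geom_rug(data = sig, sides = "b", colour = "#c02424") +
    labs(
      x = expression("Raman shift (cm"^-1 * ")"),
      y = expression(Delta * " intensity vs reference"),
      title = attr(object, "class_pair"),
      subtitle = sprintf(
        "band: +/-0.68 SD of reference; rug: p < %g and outside band",
        attr(object, "alpha")
      )
    ) +
    theme_minimal()
}

#' Plot a Lorentzian deconvolution
#'
#' Observed and fitted curves plus the individual fitted band components.
#'
#' @param object A `sers_deconv` from [fit_lorentzians()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sers_deconv
#' @export
autoplot.sers_deconv <- function(object, ...) {
  x <- object$fitted$wavenumber
  comp <- purrr::map_dfr(seq_len(nrow(object$bands)), function(i) {
    tibble(
      wavenumber = x,
      intensity = lorentzian(
        x, object$bands$center[i],
        object$bands$fwhm[i], object$bands$height[i]
      ),
      band = sprintf("%.0f", object$bands$center[i])
    )
  })
  ggplot(object$fitted, aes(.data$wavenumber, .data$observed)) +
    geom_point(size = 0.6, colour = "grey40") +
    geom_line(data = comp, aes(y = .data$intensity, group = .data$band),
      colour = "#1f5fb4", linewidth = 0.3
    ) +
    geom_line(aes(y = .data$fitted), colour = "#c02424") +
    labs(
      x = expression("Raman shift (cm"^-1 * ")"), y = "intensity",
      title = sprintf("Lorentzian deconvolution, %g-%g cm-1", object$region[1], object$region[2])
    ) +
    theme_minimal()
}

#' Scatter plot of two i-PCA score features
#'
#' @param table A `sers_scores` table.
#' @param x_feature,y_feature Feature keys, e.g. `"456-553.PC3"`.
#' @return A ggplot.
#' @export
plot_scores <- function(table, x_feature, y_feature) {
  for (f in c(x_feature, y_feature)) {
    if (!f %in% names(table)) abort(sprintf("Feature '%s' not in the table.", f))
  }
  ggplot(
    table,
    aes(.data[[x_feature]], .data[[y_feature]], colour = as.character(.data$class_label))
  ) +
    geom_point() +
    scale_colour_manual(values = .CLASS_COLOURS, name = "class") +
    theme_minimal()
}
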