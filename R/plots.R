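#' Default family of nomogram lines
#'
#' Proportions lost at 2.5% steps up to 30% and 5% steps up to 50% — the
#' granularity at which the correction factor remains readable off the
#' chart.
#'
#' @return Numeric vector of proportions.
#' @export
default_r_lines <- function() {
  c(seq(0.025, 0.30, by = 0.025), seq(0.35, 0.50, by = 0.05))
}

#' Draw the correction-factor nomogram
#'
#' One straight line per proportion lost `r`, with intercept `1 - r` and
#' slope `r` over the mortality ratio `M_L / M_NL`: `C = (1 - r) + r *
#' ratio` is exactly linear, so the nomogram is drawn as lines, not fitted
#' curves. All lines meet at `(ratio = 1, C = 1)`. An optional programme
#' point can be marked with broken guide lines, as in the worked
#' tracing-method example.
#'
#' @param ratio_max Right edge of the ratio axis (15 for the standard
#'   chart; 50 for the wide variant).
#' @param r_lines Proportions lost to draw, default [default_r_lines()].
#' @param annotate Optional `c(ratio, r)` pair to mark.
#' @param c_axis_max Optional upper limit for the correction-factor axis.
#' @return A `ggplot` object. The layer data expose every line endpoint and
#'   the annotated point, so geometry can be checked programmatically.
#' @examples
#' plot_nomogram(ratio_max = 15, annotate = c(9.1, 0.405))
#' @export
plot_nomogram <- function(ratio_max = 15, r_lines = default_r_lines(),
                          annotate = NULL, c_axis_max = NULL) {
  if (ratio_max <= 1) {
    abort("`ratio_max` must exceed 1.", class = "ltfu_validation_error")
  }
  if (length(r_lines) == 0) {
    abort("`r_lines` must be non-empty.", class = "ltfu_validation_error")
  }
  assert_prob(r_lines, "r_lines")
  lines <- tidyr::expand_grid(r = sort(r_lines), ratio = c(1, ratio_max)) |>
    dplyr::mutate(c = correction_factor(.data$r, .data$ratio))
  labels <- dplyr::filter(lines, .data$ratio == ratio_max)
  p <- ggplot2::ggplot(lines, ggplot2::aes(x = .data$ratio, y = .data$c,
                                           group = .data$r)) +
    ggplot2::geom_line(colour = "grey30", linewidth = 0.3) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(label = sprintf("%g%%", 100 * .data$r)),
                       hjust = -0.15, size = 2.6, colour = "grey30") +
    ggplot2::scale_x_continuous(limits = c(1, ratio_max * 1.06),
                                breaks = scales_breaks(ratio_max)) +
    ggplot2::labs(
      x = "Ratio of mortality, lost vs not lost (M_L / M_NL)",
      y = "Correction factor C",
      title = "Correction of programme-level mortality for loss to follow-up",
      subtitle = "Lines: proportion of patients lost to follow-up (r)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(c_axis_max)) {
    p <- p + ggplot2::coord_cartesian(ylim = c(0, c_axis_max))
  }
  if (!is.null(annotate)) {
    ratio0 <- annotate[1]; r0 <- annotate[2]
    c0 <- correction_factor(r0, ratio0)
    guides <- tibble(x = c(ratio0, ratio0, 1), y = c(0, c0, c0),
                     xend = c(ratio0, 1, NA), yend = c(c0, c0, NA))
    pt <- tibble(ratio = ratio0, r = r0, c = c0)
    p <- p +
      ggplot2::geom_segment(data = guides[1:2, ],
                            ggplot2::aes(x = .data$x, y = .data$y,
                                         xend = .data$xend, yend = .data$yend),
                            inherit.aes = FALSE,
                            linetype = "dashed", colour = "red") +
      ggplot2::geom_point(data = pt, colour = "red", size = 2)
  }
  p
}

scales_breaks <- function(ratio_max) {
  if (ratio_max <= 20) c(1, seq(5, ratio_max, by = 5)) else
    c(1, seq(10, ratio_max, by = 10))
}

#' Draw the meta-regression prediction curve with its band
#'
#' Predicted mortality among patients lost to follow-up against the
#' percentage of patients lost, with the calibrated 95% band shaded. An
#' uncalibrated model yields the curve alone, with a warning.
#'
#' @param model An [meta_model()].
#' @param r_range Range of the proportion lost, default `c(0, 0.5)`.
#' @param level Band coverage, default 0.95.
#' @param n Number of grid points.
#' @return A `ggplot` object whose `$data` holds the plotted grid
#'   (`r_pct`, `fit_pct`, `lwr_pct`, `upr_pct`).
#' @examples
#' plot_prediction_curve(meta_model())
#' @export
plot_prediction_curve <- function(model = meta_model(), r_range = c(0, 0.5),
                                  level = 0.95, n = 201) {
  stopifnot(inherits(model, "ltfu_meta"))
  r <- seq(r_range[1], r_range[2], length.out = n)
  if (is.null(model$interval)) {
    warn("model has no calibrated interval; drawing the curve without a band.")
    dat <- tibble(r = r, fit = predict_mortality_lost(r, model),
                  lwr = NA_real_, upr = NA_real_)
  } else {
    dat <- prediction_interval_lost(r, model, level = level)
  }
  dat <- dplyr::mutate(dat, r_pct = 100 * .data$r,
                       fit_pct = 100 * .data$fit,
                       lwr_pct = 100 * .data$lwr,
                       upr_pct = 100 * .data$upr)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$r_pct, y = .data$fit_pct))
  if (!anyNA(dat$lwr_pct)) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr_pct,
                                               ymax = .data$upr_pct),
                                  fill = "grey80")
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "Patients lost to follow-up (%)",
      y = "Predicted mortality among patients lost (%)",
      title = "Meta-regression prediction of mortality among patients lost"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_prediction_curve
#' @param object,... `autoplot()` method arguments.
#' @method autoplot ltfu_meta
#' @export
autoplot.ltfu_meta <- function(object, ...) {
  plot_prediction_curve(object, ...)
}

#' Nomogram populated with programme points
#'
#' Overlays programmes on the nomogram backdrop: each programme is plotted
#' at its mortality ratio `m_l / m_nl` and correction factor `C`.
#' Programmes with `m_nl = 0` have no defined ratio and are skipped with a
#' warning.
#'
#' @param data Programme summaries with columns `label`, `r`, `m_nl`,
#'   `m_l`.
#' @param ratio_max,r_lines,c_axis_max Passed to [plot_nomogram()].
#' @return A `ggplot` object; the programme layer's data carry the plotted
#'   `(ratio, c)` coordinates.
#' @examples
#' ssa <- dplyr::mutate(ssa_programmes(), m_l = m_l_pub)
#' plot_populated_nomogram(ssa)
#' @export
plot_populated_nomogram <- function(data, ratio_max = 50,
                                    r_lines = default_r_lines(),
                                    c_axis_max = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) {
    return(plot_nomogram(ratio_max = ratio_max, r_lines = r_lines,
                         c_axis_max = c_axis_max))
  }
  skip <- data$m_nl == 0
  if (any(skip)) {
    warn(sprintf("skipping %d programme(s) with m_nl = 0 (ratio undefined).",
                 sum(skip)))
    data <- data[!skip, ]
  }
  pts <- correct_mortality(data)
  p <- plot_nomogram(ratio_max = ratio_max, r_lines = r_lines,
                     c_axis_max = c_axis_max)
  p +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$ratio, y = .data$c),
                        inherit.aes = FALSE, colour = "red", size = 2) +
    ggplot2::geom_text(data = pts,
                       ggplot2::aes(x = .data$ratio, y = .data$c,
                                    label = .data$label),
                       inherit.aes = FALSE, vjust = -0.8, size = 2.8)
}

#' Save a figure to SVG or PNG
#'
#' Thin wrapper over [ggplot2::ggsave()] choosing the device from the file
#' extension; SVG output is deterministic for fixed input.
#'
#' @param plot A `ggplot` object.
#' @param path Output path ending in `.svg` or `.png`.
#' @param width,height Inches.
#' @param dpi Resolution for PNG.
#' @return `path`, invisibly.
#' @export
save_figure <- function(plot, path, width = 7, height = 5, dpi = 300) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("svg", "png")) {
    abort("output must end in .svg or .png.", class = "ltfu_validation_error")
  }
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    print(plot)
  } else {
    ggplot2::ggsave(path, plot = plot, width = width, height = height,
                    dpi = dpi, device = ext)
  }
  invisible(path)
}
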