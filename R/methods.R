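#' Broom-style accessors for validation results
#'
#' `tidy()` returns one row per sample with truth, first-tier and MLPA
#' results; `glance()` returns the one-row cohort metrics.
#'
#' @param x An `smn_validation` object from [run_validation()].
#' @param ... Unused.
#' @return A tibble.
#' @name smn_validation_methods
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname smn_validation_methods
#' @method tidy smn_validation
#' @export
tidy.smn_validation <- function(x, ...) {
  x$samples
}

#' @rdname smn_validation_methods
#' @method glance smn_validation
#' @export
glance.smn_validation <- function(x, ...) {
  x$metrics
}

#' @export
print.smn_validation <- function(x, ...) {
  m <- x$metrics
  cat("<smn_validation> two-tier SMA screening run (seed", x$seed, ")\n")
  cat(sprintf("  %d samples scored on %d plates (%d plate(s) failed QC, %d wells excluded)\n",
              m$n_total, nrow(x$plate_qc), m$n_plates_failed_qc,
              m$n_excluded))
  cat(sprintf("  screen-positive: %d (of which controls: %d); retested wells: %d\n",
              m$n_screen_positive, m$n_second_tier_controls, m$n_retested))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, tier concordance %.1f%%\n",
              100 * m$sensitivity, 100 * m$specificity, 100 * m$concordance))
  if (m$n_designed_misses > 0)
    cat(sprintf("  designed misses (non-deletion SMA, invisible to this assay): %d\n",
                m$n_designed_misses))
  invisible(x)
}

#' Plot melt curves or their derivative profiles
#'
#' @param curves Long curve tibble from [simulate_melt_curves()].
#' @param config An [sim_config()] object.
#' @param derivative Plot `-dF/dT` (with the calling windows shaded)
#'   instead of raw fluorescence?
#' @return A ggplot object.
#' @examples
#' curves <- simulate_melt_curves(generate_cohort(seed = 1)[1:3, ], seed = 1)
#' plot_melt_curves(curves, derivative = TRUE)
#' @export
plot_melt_curves <- function(curves, config = sim_config(),
                             derivative = FALSE) {
  if (derivative) {
    d <- melt_derivative(curves, config)
    wins <- purrr::imap_dfr(config$windows, ~ tibble::tibble(
      window = .y, lo = .x[1], hi = .x[2]))
    ggplot2::ggplot(d, ggplot2::aes(.data$temperature_c, .data$neg_dfdt,
                                    group = .data$sample_id,
                                    colour = .data$sample_id)) +
      ggplot2::geom_rect(data = wins,
                         ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                      ymin = -Inf, ymax = Inf),
                         inherit.aes = FALSE, alpha = 0.08) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Temperature (°C)", y = "-dF/dT",
                    colour = "Sample") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(curves,
                    ggplot2::aes(.data$temperature_c, .data$fluorescence,
                                 group = .data$sample_id,
                                 colour = .data$sample_id)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Temperature (°C)", y = "Fluorescence",
                    colour = "Sample") +
      ggplot2::theme_minimal()
  }
}

#' Plot a validation run
#'
#' Heatmap of the called SMN1/SMN2 copy-number cross-tabulation of the
#' cohort, the shape in which validation results are conventionally
#' reported.
#'
#' @param object An `smn_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot smn_validation
#' @export
autoplot.smn_validation <- function(object, ...) {
  tab <- dplyr::count(object$samples, .data$smn1_cn, .data$smn2_cn)
  ggplot2::ggplot(tab, ggplot2::aes(factor(.data$smn2_cn),
                                    factor(.data$smn1_cn))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "SMN2 exon-7 copies (called)",
                  y = "SMN1 exon-7 copies (called)", fill = "Samples") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
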