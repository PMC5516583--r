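#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' Real part against the ppm axis, printed high-to-low as is conventional.
#'
#' @param object An `mrs_spectrum`.
#' @param window Optional ppm interval to restrict the plot.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot mrs_spectrum
#' @export
autoplot.mrs_spectrum <- function(object, window = NULL, ...) {
  d <- tibble(ppm = object$ppm, value = Re(object$values))
  if (!is.null(window)) d <- d[d$ppm >= min(window) & d$ppm <= max(window), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "signal (a.u.)",
                  title = paste0(object$provenance, " spectrum")) +
    ggplot2::theme_minimal()
}

#' Plot an edited glutathione fit
#'
#' Observed difference spectrum, simple-Gaussian fit and residual in the
#' glutathione window.
#'
#' @param object An [fit_edited_gsh()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot edited_fit
#' @export
autoplot.edited_fit <- function(object, ...) {
  if (isTRUE(object$failed)) abort("Cannot plot a failed fit.")
  d <- tidyr::pivot_longer(object$data, c("observed", "fitted", "residual"),
                           names_to = "trace", values_to = "value")
  d$trace <- factor(d$trace, levels = c("observed", "fitted", "residual"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppm, y = .data$value,
                                  colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "signal (a.u.)",
                  title = sprintf("GSH fit (fit error %.0f%%)",
                                  object$fit_error_pct)) +
    ggplot2::theme_minimal()
}

#' Mean change versus time (cohort time-course)
#'
#' Mean +/- SEM of the per-subject differences versus baseline at each scan
#' midpoint, with asterisks marking bins significantly different from
#' baseline after Holm-Sidak correction.
#'
#' @param result A [run_pipeline()] result (or a summary tibble plus an
#'   optional `gsh_rm_anova`).
#' @param response `"gsh_cr"` or `"gsh_absolute_iu"` (when quantified).
#' @return A ggplot.
#' @export
plot_time_course <- function(result, response = "gsh_cr") {
  if (inherits(result, "gsh_pipeline_result")) {
    s <- if (response == "gsh_cr") result$summary else result$summary_absolute
    a <- if (response == "gsh_cr") result$anova else result$anova_absolute
  } else {
    s <- result
    a <- NULL
  }
  d <- s[!is.na(s$mean_diff), ]
  d$sig <- FALSE
  if (!is.null(a)) {
    sig_bins <- a$comparisons$bin[a$comparisons$significant]
    d$sig <- as.character(d$bin) %in% sig_bins
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_mean, y = .data$mean_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_diff - .data$sem_diff,
                                        ymax = .data$mean_diff + .data$sem_diff),
                           width = 1) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_text(data = d[d$sig, ],
                       ggplot2::aes(y = .data$mean_diff + 1.5 * .data$sem_diff),
                       label = "*", size = 6) +
    ggplot2::labs(x = "time post dose (min, scan midpoint)",
                  y = paste("change vs baseline:", response)) +
    ggplot2::theme_minimal()
}

#' Per-subject trajectories over time
#'
#' @param quant A quantification tibble with `time_min`, `subject_id` and the
#'   response.
#' @param response Response column.
#' @return A ggplot.
#' @export
plot_subject_trajectories <- function(quant, response = "gsh_cr") {
  d <- quant[!is.na(quant[[response]]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data[[response]],
                                  group = .data$subject_id,
                                  colour = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time post dose (min)", y = response) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
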