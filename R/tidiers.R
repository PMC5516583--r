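#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns the component- or comparison-level
#' table of a fitted object; `glance()` returns a one-row summary.
#'
#' @param x A fitted object from this package.
#' @param ... Ignored.
#' @return A tibble.
#' @name gshmrs-tidiers
NULL

#' @rdname gshmrs-tidiers
#' @method tidy edited_fit
#' @export
tidy.edited_fit <- function(x, ...) {
  if (isTRUE(x$failed)) return(tibble())
  comp <- x$components
  if (is.null(comp)) comp <- tibble()
  simple <- x$gsh_single
  simple$label <- "gsh_simple"
  dplyr::bind_rows(comp, simple)
}

#' @rdname gshmrs-tidiers
#' @method glance edited_fit
#' @export
glance.edited_fit <- function(x, ...) {
  tibble(gsh_area = if (isTRUE(x$failed)) NA_real_ else x$gsh_area,
         gsh_area_5g = if (isTRUE(x$failed)) NA_real_ else x$gsh_area_5g,
         gsh_height = if (isTRUE(x$failed)) NA_real_ else x$gsh_height,
         fit_error_pct = x$fit_error_pct,
         noise_floor = if (isTRUE(x$failed)) NA_real_ else x$noise_floor,
         detectable = isTRUE(x$detectable),
         failed = isTRUE(x$failed))
}

#' @rdname gshmrs-tidiers
#' @method tidy cr_fit
#' @export
tidy.cr_fit <- function(x, ...) {
  if (!isTRUE(x$usable)) return(tibble())
  x$components
}

#' @rdname gshmrs-tidiers
#' @method glance cr_fit
#' @export
glance.cr_fit <- function(x, ...) {
  tibble(cr_area = if (isTRUE(x$usable)) x$area else NA_real_,
         cr_amplitude = if (isTRUE(x$usable)) x$amplitude else NA_real_,
         fit_error_pct = x$fit_error_pct,
         usable = isTRUE(x$usable))
}

#' @rdname gshmrs-tidiers
#' @method tidy press_fit
#' @export
tidy.press_fit <- function(x, ...) x$concentrations

#' @rdname gshmrs-tidiers
#' @method glance press_fit
#' @export
glance.press_fit <- function(x, ...) {
  tibble(cr_concentration = x$cr_concentration, cr_crlb_pct = x$cr_crlb_pct,
         linewidth_ppm = x$linewidth_ppm, snr = x$snr, qc_pass = x$qc_pass)
}

#' @rdname gshmrs-tidiers
#' @method tidy gsh_rm_anova
#' @export
tidy.gsh_rm_anova <- function(x, ...) x$comparisons

#' @rdname gshmrs-tidiers
#' @method glance gsh_rm_anova
#' @export
glance.gsh_rm_anova <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, df1 = x$df[1], df2 = x$df[2],
         p_value = x$p_value, n_subjects = x$n_subjects, n_bins = x$n_bins)
}
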