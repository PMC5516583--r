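#' Pipeline configuration
#'
#' Collects every tunable default of the processing chain in one list.
#' Unknown names are rejected, so configs stay in step with the code.
#'
#' @param ... Name-value overrides of the defaults.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    broadening_edited_hz = 3,
    broadening_press_hz = 1.1,
    zero_fill_factor = 2,
    align_transients = TRUE,
    edited_fit_window = c(2.6, 3.3),
    gsh_fit_window = c(2.87, 3.03),
    cr_window = c(2.9, 3.25),
    editing_efficiency = 0.74,
    use_5g = FALSE,
    max_fit_error = 200,
    noise_floor_factor = 4,
    serial_factor_limit = Inf,
    impute = TRUE,
    percent_change_convention = "ratio_of_means",
    alpha = 0.05,
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")),
          class = "gshmrs_param_error")
  }
  structure(modifyList(defaults, over), class = "pipeline_config")
}

#' Quantify one edited scan
#'
#' Runs the edited pathway on one block of MEGA-PRESS stored averages:
#' preprocess ([preprocess_edited_scan()]), subtract ([difference_edit()]),
#' fit glutathione ([fit_edited_gsh()]) and the creatine reference
#' ([fit_reference_cr()]), and form the ratio.
#'
#' @param scan A list with `on`/`off` `mrs_fid`s (single or lists).
#' @param config A [pipeline_config()].
#' @return A one-row tibble: `gsh_area`, `cr_area`, `gsh_cr`,
#'   `fit_error_pct`, `cr_fit_error_pct`, `combined_fit_error_pct`,
#'   `noise_floor`, `detectable`, plus the fit objects in list-columns
#'   `edited_fit` and `cr_fit`.
#' @export
quantify_scan <- function(scan, config = pipeline_config()) {
  prep <- preprocess_edited_scan(scan, config$broadening_edited_hz,
                                 config$zero_fill_factor,
                                 align = config$align_transients)
  diff <- difference_edit(prep$on, prep$off)
  ed <- fit_edited_gsh(diff, config$edited_fit_window, config$gsh_fit_window)
  cr <- fit_reference_cr(prep$off, config$cr_window)
  ratio <- gsh_cr_ratio(ed, cr, config$editing_efficiency, config$use_5g)
  tibble(
    gsh_area = if (isTRUE(ed$failed)) NA_real_ else ed$gsh_area,
    cr_area = if (isTRUE(cr$usable)) cr$area else NA_real_,
    gsh_cr = ratio,
    fit_error_pct = ed$fit_error_pct,
    cr_fit_error_pct = cr$fit_error_pct,
    combined_fit_error_pct = ed$fit_error_pct + cr$fit_error_pct,
    noise_floor = if (isTRUE(ed$failed)) NA_real_ else ed$noise_floor,
    detectable = isTRUE(ed$detectable),
    edited_fit = list(ed),
    cr_fit = list(cr)
  )
}

#' Quantify a whole simulated cohort
#'
#' Applies [quantify_scan()] to every MEGA-PRESS scan, attaches per-scan QC
#' flags ([qc_scan()], with the cohort median noise floor as the corruption
#' reference), and, when reference scans are present, performs absolute
#' quantification per subject: PRESS basis fit, water T2, water referencing,
#' CSF partial-volume correction, and absolute GSH per scan.
#'
#' @param cohort A [simulate_cohort()] object with spectra.
#' @param config A [pipeline_config()].
#' @param keep_fits Keep the fit objects as list-columns (larger output).
#' @return A tibble with one row per scan: identifiers, time, truth columns,
#'   measured `gsh_cr`, fit errors, `flag` (`ok`, `undetectable`,
#'   `insufficient_quality`), and when available `cr_measured_iu`,
#'   `cr_corrected_iu`, `gsh_absolute_iu`, `press_qc_pass`.
#' @export
quantify_cohort <- function(cohort, config = pipeline_config(),
                            keep_fits = FALSE) {
  stopifnot(inherits(cohort, "gsh_cohort"))
  if (is.null(cohort$mega)) {
    abort("Cohort was generated with `spectra = FALSE`.",
          class = "gshmrs_structure_error")
  }
  per_scan <- purrr::map(cohort$mega, quantify_scan, config = config)
  q <- dplyr::bind_cols(cohort$scans, dplyr::bind_rows(per_scan))

  ref_floor <- median(q$noise_floor, na.rm = TRUE)
  q$flag <- purrr::map2_chr(q$edited_fit, q$cr_fit, function(ed, cr) {
    qc_scan(ed, cr, noise_floor_ref = ref_floor,
            max_fit_error = config$max_fit_error,
            noise_floor_factor = config$noise_floor_factor)
  })
  # a corrupted acquisition is excluded regardless of its apparent peak
  q$gsh_cr[q$flag != "ok"] <- NA_real_

  # absolute quantification from the per-subject reference scans
  if (!is.null(cohort$press)) {
    basis <- make_basis_set(
      acq = cohort$press[[1]]$acq,
      broadening_hz = config$broadening_press_hz,
      zero_fill_factor = config$zero_fill_factor)
    subs <- unique(q$subject_id)
    ref <- purrr::map(subs, function(sid) {
      spec <- preprocess_press(cohort$press[[sid]], config$broadening_press_hz,
                               config$zero_fill_factor)
      pf <- fit_press(spec, basis)
      wp <- cohort$water[[sid]]
      t2 <- estimate_water_t2(wp$a, wp$b)
      cr_iu <- if (pf$qc_pass) water_reference(pf, wp$b, t2) else NA_real_
      fcsf <- q$f_csf[q$subject_id == sid][1]
      tibble(subject_id = sid,
             press_qc_pass = pf$qc_pass,
             water_t2_est_ms = t2,
             cr_measured_iu = cr_iu,
             cr_corrected_iu = if (is.na(cr_iu)) NA_real_ else
               csf_correct(cr_iu, fcsf),
             press_fit = list(pf))
    })
    ref <- dplyr::bind_rows(ref)
    if (!keep_fits) ref$press_fit <- NULL
    q <- dplyr::left_join(q, ref, by = "subject_id")
    q$gsh_absolute_iu <- absolute_gsh(q$gsh_cr, q$cr_corrected_iu)
  }
  if (!keep_fits) {
    q$edited_fit <- NULL
    q$cr_fit <- NULL
  }
  q
}
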