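#' Form the difference-edited spectrum
#'
#' Bin-wise `OFF - ON` on identical axes, globally negated if the extremum
#' nearest 2.95 ppm comes out negative, so the glutathione peak is always
#' positive in the result.
#'
#' @param on,off `mrs_spectrum`s of the two editing conditions.
#' @return An `mrs_spectrum` with provenance `"DIFF"`.
#' @export
difference_edit <- function(on, off) {
  stopifnot(inherits(on, "mrs_spectrum"), inherits(off, "mrs_spectrum"))
  if (length(on$values) != length(off$values) ||
      max(abs(on$ppm - off$ppm)) > 1e-9) {
    abort("ON and OFF spectra must share the same ppm axis.",
          class = "gshmrs_structure_error")
  }
  d <- off
  d$values <- off$values - on$values
  idx <- which(in_window(d, c(GSH_PPM - 0.06, GSH_PPM + 0.06)))
  k <- idx[which.max(abs(Re(d$values[idx])))]
  if (length(k) == 1 && Re(d$values[k]) < 0) d$values <- -d$values
  d$provenance <- "DIFF"
  d$history <- c(d$history, "difference_edit")
  d
}

gauss_eval <- function(x, A, c0, w) A * exp(-(x - c0)^2 / (2 * w^2))

# Gaussian mixture + polynomial baseline (in a centred coordinate) via
# Levenberg-Marquardt with analytic Jacobian. Parameters are packed
# (A..., c..., w..., b0..b_degree).
fit_gaussian_model <- function(x, y, init, lower, upper, maxit = 200,
                               baseline_degree = 1) {
  m <- nrow(init)
  nb <- baseline_degree + 1
  xc <- x - mean(x)
  pack <- function(tab, b) c(tab$amplitude, tab$center, tab$width, b)
  unpack <- function(p) {
    list(A = p[seq_len(m)], c0 = p[m + seq_len(m)], w = p[2 * m + seq_len(m)],
         b = p[3 * m + seq_len(nb)])
  }
  model <- function(p) {
    q <- unpack(p)
    f <- rep(0, length(x))
    for (j in seq_len(nb)) f <- f + q$b[j] * xc^(j - 1)
    for (k in seq_len(m)) f <- f + gauss_eval(x, q$A[k], q$c0[k], q$w[k])
    f
  }
  resid_fn <- function(p) y - model(p)
  jac_fn <- function(p) {
    q <- unpack(p)
    J <- matrix(0, nrow = length(x), ncol = 3 * m + nb)
    for (k in seq_len(m)) {
      E <- exp(-(x - q$c0[k])^2 / (2 * q$w[k]^2))
      J[, k] <- -E
      J[, m + k] <- -q$A[k] * E * (x - q$c0[k]) / q$w[k]^2
      J[, 2 * m + k] <- -q$A[k] * E * (x - q$c0[k])^2 / q$w[k]^3
    }
    for (j in seq_len(nb)) J[, 3 * m + j] <- -xc^(j - 1)
    J
  }
  p0 <- pmin(pmax(pack(init, rep(0, nb)), lower), upper)
  # non-convergence of an individual start is handled by the multi-start
  # SSR comparison; the optimizer's own warning would only be noise
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = p0, fn = resid_fn, jac = jac_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxit, ptol = 1e-11,
                                         ftol = 1e-11)
  ))
  q <- unpack(fit$par)
  comp <- tibble(amplitude = q$A, center = q$c0, width = abs(q$w))
  comp$area <- comp$amplitude * comp$width * sqrt(2 * pi)
  list(components = comp, baseline = q$b, fitted = model(fit$par),
       residuals = y - model(fit$par), ssr = sum((y - model(fit$par))^2),
       converged = fit$info %in% 1:4, info = fit$info)
}

# multi-start over a fixed list of initial widths (ppm); deterministic
fit_gaussian_multistart <- function(x, y, centers, amp_lower, widths_init,
                                    center_bound = 0.05,
                                    width_bounds = c(0.006, 0.04),
                                    baseline_degree = 1) {
  m <- length(centers)
  nb <- baseline_degree + 1
  amp0 <- pmax(approx(x, y, xout = centers, rule = 2)$y, 1e-12)
  best <- NULL
  for (w0 in widths_init) {
    init <- tibble(amplitude = amp0, center = centers, width = w0)
    lower <- c(amp_lower, centers - center_bound,
               rep(width_bounds[1], m), rep(-Inf, nb))
    upper <- c(rep(Inf, m), centers + center_bound,
               rep(width_bounds[2], m), rep(Inf, nb))
    fit <- tryCatch(fit_gaussian_model(x, y, init, lower, upper,
                                       baseline_degree = baseline_degree),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$ssr < best$ssr)) best <- fit
  }
  best
}

#' Detection z-score of the edited glutathione peak
#'
#' A linear matched-filter statistic: the mean of the real difference
#' spectrum over the glutathione core (centre +/- 0.025 ppm) minus the mean
#' over symmetric flanks, divided by the empirical SD of the identical
#' statistic evaluated at signal-free centres (0.7-1.5 ppm). Being linear in
#' the data, its null distribution is Gaussian and the threshold calibrates
#' itself to whatever noise correlation the processing induced.
#'
#' @param diff A difference `mrs_spectrum`.
#' @param center Peak centre in ppm.
#' @param half_core,flank Half-width of the core window and the flank
#'   interval (offsets from the centre), ppm.
#' @param null_centers Signal-free centres used to estimate the null SD; the
#'   defaults tile the empty regions of the difference spectrum on both
#'   sides of the metabolite band.
#' @return The z-score (dimensionless).
#' @export
detection_z <- function(diff, center = GSH_PPM, half_core = 0.03,
                        flank = c(0.06, 0.10),
                        null_centers = c(seq(-2.6, 1.5, by = 0.08),
                                         seq(5.4, 12.0, by = 0.08))) {
  # work on an ascending axis so window bounds come from findInterval
  ppm <- rev(diff$ppm)
  y <- rev(Re(diff$values))
  # matched-filter core weight: the expected doublet profile about the centre
  shape <- function(d) exp(-(d - 0.01)^2 / (2 * 0.0165^2)) +
    exp(-(d + 0.01)^2 / (2 * 0.0165^2))
  null_centers <- null_centers[null_centers - flank[2] > min(ppm) &
                               null_centers + flank[2] < max(ppm)]
  slice <- function(lo, hi) {
    i <- findInterval(lo, ppm) + 1L
    j <- findInterval(hi, ppm)
    if (j < i) return(numeric(0))
    i:j
  }
  stat <- function(c0) {
    core <- slice(c0 - half_core, c0 + half_core)
    fl <- c(slice(c0 - flank[2], c0 - flank[1]), slice(c0 + flank[1], c0 + flank[2]))
    w <- shape(ppm[core] - c0)
    sum(w * y[core]) / sum(w) - mean(y[fl])
  }
  s0 <- vapply(null_centers, stat, numeric(1))
  stat(center) / sd(s0)
}

#' Fit-error statistic of a peak fit
#'
#' The standard deviation of the fit residual over the analyte-peak region,
#' expressed as a percentage of the fitted analyte peak amplitude.
#'
#' @param residuals Residuals (data minus model) over the analyte-peak
#'   region.
#' @param amplitude Fitted peak amplitude (height).
#' @return Fit error in percent; `Inf` when the amplitude is not positive.
#' @examples
#' compute_fit_error(rep(c(-0.19, 0.19), 50), 0.5) # = 38%, approximately
#' @export
compute_fit_error <- function(residuals, amplitude) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 || is.na(amplitude) ||
      amplitude <= 0) {
    return(Inf)
  }
  100 * sd(residuals) / amplitude
}

#' Quantify glutathione in a difference-edited spectrum
#'
#' Fits the real part of the difference spectrum in `fit_window` with a
#' 5-Gaussian model (components initialised at 2.82, 2.95, 3.01, 3.10 and
#' 3.26 ppm, centres bounded within +/-0.02 ppm, glutathione amplitude
#' constrained non-negative) plus a linear baseline, then fits a simple
#' single Gaussian to the glutathione peak after subtracting the resolved
#' co-edited components. The fit error is the SD of
#' the simple-fit residual over the analyte region (GSH centre +/- 0.1 ppm)
#' as a percentage of the fitted peak height. Glutathione is deemed
#' undetectable when the matched-filter detection z-score ([detection_z()])
#' falls below 4.5 or the fit error exceeds 200%.
#'
#' @param diff An `mrs_spectrum` from [difference_edit()].
#' @param fit_window ppm interval of the 5-Gaussian fit (default 2.6-3.3).
#' @param gsh_window ppm interval of the simple glutathione fit.
#' @param config Optional [pipeline_config()] overriding the defaults above.
#' @return An object of class `edited_fit` with the 5-Gaussian component
#'   table, the simple GSH component, baseline, `fit_error_pct`,
#'   `gsh_area` (from the simple fit, the default quantification),
#'   `gsh_area_5g` (from the 5-Gaussian component at 2.95 ppm),
#'   `noise_floor`, and `detectable`.
#' @export
fit_edited_gsh <- function(diff, fit_window = c(2.6, 3.3),
                           gsh_window = c(2.87, 3.03), config = NULL) {
  stopifnot(inherits(diff, "mrs_spectrum"))
  if (!is.null(config)) {
    fit_window <- config$edited_fit_window
    gsh_window <- config$gsh_fit_window
  }
  if (min(fit_window) < min(diff$ppm) || max(fit_window) > max(diff$ppm)) {
    abort("`fit_window` must lie inside the spectrum axis.",
          class = "gshmrs_param_error")
  }
  centers5 <- c(2.82, GSH_PPM, 3.01, 3.10, 3.26)
  idx <- in_window(diff, fit_window)
  x <- diff$ppm[idx]; y <- Re(diff$values[idx])
  amp_lower <- c(-Inf, 0, -Inf, -Inf, -Inf) # only GSH constrained >= 0
  widths <- c(0.012, 0.02, 0.035)
  fit5 <- fit_gaussian_multistart(x, y, centers5, amp_lower, widths,
                                  center_bound = 0.02,
                                  width_bounds = c(0.006, 0.03))
  failed5 <- is.null(fit5) || !fit5$converged

  # simple single-Gaussian quantification fit on the GSH peak, after
  # subtracting the resolved co-edited components of the 5-Gaussian model
  # (components overlapping the GSH line trade area with it and are left to
  # the simple fit's own linear baseline instead)
  idx_g <- in_window(diff, gsh_window)
  xg <- diff$ppm[idx_g]; yg <- Re(diff$values[idx_g])
  if (!failed5) {
    cf <- fit5$components
    for (k in which(abs(cf$center - GSH_PPM) > 0.1)) {
      yg <- yg - gauss_eval(xg, cf$amplitude[k], cf$center[k], cf$width[k])
    }
  }
  fit1 <- fit_gaussian_multistart(xg, yg, GSH_PPM, 0, widths_init = c(0.014, 0.025),
                                  center_bound = 0.03)
  failed1 <- is.null(fit1) || !fit1$converged
  if (failed1 && failed5) {
    return(structure(list(failed = TRUE, detectable = FALSE,
                          fit_error_pct = Inf),
                     class = "edited_fit"))
  }

  gsh1 <- fit1$components[1, ]
  region <- abs(xg - gsh1$center) <= 0.1
  fe <- compute_fit_error(fit1$residuals[region], gsh1$amplitude)
  floor_sd <- noise_floor(diff)
  dz <- detection_z(diff)
  detectable <- is.finite(fe) && fe <= 200 && is.finite(dz) && dz >= 4.5

  comp5 <- if (!failed5) {
    f <- fit5$components
    f$label <- c("coedit_2.82", "gsh", "coedit_3.01", "coedit_3.10", "coedit_3.26")
    f
  } else NULL

  structure(list(
    components = comp5,
    gsh_single = gsh1,
    baseline = fit1$baseline,
    baseline_5g = if (!failed5) fit5$baseline else NULL,
    fit_error_pct = fe,
    gsh_area = gsh1$area,
    gsh_area_5g = if (!failed5) comp5$area[comp5$label == "gsh"] else NA_real_,
    gsh_height = gsh1$amplitude,
    noise_floor = floor_sd,
    detection_z = dz,
    detectable = detectable,
    failed = FALSE,
    window = fit_window,
    data = tibble(ppm = xg, observed = yg, fitted = fit1$fitted,
                  residual = fit1$residuals),
    data_5g = if (!failed5) tibble(ppm = x, observed = y, fitted = fit5$fitted,
                                   residual = fit5$residuals) else NULL
  ), class = "edited_fit")
}

#' @export
print.edited_fit <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat("<edited_fit> FAILED\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<edited_fit> GSH %.4g (area, simple fit) at %.3f ppm; fit error %.1f%%; %s\n",
    x$gsh_area, x$gsh_single$center, x$fit_error_pct,
    if (x$detectable) "detectable" else "UNDETECTABLE"))
  invisible(x)
}

#' Fit the creatine reference peak
#'
#' Gaussian model of the creatine 3.03 ppm singlet in the (mean) OFF
#' sub-spectrum, with tightly centre-bounded companion components at 3.01
#' and 3.19 ppm absorbing the GABA-like neighbour and any choline edge, plus
#' a linear baseline. Fit error is computed over Cr centre +/- 0.1 ppm.
#'
#' @param off An `mrs_spectrum` (the OFF condition, or any spectrum carrying
#'   an isolated creatine singlet).
#' @param window Fit window in ppm.
#' @return An object of class `cr_fit` with `amplitude`, `center`, `width`,
#'   `area`, `fit_error_pct` and `usable`.
#' @export
fit_reference_cr <- function(off, window = c(2.9, 3.25)) {
  stopifnot(inherits(off, "mrs_spectrum"))
  idx <- in_window(off, window)
  x <- off$ppm[idx]; y <- Re(off$values[idx])
  # companion at 3.19 ppm absorbs any choline edge; unresolvable 3.01 ppm
  # signal is deliberately not modelled (it would trade area with creatine)
  centers <- c(CR_PPM, 3.19)
  fit <- fit_gaussian_multistart(x, y, centers, c(0, 0),
                                 widths_init = c(0.014, 0.025),
                                 center_bound = 0.015)
  if (is.null(fit) || !fit$converged) {
    return(structure(list(usable = FALSE, fit_error_pct = Inf),
                     class = "cr_fit"))
  }
  cr <- fit$components[1, ]
  region <- abs(x - cr$center) <= 0.08
  fe <- compute_fit_error(fit$residuals[region], cr$amplitude)
  usable <- cr$amplitude > 0 && is.finite(fe) &&
    cr$amplitude >= 2 * noise_floor(off)
  structure(list(
    amplitude = cr$amplitude, center = cr$center, width = cr$width,
    area = cr$area, fit_error_pct = fe, usable = usable,
    components = fit$components, baseline = fit$baseline,
    data = tibble(ppm = x, observed = y, fitted = fit$fitted,
                  residual = fit$residuals)
  ), class = "cr_fit")
}

#' @export
print.cr_fit <- function(x, ...) {
  if (!isTRUE(x$usable)) {
    cat("<cr_fit> unusable (no creatine reference)\n")
    return(invisible(x))
  }
  cat(sprintf("<cr_fit> area %.4g at %.3f ppm; fit error %.2f%%\n",
              x$area, x$center, x$fit_error_pct))
  invisible(x)
}

#' Glutathione-to-creatine ratio
#'
#' The edited glutathione area, corrected for the assumed editing efficiency,
#' divided by the creatine reference area. Scale-invariant under any global
#' rescaling of the raw data. Returns `NA` (no ratio) when GSH is
#' undetectable or either fit is unusable; imputation of undetectable
#' baselines happens at cohort level, not here.
#'
#' @param edited An [fit_edited_gsh()] result.
#' @param cr A [fit_reference_cr()] result.
#' @param editing_efficiency Editing efficiency assumed in the
#'   quantification (must match the acquisition's, default 0.74).
#' @param use_5g Use the 5-Gaussian GSH component area instead of the simple
#'   single-Gaussian fit (the default quantification uses the simple fit).
#' @return The GSH/Cr ratio, or `NA_real_`.
#' @export
gsh_cr_ratio <- function(edited, cr, editing_efficiency = 0.74, use_5g = FALSE) {
  stopifnot(inherits(edited, "edited_fit"), inherits(cr, "cr_fit"))
  if (isTRUE(edited$failed) || !isTRUE(edited$detectable) || !isTRUE(cr$usable)) {
    return(NA_real_)
  }
  area <- if (use_5g) edited$gsh_area_5g else edited$gsh_area
  (area / editing_efficiency) / cr$area
}

#' Per-scan quality flags
#'
#' Classifies one edited scan as `"ok"`, `"undetectable"` (no usable
#' glutathione peak; at baseline this triggers cohort-level imputation) or
#' `"insufficient_quality"` (failed/unusable fits, fit error above
#' `max_fit_error`, or a noise floor more than `noise_floor_factor` times the
#' cohort reference, the signature of a corrupted acquisition).
#'
#' @param edited An `edited_fit`.
#' @param cr A `cr_fit`.
#' @param noise_floor_ref Reference noise floor (e.g. the cohort median);
#'   `NULL` skips the noise-floor rule.
#' @param max_fit_error Fit-error exclusion threshold, percent.
#' @param noise_floor_factor Multiple of the reference noise floor above
#'   which a scan is excluded.
#' @return A single string flag.
#' @export
qc_scan <- function(edited, cr, noise_floor_ref = NULL, max_fit_error = 200,
                    noise_floor_factor = 4) {
  if (isTRUE(edited$failed) || !isTRUE(cr$usable)) return("insufficient_quality")
  if (!is.null(noise_floor_ref) && is.finite(noise_floor_ref) &&
      edited$noise_floor > noise_floor_factor * noise_floor_ref) {
    return("insufficient_quality")
  }
  if (!isTRUE(edited$detectable)) return("undetectable")
  if (edited$fit_error_pct > max_fit_error) return("insufficient_quality")
  "ok"
}

#' Serial consistency of fit errors within a subject
#'
#' The ratio of the largest to the smallest combined (GSH + Cr) fit error
#' across one subject's serial scans. In well-behaved data this stays below
#' about 2; because relative fit error scales inversely with the changing
#' glutathione level it is reported as a QC diagnostic rather than enforced
#' as an exclusion.
#'
#' @param fit_errors Numeric vector of combined fit errors (percent) for one
#'   subject's scans (non-finite entries are ignored).
#' @return The max/min factor (`NA` if fewer than 2 finite values).
#' @export
serial_fit_error_factor <- function(fit_errors) {
  fe <- fit_errors[is.finite(fit_errors)]
  if (length(fe) < 2) return(NA_real_)
  max(fe) / min(fe)
}
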