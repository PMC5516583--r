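#' Voxel tissue composition
#'
#' @param f_gm,f_wm,f_csf Grey-matter, white-matter and CSF fractions; each
#'   in \[0, 1\] and summing to 1 within 0.01.
#' @return A one-row tibble.
#' @export
voxel_composition <- function(f_gm, f_wm, f_csf) {
  if (any(c(f_gm, f_wm, f_csf) < 0) || any(c(f_gm, f_wm, f_csf) > 1)) {
    abort("Tissue fractions must lie in [0, 1].", class = "gshmrs_param_error")
  }
  if (abs(f_gm + f_wm + f_csf - 1) > 0.01) {
    abort("Tissue fractions must sum to 1 (within 0.01).",
          class = "gshmrs_param_error")
  }
  tibble(f_gm = f_gm, f_wm = f_wm, f_csf = f_csf)
}

#' Build a self-consistent PRESS basis set
#'
#' Simulates each metabolite at 1 IU with the same acquisition and
#' preprocessing as the data (zero-fill, exponential dampening), yielding
#' model spectra on the acquisition grid. The creatine unit area (real part
#' over a wide creatine window) is stored for water referencing.
#'
#' @param names Metabolite names (subset of `cr`, `naa`, `cho`, `glx`, `mi`);
#'   `cr` is required.
#' @param acq PRESS acquisition parameters.
#' @param fit_window ppm window of the basis fit.
#' @param broadening_hz,zero_fill_factor Preprocessing applied (must match
#'   the data pathway).
#' @return An object of class `press_basis`.
#' @export
make_basis_set <- function(names = c("cr", "naa", "cho", "glx", "mi"),
                           acq = acq_params(te_ms = 36, n_averages = 64),
                           fit_window = c(1.8, 4.2),
                           broadening_hz = 1.1, zero_fill_factor = 2) {
  if (!"cr" %in% names) {
    abort("The basis must include creatine (`cr`).", class = "gshmrs_param_error")
  }
  specs <- purrr::map(names, function(nm) {
    fid <- simulate_press(setNames(1, nm), acq, noise_model(0))
    preprocess_press(fid, broadening_hz, zero_fill_factor, remove_water = FALSE)
  })
  ppm <- specs[[1]]$ppm
  idx <- ppm >= min(fit_window) & ppm <= max(fit_window)
  B <- vapply(specs, function(s) Re(s$values[idx]), numeric(sum(idx)))
  B <- matrix(B, ncol = length(names), dimnames = list(NULL, names))
  if (qr(B)$rank < ncol(B)) {
    abort("Basis spectra are linearly dependent.", class = "gshmrs_structure_error")
  }
  # unit creatine area from the isolated 3.03 ppm singlet through the same
  # processing, integrated essentially completely (no neighbours in the
  # synthetic singlet spectrum), so the capture fraction matches the wide
  # integral used for the water peak
  singlet <- simulate_fid(
    metabolite_peaks("cr_303", CR_PPM, 1, 6, edit_behavior = "unedited"),
    acq, noise_model(0))
  singlet_spec <- preprocess_press(singlet, broadening_hz, zero_fill_factor,
                                   remove_water = FALSE,
                                   phase_window = c(2.8, 3.3))
  cr_i <- which(names == "cr")
  structure(list(
    names = names, B = B, ppm = ppm[idx], fit_window = fit_window,
    acq = acq, broadening_hz = broadening_hz,
    zero_fill_factor = zero_fill_factor,
    cr_unit_area = spectrum_area(singlet_spec, c(1.0, 5.0), "real")
  ), class = "press_basis")
}

# correlation of frequency-domain noise induced by exponential apodization
# and zero-filling of initially white time-domain noise
freq_noise_correlation <- function(n_acq, n_zf, broadening_hz, sw_hz,
                                   max_lag = 200) {
  t <- (seq_len(n_acq) - 1) / sw_hz
  w2 <- exp(-2 * pi * broadening_hz * t)
  lags <- 0:max_lag
  rho <- vapply(lags, function(k) sum(w2 * cos(2 * pi * k * t * sw_hz / n_zf)),
                numeric(1)) / sum(w2)
  rho
}

#' Fit a PRESS spectrum against a basis set
#'
#' Non-negative linear combination of the basis spectra plus a free quadratic
#' baseline, fitted to the real part over the basis window. Concentration
#' uncertainties (reported as Cramer-Rao-style percent bounds) come from the
#' linear-model covariance under the frequency-domain noise correlation that
#' the zero-filling and exponential dampening induce, with the marginal noise
#' SD estimated from a signal-free region. QC follows the standard gates:
#' creatine linewidth at most 0.1 ppm, SNR at least 5, creatine CRLB below
#' 20 percent.
#'
#' @param spectrum A preprocessed PRESS `mrs_spectrum` (water removed,
#'   zero-filled, dampened, phased) on the same grid as the basis.
#' @param basis A [make_basis_set()] object.
#' @param baseline_degree Polynomial baseline degree (default 2).
#' @return An object of class `press_fit` with `concentrations` (tibble of
#'   name, concentration, crlb_pct), `linewidth_ppm`, `snr`, `qc_pass`,
#'   and the creatine absolute area for water referencing.
#' @export
fit_press <- function(spectrum, basis, baseline_degree = 2) {
  stopifnot(inherits(spectrum, "mrs_spectrum"), inherits(basis, "press_basis"))
  idx <- spectrum$ppm >= min(basis$fit_window) & spectrum$ppm <= max(basis$fit_window)
  y <- Re(spectrum$values[idx])
  if (sum(idx) != nrow(basis$B)) {
    abort("Spectrum grid does not match the basis grid; preprocess identically.",
          class = "gshmrs_structure_error")
  }
  m <- ncol(basis$B)
  xs <- seq(-1, 1, length.out = length(y))
  P <- vapply(0:baseline_degree, function(d) xs^d, numeric(length(y)))
  scale_b <- max(abs(basis$B))
  X <- cbind(basis$B, P * scale_b)
  # non-negativity on metabolites only: baseline columns enter with both signs
  Xnn <- cbind(basis$B, P * scale_b, -P * scale_b)
  nn <- pracma::lsqnonneg(Xnn, y)$x
  kappa <- nn[seq_len(m)]
  resid <- y - as.vector(Xnn %*% nn)

  sigma <- noise_floor(spectrum, c(6.5, 8.5))
  rho <- freq_noise_correlation(basis$acq$n_points,
                                basis$acq$n_points * basis$zero_fill_factor,
                                basis$broadening_hz, basis$acq$sw_hz)
  nb <- length(y)
  lag <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  Sig <- matrix(0, nb, nb)
  known <- lag <= (length(rho) - 1)
  Sig[known] <- rho[lag[known] + 1]
  XtX <- crossprod(X)
  V <- sigma^2 * solve(XtX, t(X)) %*% Sig %*% X %*% solve(XtX)
  crlb_pct <- 100 * sqrt(pmax(diag(V)[seq_len(m)], 0)) /
    ifelse(kappa > 0, kappa, NA_real_)

  cr_i <- which(basis$names == "cr")
  lw <- tryCatch(measure_fwhm(spectrum, c(2.95, 3.12))$fwhm_ppm,
                 error = function(e) NA_real_)
  snr <- spectrum_height(spectrum, c(2.95, 3.12), "real") / sigma
  qc <- is.finite(lw) && lw <= 0.1 && snr >= 5 &&
    is.finite(crlb_pct[cr_i]) && crlb_pct[cr_i] < 20

  structure(list(
    concentrations = tibble(name = basis$names, concentration = kappa,
                            crlb_pct = crlb_pct),
    cr_concentration = kappa[cr_i],
    cr_crlb_pct = crlb_pct[cr_i],
    cr_area_abs = kappa[cr_i] * basis$cr_unit_area,
    linewidth_ppm = lw, snr = snr, qc_pass = qc,
    noise_sd = sigma, residual_sd = sd(resid),
    basis_names = basis$names
  ), class = "press_fit")
}

#' @export
print.press_fit <- function(x, ...) {
  cat(sprintf("<press_fit> Cr %.3f IU-equivalent (CRLB %.2f%%), LW %.3f ppm, SNR %.1f, QC %s\n",
              x$cr_concentration, x$cr_crlb_pct, x$linewidth_ppm, x$snr,
              if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

water_peak_area <- function(spec, window = c(2.2, 7.2)) {
  spectrum_area(spec, window, "real")
}

#' Estimate water T2 from two unsuppressed acquisitions
#'
#' `T2 = (TE_b - TE_a) / log(S_a / S_b)` from the water peak areas of two
#' spectra at distinct echo times.
#'
#' @param water_a,water_b `mrs_spectrum`s (or `mrs_fid`s, which are
#'   preprocessed without water removal) at two echo times carried in their
#'   `acq$te_ms`.
#' @return Water T2 in ms, or `NA_real_` (with a warning) when the areas do
#'   not decay with echo time.
#' @export
estimate_water_t2 <- function(water_a, water_b) {
  prep <- function(w) {
    if (inherits(w, "mrs_fid")) {
      w <- preprocess_press(w, remove_water = FALSE, phase_window = c(4.2, 5.2))
    }
    w
  }
  a <- prep(water_a); b <- prep(water_b)
  te_a <- a$acq$te_ms; te_b <- b$acq$te_ms
  if (te_a == te_b) {
    abort("Echo times are equal; water T2 is unidentifiable.",
          class = "gshmrs_param_error")
  }
  if (te_a > te_b) { tmp <- a; a <- b; b <- tmp; tmp <- te_a; te_a <- te_b; te_b <- tmp }
  s_a <- water_peak_area(a); s_b <- water_peak_area(b)
  if (!is.finite(s_a) || !is.finite(s_b) || s_a <= s_b || s_b <= 0) {
    warn("Water areas do not decay with echo time; T2 not estimable.")
    return(NA_real_)
  }
  (te_b - te_a) / log(s_a / s_b)
}

#' Water-referenced absolute creatine concentration
#'
#' Scales the fitted creatine area to the unsuppressed water peak,
#' extrapolated to TE 0 with the water T2, and multiplies by the water
#' concentration-equivalent [IU_WATER], yielding institutional units (IU)
#' that approximate mmol/l. Invariant to receiver gain, which scales both
#' areas together.
#'
#' @param press_fit A [fit_press()] result (must pass QC to be meaningful).
#' @param water An unsuppressed water `mrs_spectrum` (or `mrs_fid`), TE in
#'   its `acq$te_ms`.
#' @param water_t2_ms Water T2 from [estimate_water_t2()]; `Inf` applies no
#'   T2 correction.
#' @return Creatine concentration in IU, or `NA_real_` if water is missing.
#' @export
water_reference <- function(press_fit, water, water_t2_ms) {
  stopifnot(inherits(press_fit, "press_fit"))
  if (is.null(water) || !is.finite(water_t2_ms) && !is.infinite(water_t2_ms)) {
    return(NA_real_)
  }
  if (inherits(water, "mrs_fid")) {
    water <- preprocess_press(water, remove_water = FALSE,
                              phase_window = c(4.2, 5.2))
  }
  a0 <- water_peak_area(water) *
    (if (is.infinite(water_t2_ms)) 1 else exp(water$acq$te_ms / water_t2_ms))
  IU_WATER * press_fit$cr_area_abs / a0
}

#' Partial-volume (CSF) correction
#'
#' Rescales a measured concentration for the CSF fraction of the voxel,
#' `c / (1 - f_csf)`: CSF contributes negligible metabolite signal, so the
#' measured value is diluted by the non-tissue fraction and corrected
#' upward. Identity at `f_csf = 0`, monotone increasing in `f_csf`.
#'
#' @param c_measured Measured concentration (IU).
#' @param f_csf CSF fraction in \[0, 1), or a [voxel_composition()] row.
#' @return Corrected concentration (IU).
#' @examples
#' csf_correct(5.05, 0.17) # 6.08
#' @export
csf_correct <- function(c_measured, f_csf) {
  if (is.data.frame(f_csf)) f_csf <- f_csf$f_csf
  if (any(f_csf < 0 | f_csf >= 1)) {
    abort("`f_csf` must lie in [0, 1).", class = "gshmrs_param_error")
  }
  c_measured / (1 - f_csf)
}

#' Absolute glutathione concentration
#'
#' The GSH/Cr ratio multiplied by the CSF-corrected absolute creatine
#' concentration.
#'
#' @param gsh_cr GSH/Cr ratio.
#' @param cr_corrected CSF-corrected creatine concentration (IU).
#' @return Absolute GSH in IU (`NA` if either input is missing).
#' @examples
#' absolute_gsh(0.0170, 6.41) # 0.109
#' @export
absolute_gsh <- function(gsh_cr, cr_corrected) {
  ifelse(is.na(gsh_cr) | is.na(cr_corrected), NA_real_, gsh_cr * cr_corrected)
}
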