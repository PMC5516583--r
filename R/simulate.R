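#' @rdname gshmrs_defaults
#' @format NULL
#' @export
GSH_PPM <- 2.95

#' @rdname gshmrs_defaults
#' @format NULL
#' @export
CR_PPM <- 3.03

#' Package-wide spectroscopy constants
#'
#' `GSH_PPM` (2.95) is the chemical shift of the cysteinyl beta-CH2 resonance
#' of glutathione that survives spectral editing; `CR_PPM` (3.03) the creatine
#' methyl singlet used as the in-voxel reference; `IU_WATER` the water
#' concentration-equivalent used for water referencing: 55,510 mmol/l of
#' protons-equivalent scaled by a 0.7 tissue-water attenuation factor, so
#' water-referenced values come out in institutional units (IU) that
#' approximate mmol/l.
#' @name gshmrs_defaults
#' @format NULL
#' @export
IU_WATER <- 55510 * 0.7

#' Simulate a free induction decay from a peak table
#'
#' Forward model: each peak contributes a damped complex exponential
#' `a * exp(1i*phase) * exp((2i*pi*df - d) * t)` with `df` the Hz offset of
#' its centre from the reference and `d` its damping (Hz), sampled at the
#' dwell time; independent complex Gaussian noise is added per point.
#'
#' @param peaks Peak tibble from [metabolite_peaks()] (the `edit_behavior`
#'   column is ignored here; all rows are rendered).
#' @param acq An [acq_params()] object.
#' @param noise A [noise_model()]; `freq_jitter_sd`/`phase_jitter_sd` draw a
#'   single whole-transient offset each.
#' @param provenance Provenance label stored on the FID.
#'
#' @return An `mrs_fid` of length `acq$n_points`.
#' @examples
#' fid <- simulate_fid(metabolite_peaks("cr", 3.03, 1, 6), acq_params(), noise_model(0))
#' @export
simulate_fid <- function(peaks, acq, noise = noise_model(0), provenance = "PRESS") {
  stopifnot(inherits(acq, "acq_params"), inherits(noise, "noise_model"))
  validate_peaks(peaks, acq)
  t <- (seq_len(acq$n_points) - 1) * dwell_time(acq)
  s <- complex(real = rep(0, acq$n_points))
  df_jit <- if (noise$freq_jitter_sd > 0) rnorm(1, 0, noise$freq_jitter_sd) else 0
  ph_jit <- if (noise$phase_jitter_sd > 0) rnorm(1, 0, noise$phase_jitter_sd) else 0
  if (nrow(peaks) > 0) {
    for (k in seq_len(nrow(peaks))) {
      df <- (peaks$center_ppm[k] - acq$ref_ppm) * acq$f0_mhz + df_jit
      s <- s + peaks$amplitude[k] *
        exp(1i * (peaks$phase[k] + ph_jit)) *
        exp((2i * pi * df - peaks$damping_hz[k]) * t)
    }
  }
  if (noise$noise_sd > 0) {
    s <- s + complex(real = rnorm(acq$n_points, 0, noise$noise_sd),
                     imaginary = rnorm(acq$n_points, 0, noise$noise_sd))
  }
  new_fid(s, acq, provenance, "simulate_fid")
}

#' Default co-edited contaminant peaks
#'
#' The resonances that, besides glutathione, partially survive the editing
#' scheme and appear in the difference spectrum (the "co-edited molecules" a
#' 5-Gaussian model must absorb). Amplitudes are in creatine units.
#'
#' @return A peak tibble of four `"edited"` rows at 2.82, 3.01, 3.10 and
#'   3.26 ppm.
#' @export
default_coedited_peaks <- function() {
  metabolite_peaks(
    name = c("asp_coedit", "gaba_coedit", "coedit_a", "coedit_b"),
    center_ppm = c(2.82, 3.01, 3.10, 3.26),
    amplitude = c(0.02, 0.004, 0.015, 0.02),
    damping_hz = c(5, 5, 6, 6),
    edit_behavior = "edited",
    editing_efficiency = c(0.30, 0.08, 0.40, 0.40)
  )
}

#' Background (non-edited) peaks of the edited acquisition
#'
#' The resonances that are identical in the ON and OFF sub-spectra and so
#' cancel in the difference: creatine at 3.03 ppm with GABA-like (3.01 ppm)
#' and aspartate-like (2.82 ppm) neighbours, plus the large common peaks a
#' real OFF sub-spectrum carries (NAA 2.01, choline 3.19, myo-inositol
#' 3.56 ppm), which anchor the frequency/phase registration.
#'
#' @param cr_amplitude Creatine time-domain amplitude (the unit all edited
#'   amplitudes are expressed in).
#' @return A peak tibble of `"suppressed"` rows.
#' @export
megapress_background_peaks <- function(cr_amplitude = 1) {
  metabolite_peaks(
    name = c("cr", "gaba", "asp", "naa", "cho", "mi"),
    center_ppm = c(3.03, 3.01, 2.82, 2.01, 3.19, 3.56),
    amplitude = cr_amplitude * c(1, 0.02, 0.15, 1.4, 0.25, 0.5),
    damping_hz = c(6, 8, 9, 7, 6, 8),
    edit_behavior = "suppressed"
  )
}

megapress_peak_tables <- function(gsh_cr_true, editing_efficiency, coedited,
                                  cr_amplitude = 1, gain = 1,
                                  gsh_split = 0.02) {
  if (editing_efficiency < 0 || editing_efficiency > 1) {
    abort("`editing_efficiency` must lie in [0, 1].", class = "gshmrs_param_error")
  }
  if (gsh_cr_true < 0) {
    abort("`gsh_cr_true` must be >= 0.", class = "gshmrs_param_error")
  }
  # the edited cysteinyl CH2 resonance is not a clean singlet: it is
  # rendered as a narrowly split symmetric doublet about 2.95 ppm
  gsh <- metabolite_peaks(c("gsh_a", "gsh_b"),
                          GSH_PPM + c(-1, 1) * gsh_split / 2,
                          gsh_cr_true * cr_amplitude / 2, 6,
                          edit_behavior = "edited",
                          editing_efficiency = editing_efficiency)
  pk <- dplyr::bind_rows(gsh, megapress_background_peaks(cr_amplitude), coedited)
  pk$amplitude <- pk$amplitude * gain
  on <- pk[pk$edit_behavior != "unedited", ]
  off <- on
  edited <- off$edit_behavior == "edited"
  off$amplitude[edited] <- off$amplitude[edited] * (1 - off$editing_efficiency[edited])
  list(on = on, off = off)
}

#' Simulate one MEGA-PRESS ON/OFF transient pair
#'
#' The editing pulse refocuses glutathione J-evolution in ON acquisitions;
#' in OFF acquisitions the GSH line evolves, retaining amplitude
#' `a * (1 - editing_efficiency)`, so the OFF-ON difference carries
#' `a * editing_efficiency`. Background creatine/GABA-like/aspartate-like
#' lines are identical in both members and cancel; co-edited contaminants
#' subtract per their own efficiencies.
#'
#' @param gsh_cr_true True glutathione-to-creatine amplitude ratio.
#' @param editing_efficiency Fraction of the GSH amplitude surviving in the
#'   difference (default 0.74, a conventional editing efficiency).
#' @param coedited Peak tibble of co-edited contaminants (possibly empty);
#'   see [default_coedited_peaks()].
#' @param acq,noise Acquisition and noise settings.
#' @param cr_amplitude Creatine time-domain amplitude.
#' @param gain Overall receiver gain multiplying every amplitude; ratio
#'   quantification must be invariant to it.
#' @return A list with `mrs_fid` elements `on` and `off`.
#' @examples
#' pair <- simulate_megapress_pair(0.04, coedited = NULL)
#' @export
simulate_megapress_pair <- function(gsh_cr_true, editing_efficiency = 0.74,
                                    coedited = default_coedited_peaks(),
                                    acq = acq_params(), noise = noise_model(0),
                                    cr_amplitude = 1, gain = 1) {
  pk <- megapress_peak_tables(gsh_cr_true, editing_efficiency, coedited,
                              cr_amplitude, gain)
  list(on = simulate_fid(pk$on, acq, noise, provenance = "ON"),
       off = simulate_fid(pk$off, acq, noise, provenance = "OFF"))
}

#' Simulate a full MEGA-PRESS scan (block of stored averages)
#'
#' Generates `n_pairs` independent ON/OFF transient pairs with per-transient
#' noise and frequency/phase jitter, as the alignment step sees them.
#'
#' @inheritParams simulate_megapress_pair
#' @param n_pairs Number of stored ON/OFF average pairs.
#' @return A list with fields `on` and `off`, each a list of `mrs_fid`.
#' @export
simulate_megapress_scan <- function(gsh_cr_true, editing_efficiency = 0.74,
                                    coedited = default_coedited_peaks(),
                                    acq = acq_params(), noise = noise_model(0),
                                    n_pairs = 8, cr_amplitude = 1, gain = 1) {
  pk <- megapress_peak_tables(gsh_cr_true, editing_efficiency, coedited,
                              cr_amplitude, gain)
  list(
    on = purrr::map(seq_len(n_pairs),
                    function(i) simulate_fid(pk$on, acq, noise, provenance = "ON")),
    off = purrr::map(seq_len(n_pairs),
                     function(i) simulate_fid(pk$off, acq, noise, provenance = "OFF"))
  )
}

press_metabolite_library <- function() {
  list(
    cr  = metabolite_peaks(c("cr_303", "cr_391"), c(3.03, 3.91), c(1, 0.7),
                           c(6, 7), edit_behavior = "unedited"),
    naa = metabolite_peaks(c("naa_201", "naa_249"), c(2.01, 2.49), c(1, 0.15),
                           c(6, 9), edit_behavior = "unedited"),
    cho = metabolite_peaks("cho_319", 3.19, 1, 6, edit_behavior = "unedited"),
    glx = metabolite_peaks(c("glx_235", "glx_375"), c(2.35, 3.75), c(0.4, 0.3),
                           c(10, 10), edit_behavior = "unedited"),
    mi  = metabolite_peaks("mi_356", 3.56, 0.6, 8, edit_behavior = "unedited")
  )
}

#' Simulate a short-echo PRESS acquisition
#'
#' Renders one line set per named metabolite at an amplitude proportional to
#' its concentration (IU), plus a configurable residual-water component near
#' 4.7 ppm left over from water suppression.
#'
#' @param concentrations Named numeric vector of concentrations in IU; names
#'   must come from `cr`, `naa`, `cho`, `glx`, `mi`. Creatine drives the
#'   reference, so include `cr` for quantification.
#' @param acq Acquisition parameters; the study protocol is TE 36 ms with 64
#'   averages.
#' @param noise A [noise_model()].
#' @param residual_water_iu Amplitude of the residual water line, on the same
#'   concentration scale (0 disables it).
#' @param gain Receiver gain multiplying all amplitudes.
#' @return An `mrs_fid` with provenance `"PRESS"`.
#' @examples
#' fid <- simulate_press(c(cr = 6.09, naa = 8))
#' @export
simulate_press <- function(concentrations,
                           acq = acq_params(te_ms = 36, n_averages = 64),
                           noise = noise_model(0), residual_water_iu = 0,
                           gain = 1) {
  lib <- press_metabolite_library()
  bad <- setdiff(names(concentrations), names(lib))
  if (length(bad) > 0 || is.null(names(concentrations))) {
    abort(paste0("Unknown metabolite name(s): ",
                 paste(bad, collapse = ", "),
                 ". Known: ", paste(names(lib), collapse = ", "), "."),
          class = "gshmrs_param_error")
  }
  if (any(concentrations < 0)) {
    abort("Concentrations must be >= 0.", class = "gshmrs_param_error")
  }
  pk <- purrr::imap(as.list(concentrations), function(conc, nm) {
    p <- lib[[nm]]
    p$amplitude <- p$amplitude * conc
    p
  })
  pk <- dplyr::bind_rows(pk)
  if (residual_water_iu > 0) {
    pk <- dplyr::bind_rows(pk, metabolite_peaks("water_residual", 4.70,
                                                residual_water_iu, 18,
                                                edit_behavior = "unedited"))
  }
  pk$amplitude <- pk$amplitude * gain
  simulate_fid(pk, acq, noise, provenance = "PRESS")
}

#' Simulate unsuppressed water spectra at two echo times
#'
#' The water line amplitude decays as `exp(-TE / water_t2)`, so the two
#' acquisitions determine the water T2 and allow extrapolation of the water
#' reference to TE 0.
#'
#' @param water_t2_ms Water transverse relaxation time, ms; must be > 0.
#' @param te_ms Length-2 vector of distinct echo times, ms (study protocol:
#'   68 and 122 ms).
#' @param acq Base acquisition parameters (TE is overridden per member).
#' @param noise A [noise_model()].
#' @param gain Receiver gain.
#' @return A list of two `mrs_fid`s (`a`, `b`), provenance `"WATER"`, whose
#'   `acq$te_ms` carry the respective echo times. Water amplitude at TE 0 is
#'   `gain * IU_WATER` so that water referencing yields IU.
#' @export
simulate_water_pair <- function(water_t2_ms = 80, te_ms = c(68, 122),
                                acq = acq_params(n_averages = 8),
                                noise = noise_model(0), gain = 1) {
  if (!is.numeric(water_t2_ms) || water_t2_ms <= 0) {
    abort("`water_t2_ms` must be > 0.", class = "gshmrs_param_error")
  }
  if (length(te_ms) != 2 || te_ms[1] == te_ms[2]) {
    abort("Two distinct echo times are required (water T2 unidentifiable).",
          class = "gshmrs_param_error")
  }
  one <- function(te) {
    a <- acq
    a$te_ms <- te
    pk <- metabolite_peaks("water", 4.70, gain * IU_WATER * exp(-te / water_t2_ms),
                           12, edit_behavior = "unedited")
    simulate_fid(pk, a, noise, provenance = "WATER")
  }
  list(a = one(te_ms[1]), b = one(te_ms[2]))
}
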