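#' Acquisition parameters for a single-voxel MRS scan
#'
#' Bundles the timing and sampling parameters of one acquisition. Defaults
#' reproduce the edited (MEGA-PRESS) protocol used throughout the package:
#' TR 2000 ms, TE 122 ms, 2048 complex points over a 2000 Hz spectral width
#' on a 3 T system (127.7 MHz), with the spectrum referenced to water at
#' 4.7 ppm.
#'
#' @param tr_ms Repetition time in milliseconds.
#' @param te_ms Echo time in milliseconds.
#' @param n_points Number of complex time-domain points acquired (before any
#'   zero-filling). Must be a positive power of two.
#' @param sw_hz Spectral width (sampling rate) in Hz; dwell time is `1/sw_hz`.
#' @param n_averages Number of stored averages.
#' @param f0_mhz Transmitter frequency in MHz; converts ppm offsets to Hz.
#' @param ref_ppm Chemical shift assigned to the centre of the spectrum
#'   (water, 4.7 ppm).
#'
#' @return An object of class `acq_params`.
#' @examples
#' acq_params()
#' acq_params(te_ms = 36, n_averages = 64) # short-echo PRESS protocol
#' @export
acq_params <- function(tr_ms = 2000, te_ms = 122, n_points = 2048,
                       sw_hz = 2000, n_averages = 8, f0_mhz = 127.7,
                       ref_ppm = 4.7) {
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points <= 0 ||
      n_points != round(n_points) || bitwAnd(as.integer(n_points), as.integer(n_points) - 1L) != 0L) {
    abort("`n_points` must be a positive power of two.", class = "gshmrs_param_error")
  }
  if (!is.numeric(sw_hz) || sw_hz <= 0) {
    abort("`sw_hz` must be a positive spectral width in Hz.", class = "gshmrs_param_error")
  }
  if (tr_ms <= 0 || te_ms < 0 || n_averages < 1 || f0_mhz <= 0) {
    abort("Invalid acquisition timing parameters.", class = "gshmrs_param_error")
  }
  structure(
    list(tr_ms = tr_ms, te_ms = te_ms, n_points = as.integer(n_points),
         sw_hz = sw_hz, n_averages = as.integer(n_averages),
         f0_mhz = f0_mhz, ref_ppm = ref_ppm),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "<acq_params> TR %g ms, TE %g ms, %d pts, SW %g Hz, %d avg, %g MHz, ref %g ppm\n",
    x$tr_ms, x$te_ms, x$n_points, x$sw_hz, x$n_averages, x$f0_mhz, x$ref_ppm))
  invisible(x)
}

#' Dwell time of an acquisition
#' @param acq An [acq_params()] object.
#' @return Dwell time in seconds (`1/sw_hz`).
#' @export
dwell_time <- function(acq) 1 / acq$sw_hz

#' Metabolite peak table
#'
#' Builds the tibble of resonances used by the simulators. Each row is one
#' Lorentzian line: a damped complex exponential in the time domain.
#' `edit_behavior` states how the line responds to the editing pulse:
#' `"edited"` lines appear at full amplitude in ON and at
#' `amplitude * (1 - editing_efficiency)` in OFF, so the ON/OFF difference
#' retains `amplitude * editing_efficiency`; `"suppressed"` lines are
#' identical in ON and OFF and cancel in the difference; `"unedited"` lines
#' appear only in non-edited (PRESS-type) acquisitions.
#'
#' @param name Character label per peak.
#' @param center_ppm Chemical shift of the line centre (ppm).
#' @param amplitude Non-negative, concentration-proportional time-domain
#'   amplitude (equal to the integral of the frequency-domain line, up to a
#'   fixed transform constant).
#' @param damping_hz Lorentzian decay rate in Hz; the frequency-domain full
#'   width at half maximum is `damping_hz / pi` Hz.
#' @param phase Zero-order phase of the line, radians.
#' @param edit_behavior One of `"edited"`, `"suppressed"`, `"unedited"`.
#' @param editing_efficiency Fraction (0-1) of the line amplitude retained in
#'   the ON-OFF difference; only meaningful for `"edited"` rows.
#'
#' @return A tibble with one row per peak.
#' @examples
#' metabolite_peaks(name = "cr", center_ppm = 3.03, amplitude = 1, damping_hz = 6)
#' @export
metabolite_peaks <- function(name, center_ppm, amplitude, damping_hz,
                             phase = 0, edit_behavior = "suppressed",
                             editing_efficiency = 0) {
  pk <- tibble(
    name = as.character(name), center_ppm = center_ppm,
    amplitude = amplitude, damping_hz = damping_hz, phase = phase,
    edit_behavior = edit_behavior, editing_efficiency = editing_efficiency
  )
  validate_peaks(pk)
  pk
}

validate_peaks <- function(peaks, acq = NULL) {
  if (nrow(peaks) == 0) return(invisible(peaks))
  if (any(peaks$amplitude < 0)) {
    abort("Peak amplitudes must be >= 0.", class = "gshmrs_param_error")
  }
  if (any(peaks$damping_hz <= 0)) {
    abort("Peak damping must be > 0 Hz.", class = "gshmrs_param_error")
  }
  if (!all(peaks$edit_behavior %in% c("edited", "suppressed", "unedited"))) {
    abort("`edit_behavior` must be edited, suppressed or unedited.",
          class = "gshmrs_param_error")
  }
  if (any(peaks$editing_efficiency < 0 | peaks$editing_efficiency > 1)) {
    abort("`editing_efficiency` must lie in [0, 1].", class = "gshmrs_param_error")
  }
  if (!is.null(acq)) {
    half_ppm <- acq$sw_hz / 2 / acq$f0_mhz
    lo <- acq$ref_ppm - half_ppm
    hi <- acq$ref_ppm + half_ppm
    if (any(peaks$center_ppm <= lo | peaks$center_ppm >= hi)) {
      abort("Peak centres must lie inside the spectral window.",
            class = "gshmrs_param_error")
    }
  }
  invisible(peaks)
}

#' Noise and instability model for simulated transients
#'
#' @param noise_sd Standard deviation of the independent complex Gaussian
#'   noise added to each time-domain point (same SD on the real and
#'   imaginary parts), per stored average.
#' @param freq_jitter_sd Per-transient frequency offset SD, Hz.
#' @param phase_jitter_sd Per-transient zero-order phase offset SD, radians.
#'
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(0)                  # noiseless
#' noise_model(0.002, 1.5, 0.12)   # realistic drift
#' @export
noise_model <- function(noise_sd = 0, freq_jitter_sd = 0, phase_jitter_sd = 0) {
  if (noise_sd < 0 || freq_jitter_sd < 0 || phase_jitter_sd < 0) {
    abort("Noise model SDs must be >= 0.", class = "gshmrs_param_error")
  }
  structure(list(noise_sd = noise_sd, freq_jitter_sd = freq_jitter_sd,
                 phase_jitter_sd = phase_jitter_sd),
            class = "noise_model")
}
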