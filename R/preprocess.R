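#' Average a list of FIDs
#'
#' @param fids Non-empty list of `mrs_fid`s on the same grid.
#' @param provenance Provenance label of the result.
#' @return The point-wise mean `mrs_fid`.
#' @export
average_fids <- function(fids, provenance = fids[[1]]$provenance) {
  stopifnot(length(fids) > 0)
  n <- unique(purrr::map_int(fids, function(f) length(f$samples)))
  if (length(n) != 1) {
    abort("All FIDs must have the same length.", class = "gshmrs_structure_error")
  }
  s <- Reduce(`+`, purrr::map(fids, "samples")) / length(fids)
  new_fid(s, fids[[1]]$acq, provenance,
          c(fids[[1]]$history, sprintf("average(%d)", length(fids))))
}

#' Frequency- and phase-align individual transients
#'
#' Spectral registration in the time domain: each transient is aligned to the
#' point-wise median transient by a rigid frequency shift and zero-order
#' phase, found by maximising the magnitude of the inner product with the
#' reference over candidate shifts (the optimal phase for a given shift is
#' analytic). Transients whose normalised correlation with the reference
#' stays below `min_correlation` (no usable reference peak) are flagged and
#' passed through uncorrected.
#'
#' @param transients List of `mrs_fid`s (e.g. all ON and OFF averages of one
#'   scan).
#' @param max_shift_hz Search range for the frequency shift.
#' @param n_fit_points Number of initial time-domain points used for
#'   registration (the high-signal part of the FID).
#' @param min_correlation Flagging threshold on the normalised correlation.
#' @param exclude_band Soft Gaussian notch (centre, sigma in ppm) suppressing
#'   spectral content that legitimately differs between editing conditions
#'   (the edited glutathione resonance and its co-edited neighbours) from the
#'   registration signals, so it cannot steer the alignment. The applied
#'   correction is still rigid over the whole spectrum. `NULL` registers on
#'   the full spectrum.
#' @return The list of corrected `mrs_fid`s, with a tibble of per-transient
#'   corrections (`shift_hz`, `phase_rad`, `flagged`) in attribute
#'   `"corrections"`.
#' @export
correct_frequency_phase <- function(transients, max_shift_hz = 8,
                                    n_fit_points = 384, min_correlation = 0.5,
                                    exclude_band = c(2.95, 0.12)) {
  stopifnot(length(transients) > 0)
  nfull <- length(transients[[1]]$samples)
  filt <- function(smp) smp
  if (!is.null(exclude_band)) {
    acq <- transients[[1]]$acq
    freq <- c(seq(0, nfull / 2 - 1), seq(-nfull / 2, -1)) * acq$sw_hz / nfull
    ppm <- acq$ref_ppm + freq / acq$f0_mhz
    W <- 1 - exp(-(ppm - exclude_band[1])^2 / (2 * exclude_band[2]^2))
    filt <- function(smp) fft(fft(smp) * W, inverse = TRUE) / nfull
  }
  npt <- min(n_fit_points, nfull)
  t <- fid_times(transients[[1]])[seq_len(npt)]
  mat <- vapply(transients, function(f) filt(f$samples)[seq_len(npt)],
                complex(npt))
  mat <- matrix(mat, nrow = npt)
  ref <- complex(real = apply(Re(mat), 1, median),
                 imaginary = apply(Im(mat), 1, median))
  ref_norm <- sqrt(sum(Mod(ref)^2))

  score <- function(df, s) {
    u <- s * exp(2i * pi * df * t)
    Mod(sum(u * Conj(ref)))
  }
  out <- vector("list", length(transients))
  corr <- tibble(shift_hz = numeric(length(transients)),
                 phase_rad = numeric(length(transients)),
                 flagged = logical(length(transients)))
  for (k in seq_along(transients)) {
    s <- mat[, k]
    grid <- seq(-max_shift_hz, max_shift_hz, by = 1)
    sc <- vapply(grid, score, numeric(1), s = s)
    j <- which.max(sc)
    lo <- grid[max(1, j - 1)]; hi <- grid[min(length(grid), j + 1)]
    opt <- optimize(function(df) -score(df, s), lower = lo, upper = hi)
    df <- opt$minimum
    u <- s * exp(2i * pi * df * t)
    ip <- sum(u * Conj(ref))
    phi <- -Arg(ip)
    rho <- Mod(ip) / (sqrt(sum(Mod(u)^2)) * ref_norm)
    if (!is.finite(rho) || rho < min_correlation) {
      corr$flagged[k] <- TRUE
      out[[k]] <- transients[[k]]
      next
    }
    corr$shift_hz[k] <- df
    corr$phase_rad[k] <- phi
    f <- transients[[k]]
    tf <- fid_times(f)
    f$samples <- f$samples * exp(1i * (2 * pi * df * tf + phi))
    out[[k]] <- record_step(f, sprintf("align(%.3f Hz, %.3f rad)", df, phi))
  }
  attr(out, "corrections") <- corr
  out
}

hsvd_components <- function(y, dt, n_est = 512, rank = 16) {
  m <- min(n_est, length(y))
  yk <- y[seq_len(m)]
  L <- m %/% 2
  H <- matrix(0i, nrow = L, ncol = m - L + 1)
  for (i in seq_len(L)) H[i, ] <- yk[i:(i + m - L)]
  sv <- svd(H, nu = rank, nv = 0)
  U <- sv$u
  # shift-invariance of the signal subspace gives the pole matrix
  Ub <- U[-L, , drop = FALSE]
  Ut <- U[-1, , drop = FALSE]
  Z <- qr.solve(Ub, Ut)
  z <- eigen(Z, only.values = TRUE)$values
  tibble(
    freq_hz = Arg(z) / (2 * pi * dt),
    damping_hz = -log(Mod(z)) / dt
  ) |> dplyr::mutate(pole = z)
}

#' Remove residual water by time-domain decomposition
#'
#' Fits a small number of decaying complex exponentials (Hankel-SVD
#' subspace estimation) and subtracts those whose frequency falls in the
#' water band, leaving the metabolite region essentially untouched.
#'
#' @param x An `mrs_fid` or `mrs_spectrum` (returned in kind).
#' @param water_band ppm interval treated as water (default 4.4-5.0).
#' @param rank Signal-subspace rank for the decomposition (at most 8
#'   components end up subtracted).
#' @param max_components Maximum number of water components subtracted.
#' @return Object of the same class with the water components removed. If the
#'   decomposition fails (rank deficiency), the input is returned unchanged
#'   with attribute `water_removal_failed = TRUE` and a warning.
#' @export
remove_residual_water <- function(x, water_band = c(4.4, 5.0), rank = 16,
                                  max_components = 8) {
  is_spec <- inherits(x, "mrs_spectrum")
  fid <- if (is_spec) from_spectrum(x) else x
  stopifnot(inherits(fid, "mrs_fid"))
  dt <- dwell_time(fid$acq)
  acq <- fid$acq
  band_hz <- sort((water_band - acq$ref_ppm) * acq$f0_mhz)
  comp <- tryCatch(hsvd_components(fid$samples, dt, rank = rank),
                   error = function(e) NULL)
  if (is.null(comp)) {
    warn("Water decomposition failed; returning input unchanged.")
    attr(x, "water_removal_failed") <- TRUE
    return(x)
  }
  # damping capped: very broad poles model the spectrum-wide offset of the
  # one-sided FID rather than actual water, and subtracting them perturbs
  # the metabolite region
  sel <- comp$freq_hz >= band_hz[1] & comp$freq_hz <= band_hz[2] &
    comp$damping_hz > 0 & comp$damping_hz < 60
  comp <- comp[sel, , drop = FALSE]
  if (nrow(comp) == 0) {
    out_fid <- record_step(fid, "remove_residual_water(none found)")
    return(if (is_spec) to_spectrum(out_fid) else out_fid)
  }
  if (nrow(comp) > max_components) {
    comp <- comp[order(-comp$damping_hz)[seq_len(max_components)], , drop = FALSE]
  }
  tt <- fid_times(fid)
  V <- vapply(seq_len(nrow(comp)),
              function(k) exp((2i * pi * comp$freq_hz[k] - comp$damping_hz[k]) * tt),
              complex(length(tt)))
  V <- matrix(V, ncol = nrow(comp))
  amp <- tryCatch(qr.solve(V, fid$samples), error = function(e) NULL)
  if (is.null(amp)) {
    warn("Water component amplitude fit failed; returning input unchanged.")
    attr(x, "water_removal_failed") <- TRUE
    return(x)
  }
  # only subtract components clearly above the noise: the subspace method
  # will happily fit pure-noise exponentials in the water band, and
  # subtracting those perturbs the metabolite region for nothing
  tail_idx <- seq(max(1, length(tt) - 255), length(tt))
  sigma_t <- sd(c(Re(fid$samples[tail_idx]), Im(fid$samples[tail_idx])))
  keep <- Mod(amp) > 30 * max(sigma_t, .Machine$double.eps)
  if (!any(keep)) {
    out_fid <- record_step(fid, "remove_residual_water(none above noise)")
    return(if (is_spec) to_spectrum(out_fid) else out_fid)
  }
  fid$samples <- fid$samples - as.vector(V[, keep, drop = FALSE] %*% amp[keep])
  comp <- comp[keep, , drop = FALSE]
  fid <- record_step(fid, sprintf("remove_residual_water(%d comp)", nrow(comp)))
  if (is_spec) to_spectrum(fid) else fid
}

# standard first-point correction: halving the t = 0 sample makes the
# discrete transform of a one-sided decay match the continuous lineshape
# (trapezoid rule) and removes the constant baseline offset it otherwise
# spreads over every bin
halve_first_point <- function(fid) {
  fid$samples[1] <- fid$samples[1] / 2
  record_step(fid, "halve_first_point")
}

# zero-order phase that makes the largest magnitude bin in `window` real
# and positive; returns the angle to pass to phase_correct()
phase_from_peak <- function(spec, window) {
  idx <- which(in_window(spec, window))
  k <- idx[which.max(Mod(spec$values[idx]))]
  ppm_k <- spec$ppm[k]
  near <- which(abs(spec$ppm - ppm_k) <= 0.05)
  # magnitude-weighted average phase over the peak core (robust to noise)
  Arg(sum(spec$values[near] * Mod(spec$values[near])))
}

#' Preprocess one edited (MEGA-PRESS) scan
#'
#' The edited pathway: 3 Hz exponential line broadening of every stored
#' average, frequency- and phase-alignment of the individual transients
#' (ON and OFF together, against their shared median), averaging per
#' condition, zero-filling, Fourier transform, and a common zero-order phase
#' taken from the creatine peak of the OFF spectrum (applied identically to
#' both so the subtraction stays valid).
#'
#' @param scan A list with `on` and `off` lists of `mrs_fid`s, as produced by
#'   [simulate_megapress_scan()] (a single pair also works).
#' @param broadening_hz Exponential line broadening (default 3 Hz).
#' @param zero_fill_factor Zero-filling factor (default 2).
#' @param align Logical; set `FALSE` to skip transient alignment (e.g. for
#'   noiseless single pairs).
#' @return A list with `mrs_spectrum` fields `on` and `off` plus the
#'   alignment `corrections` tibble.
#' @export
preprocess_edited_scan <- function(scan, broadening_hz = 3, zero_fill_factor = 2,
                                   align = TRUE) {
  on <- scan$on; off <- scan$off
  if (inherits(on, "mrs_fid")) on <- list(on)
  if (inherits(off, "mrs_fid")) off <- list(off)
  all_t <- purrr::map(c(on, off), apodize, broadening_hz = broadening_hz)
  corrections <- NULL
  if (align && length(all_t) > 1) {
    all_t <- correct_frequency_phase(all_t)
    corrections <- attr(all_t, "corrections")
  }
  n_on <- length(on)
  on_avg <- halve_first_point(average_fids(all_t[seq_len(n_on)], provenance = "ON"))
  off_avg <- halve_first_point(average_fids(all_t[n_on + seq_along(off)], provenance = "OFF"))
  target <- zero_fill_factor * length(on_avg$samples)
  on_spec <- to_spectrum(zero_fill(on_avg, target))
  off_spec <- to_spectrum(zero_fill(off_avg, target))
  phi0 <- phase_from_peak(off_spec, c(2.9, 3.2))
  list(on = phase_correct(on_spec, phi0),
       off = phase_correct(off_spec, phi0),
       corrections = corrections)
}

#' Preprocess one short-echo PRESS (or water) acquisition
#'
#' The PRESS pathway: residual-water removal, zero-filling, 1.1 Hz
#' exponential dampening, Fourier transform, and zero-order phasing on the
#' largest peak.
#'
#' @param fid An `mrs_fid`.
#' @param broadening_hz Exponential dampening (default 1.1 Hz).
#' @param zero_fill_factor Zero-filling factor (default 2).
#' @param remove_water Logical; water-reference scans keep their water line.
#' @param phase_window ppm window whose dominant peak defines the zero-order
#'   phase.
#' @return An `mrs_spectrum`.
#' @export
preprocess_press <- function(fid, broadening_hz = 1.1, zero_fill_factor = 2,
                             remove_water = TRUE, phase_window = c(1.8, 4.2)) {
  stopifnot(inherits(fid, "mrs_fid"))
  if (remove_water) fid <- remove_residual_water(fid)
  fid <- halve_first_point(fid)
  fid <- zero_fill(fid, zero_fill_factor * length(fid$samples))
  fid <- apodize(fid, broadening_hz)
  spec <- to_spectrum(fid)
  phase_correct(spec, phase_from_peak(spec, phase_window))
}
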