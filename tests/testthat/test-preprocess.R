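test_that("apodization applies the exponential window exactly", {
  acq <- acq_params()
  ones <- new_fid(rep(1 + 0i, 2048), acq)
  expect_identical(apodize(ones, 0)$samples, ones$samples)
  a3 <- apodize(ones, 3)
  expect_equal(Re(a3$samples[2048]), exp(-pi * 3 * 2047 / 2000),
               tolerance = 1e-12)
  expect_error(apodize(ones, -1), class = "gshmrs_param_error")

  # frequency-domain width grows monotonically with broadening
  fid <- simulate_fid(metabolite_peaks("x", 3.03, 1, 4), acq, noise_model(0))
  widths <- vapply(c(0, 2, 5, 10), function(b) {
    measure_fwhm(to_spectrum(zero_fill(apodize(fid, b), 8192)), c(2.8, 3.3))$fwhm_hz
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("zero-filling preserves the leading samples and the peak area", {
  acq <- acq_params()
  fid <- simulate_fid(metabolite_peaks("x", 3.03, 1, 6), acq, noise_model(0))
  zf <- zero_fill(fid, 4096)
  expect_identical(zf$samples[1:2048], fid$samples)
  expect_identical(zero_fill(fid, 2048)$samples, fid$samples)
  expect_error(zero_fill(fid, 1024), class = "gshmrs_param_error")

  # integrated area conserved within 0.1% (rectangle rule on each grid;
  # first-point correction removes the discrete-transform offset)
  h <- gshmrs:::halve_first_point(fid)
  sp1 <- to_spectrum(h)
  sp2 <- to_spectrum(zero_fill(h, 4096))
  # the (single) peak integrates to the same area on either grid: exactly
  # over the whole spectrum, and within 0.1% inside a finite window once
  # windowing discretization is allowed for
  dppm1 <- abs(diff(sp1$ppm[1:2]))
  dppm2 <- abs(diff(sp2$ppm[1:2]))
  expect_equal(sum(Re(sp2$values)) * dppm2, sum(Re(sp1$values)) * dppm1,
               tolerance = 1e-9)
  expect_equal(spectrum_area(sp2, c(2, 4), "real"),
               spectrum_area(sp1, c(2, 4), "real"), tolerance = 1.5e-3)
})

test_that("the Fourier transform is unitary and maps ppm correctly", {
  acq <- acq_params()
  fid <- simulate_fid(metabolite_peaks("cr", 3.03, 1, 6), acq,
                      noise_model(0))
  sp <- to_spectrum(fid)
  # energy conservation (Parseval): integral form on each domain
  dt <- 1 / acq$sw_hz
  df <- acq$sw_hz / acq$n_points
  expect_equal(sum(Mod(sp$values)^2) * df, sum(Mod(fid$samples)^2) * dt,
               tolerance = 1e-9 * sum(Mod(fid$samples)^2) * dt)
  # exact inverse
  back <- from_spectrum(sp)
  expect_lt(max(Mod(back$samples - fid$samples)), 1e-9)
  # a pure oscillation at the creatine offset lands on the 3.03 ppm bin
  t <- (0:2047) / 2000
  osc <- new_fid(exp(2i * pi * (3.03 - 4.7) * 127.7 * t), acq)
  so <- to_spectrum(osc)
  expect_equal(so$ppm[which.max(Mod(so$values))], 3.03,
               tolerance = acq$sw_hz / acq$n_points / acq$f0_mhz)
  # zero in, zero out
  expect_equal(max(Mod(to_spectrum(new_fid(rep(0i, 2048), acq))$values)), 0)
  # axis is strictly decreasing and centred on the reference
  expect_true(all(diff(sp$ppm) < 0))
})

test_that("phase correction rotates bins and leaves magnitudes alone", {
  acq <- acq_params()
  sp <- to_spectrum(simulate_fid(metabolite_peaks("x", 3.03, 1, 6), acq,
                                 noise_model(0)))
  expect_equal(phase_correct(sp, 0, 0)$values, sp$values)
  both <- phase_correct(phase_correct(sp, 0.7, 0.1), -0.7, -0.1)
  expect_equal(both$values, sp$values, tolerance = 1e-12)
  rot <- phase_correct(sp, 1.1, -0.3)
  expect_equal(Mod(rot$values), Mod(sp$values), tolerance = 1e-12)

  # a purely absorptive line phased by 90 degrees becomes dispersive:
  # antisymmetric lobes with a zero crossing at the centre (within a bin,
  # the line centre generally falling between bins)
  spf <- to_spectrum(zero_fill(gshmrs:::halve_first_point(
    simulate_fid(metabolite_peaks("x", 3.03, 1, 6), acq, noise_model(0))),
    32768))
  k <- which.max(Re(spf$values))
  disp <- phase_correct(spf, pi / 2, 0)
  expect_lt(abs(Re(disp$values[k])), 0.05 * Re(spf$values[k]))
  expect_lt(Re(disp$values[k + 40]) * Re(disp$values[k - 40]), 0)
  expect_true(any(diff(sign(Re(disp$values[(k - 8):(k + 8)]))) != 0))
  expect_error(phase_correct(sp, NaN), class = "gshmrs_param_error")
})

test_that("transient registration recovers injected frequency and phase jitter", {
  acq <- acq_params()
  pk <- megapress_background_peaks()
  base <- simulate_fid(pk, acq, noise_model(0.002))
  t <- gshmrs:::fid_times(base)
  shifts <- c(-3, -1.5, 0, 0.8, 2.2, 3, -2.4, 1.7)
  phases <- c(0.17, -0.1, 0.05, -0.17, 0.08, 0.12, -0.06, 0.02)
  set.seed(4)
  trans <- lapply(seq_along(shifts), function(k) {
    f <- simulate_fid(pk, acq, noise_model(0.002))
    f$samples <- f$samples * exp(1i * (2 * pi * shifts[k] * t + phases[k]))
    f
  })
  out <- correct_frequency_phase(trans)
  corr <- attr(out, "corrections")
  expect_false(any(corr$flagged))
  # recovered shifts within 0.3 Hz of the injected values (up to the common
  # offset that aligns everything to the median transient)
  rec <- -(corr$shift_hz - mean(corr$shift_hz))
  expect_lt(max(abs(rec - (shifts - mean(shifts)))), 0.3)
  # residual phase spread at the creatine peak below 1 degree
  ph <- vapply(out, function(f) {
    sp <- to_spectrum(f)
    idx <- which(gshmrs:::in_window(sp, c(3.0, 3.06)))
    Arg(sum(sp$values[idx] * Mod(sp$values[idx])))
  }, numeric(1))
  expect_lt(diff(range(ph)) * 180 / pi, 1)

  # already-aligned input passes through essentially unchanged
  aligned <- lapply(1:4, function(k) simulate_fid(pk, acq, noise_model(0)))
  out2 <- correct_frequency_phase(aligned)
  expect_lt(max(Mod(out2[[1]]$samples - aligned[[1]]$samples)) /
              max(Mod(aligned[[1]]$samples)), 1e-3)
})

test_that("registration flags transients without a usable reference", {
  acq <- acq_params()
  pk <- megapress_background_peaks()
  good <- lapply(1:3, function(k) simulate_fid(pk, acq, noise_model(0.001)))
  set.seed(1)
  noise_only <- new_fid(complex(real = rnorm(2048, 0, 5),
                                imaginary = rnorm(2048, 0, 5)), acq)
  out <- correct_frequency_phase(c(good, list(noise_only)))
  corr <- attr(out, "corrections")
  expect_true(corr$flagged[4])
  expect_identical(out[[4]]$samples, noise_only$samples)
})

test_that("residual water removal cleans the water band and spares metabolites", {
  acq <- press_acq()
  conc <- c(cr = 6, naa = 8, cho = 1.5)
  dry <- simulate_press(conc, acq, noise_model(0))
  wet <- simulate_press(conc, acq, noise_model(0), residual_water_iu = 600)

  # nothing to remove: output within 1% of the input
  dry_out <- remove_residual_water(dry)
  expect_lt(max(Mod(dry_out$samples - dry$samples)) / max(Mod(dry$samples)),
            0.01)

  # water 100x the creatine amplitude: >= 90% of the water-band signal goes,
  # and the creatine area agrees with the water-free truth within 2%
  wet_out <- remove_residual_water(wet)
  sp_wet <- to_spectrum(zero_fill(wet, 4096))
  sp_out <- to_spectrum(zero_fill(wet_out, 4096))
  expect_lt(spectrum_area(sp_out, c(4.4, 5.0), "magnitude"),
            0.1 * spectrum_area(sp_wet, c(4.4, 5.0), "magnitude"))
  basis <- press_basis_cached()
  cr_wet <- fit_press(preprocess_press(wet), basis)$cr_concentration
  cr_dry <- fit_press(preprocess_press(dry, remove_water = FALSE),
                      basis)$cr_concentration
  expect_equal(cr_wet, cr_dry, tolerance = 0.02 * cr_dry)

  # water-only input: residual energy at most 10% of the input
  only <- simulate_press(c(cr = 0), acq, noise_model(0),
                         residual_water_iu = 100)
  only_out <- remove_residual_water(only)
  expect_lt(sum(Mod(only_out$samples)^2), 0.1 * sum(Mod(only$samples)^2))

  # away from the water band the cleaned spectrum matches the water-free
  # truth to within 1% of the strongest metabolite signal
  sp_dry <- to_spectrum(zero_fill(dry, 4096))
  idx <- gshmrs:::in_window(sp_wet, c(0.5, 4.0))
  expect_lt(max(Mod(sp_out$values[idx] - sp_dry$values[idx])),
            0.01 * max(Mod(sp_dry$values[idx])))
})
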