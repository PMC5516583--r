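test_that("forward model places resonances with the right area and width", {
  acq <- acq_params()
  # single resonance: spectrum magnitude peaks at the peak's ppm bin
  fid <- simulate_fid(metabolite_peaks("cr", 3.03, 1, 5), acq, noise_model(0))
  sp <- to_spectrum(fid)
  expect_equal(sp$ppm[which.max(Mod(sp$values))], 3.03,
               tolerance = acq$sw_hz / acq$n_points / acq$f0_mhz)

  # linearity: two identical peaks double the spectrum everywhere
  pk2 <- metabolite_peaks(c("a", "b"), c(3.03, 3.03), c(1, 1), c(5, 5))
  sp2 <- to_spectrum(simulate_fid(pk2, acq, noise_model(0)))
  expect_equal(sp2$values, 2 * sp$values, tolerance = 1e-12)

  # Lorentzian FWHM = damping / pi Hz, measured after fine zero-fill
  for (d in c(4, 8)) {
    f <- simulate_fid(metabolite_peaks("x", 3.03, 1, d), acq, noise_model(0))
    fw <- measure_fwhm(to_spectrum(zero_fill(f, 65536)), c(2.9, 3.2))
    expect_equal(fw$fwhm_hz, d / pi, tolerance = 0.02 * d / pi)
  }

  # empty peak list with zero noise is an all-zero FID; bad acq is rejected
  expect_equal(max(Mod(simulate_fid(metabolite_peaks(character(), numeric(),
                                                     numeric(), numeric()),
                                    acq, noise_model(0))$samples)), 0)
  expect_error(acq_params(n_points = 1000), class = "gshmrs_param_error")
  expect_error(acq_params(sw_hz = -5), class = "gshmrs_param_error")
  expect_error(metabolite_peaks("x", 3, -1, 5), class = "gshmrs_param_error")
})

test_that("editing algebra: ON/OFF members differ only by the edited lines", {
  # zero efficiency: ON and OFF are bit-identical
  pair0 <- simulate_megapress_pair(0.04, 0, coedited = NULL)
  expect_identical(pair0$on$samples, pair0$off$samples)

  # full efficiency: the difference equals the edited (GSH) signal alone --
  # the unedited background cancels to numerical precision at every bin,
  # including the creatine bin
  pair1 <- simulate_megapress_pair(0.04, 1, coedited = NULL)
  d <- to_spectrum(pair1$off)
  d$values <- d$values - to_spectrum(pair1$on)$values
  pk <- gshmrs:::megapress_peak_tables(0.04, 1, NULL)
  gsh_on <- simulate_fid(pk$on[grepl("gsh", pk$on$name), ], acq_params())
  gsh_off <- simulate_fid(pk$off[grepl("gsh", pk$off$name), ], acq_params())
  d_gsh_only <- to_spectrum(gsh_off)$values - to_spectrum(gsh_on)$values
  off <- to_spectrum(pair1$off)
  cr_bin <- which.max(Mod(off$values) * gshmrs:::in_window(off, c(3.02, 3.04)))
  expect_lt(Mod(d$values[cr_bin] - d_gsh_only[cr_bin]),
            1e-9 * Mod(off$values[cr_bin]))
  # and the difference carries the full GSH amplitude
  expect_equal(Re(d$values), Re(d_gsh_only), tolerance = 1e-9)

  # an edited peak retains efficiency x amplitude in the difference
  e <- 0.6
  pk2 <- gshmrs:::megapress_peak_tables(0.05, e, NULL)
  on_g <- to_spectrum(simulate_fid(pk2$on[grepl("gsh", pk2$on$name), ],
                                   acq_params()))
  off_g <- to_spectrum(simulate_fid(pk2$off[grepl("gsh", pk2$off$name), ],
                                    acq_params()))
  gsh_bin <- which.max(Mod(on_g$values))
  expect_equal(Mod(off_g$values[gsh_bin] - on_g$values[gsh_bin]) /
                 Mod(on_g$values[gsh_bin]), e, tolerance = 1e-9)

  expect_error(simulate_megapress_pair(0.04, 1.4), class = "gshmrs_param_error")
})

test_that("noiseless GSH/Cr round trip through the full pipeline", {
  pair <- clean_pair(0.04, 0.5)
  prep <- preprocess_edited_scan(pair, align = FALSE)
  ed <- fit_edited_gsh(difference_edit(prep$on, prep$off))
  cr <- fit_reference_cr(prep$off)
  expect_equal(gsh_cr_ratio(ed, cr, 0.5), 0.04, tolerance = 0.01)
})

test_that("PRESS simulation validates names and supports recovery", {
  expect_error(simulate_press(c(unobtainium = 1)), class = "gshmrs_param_error")
  expect_error(simulate_press(c(cr = -1)), class = "gshmrs_param_error")

  # all-zero concentrations give a flat spectrum
  flat <- to_spectrum(simulate_press(c(cr = 0, naa = 0)))
  expect_lt(max(Mod(flat$values)), 1e-12)

  # two-metabolite round trip through the basis fit
  basis <- press_basis_cached()
  fid <- simulate_press(c(cr = 6, naa = 8), press_acq(), noise_model(0))
  pf <- fit_press(preprocess_press(fid), basis)
  conc <- setNames(pf$concentrations$concentration, pf$concentrations$name)
  expect_equal(unname(conc["cr"]), 6, tolerance = 0.02)
  expect_equal(unname(conc["naa"]), 8, tolerance = 0.02)
})

test_that("water pair encodes the T2 decay between echo times", {
  wp <- simulate_water_pair(80, te_ms = c(68, 122))
  a <- preprocess_press(wp$a, remove_water = FALSE, phase_window = c(4.2, 5.2))
  b <- preprocess_press(wp$b, remove_water = FALSE, phase_window = c(4.2, 5.2))
  r <- spectrum_area(a, c(2.2, 7.2)) / spectrum_area(b, c(2.2, 7.2))
  expect_equal(r, exp(54 / 80), tolerance = 0.01)

  # no-decay limit: equal areas
  wp_inf <- simulate_water_pair(1e9, te_ms = c(68, 122))
  expect_equal(max(Mod(wp_inf$a$samples)), max(Mod(wp_inf$b$samples)),
               tolerance = 1e-6)

  # round trip through the estimator at zero noise
  expect_equal(estimate_water_t2(wp$a, wp$b), 80, tolerance = 0.01)
  expect_error(simulate_water_pair(80, te_ms = c(68, 68)),
               class = "gshmrs_param_error")
  expect_error(simulate_water_pair(-3), class = "gshmrs_param_error")
})

test_that("default cohort reproduces the study design and is deterministic", {
  co <- simulate_cohort(seed = 42, spectra = FALSE)
  tt <- truth_table(co)
  expect_equal(nrow(tt), 70)                      # 15 baseline + 55 post-dose
  expect_equal(sum(tt$scan_index == 0), 15)
  expect_equal(sum(!tt$detectable_truth), 6)      # undetectable baselines
  expect_equal(sum(tt$corrupt), 1)                # one corrupted scan
  expect_true(all(table(tt$subject_id) %in% 4:6))
  # schedule: 6 subjects x 3, 8 x 4, 1 x 5 post-dose scans
  expect_equal(as.integer(sort(table(tt$subject_id[tt$scan_index > 0]))),
               c(rep(3, 6), rep(4, 8), 5L))
  # truth table covers every scan, times strictly increasing per subject
  expect_false(anyNA(tt$true_gsh_cr))
  by_subj <- split(tt$time_min, tt$subject_id)
  expect_true(all(vapply(by_subj, function(x) all(diff(sort(x)) > 0), TRUE)))

  # determinism: identical seed reproduces the dataset byte-for-byte
  co2 <- simulate_cohort(seed = 42, spectra = FALSE)
  expect_identical(co$scans, co2$scans)
  m1 <- simulate_cohort(seed = 9, spectra = TRUE, n_pairs = 1, press = "none")
  m2 <- simulate_cohort(seed = 9, spectra = TRUE, n_pairs = 1, press = "none")
  expect_identical(m1$mega[[1]]$on[[1]]$samples, m2$mega[[1]]$on[[1]]$samples)

  expect_error(simulate_cohort(design = modifyList(cohort_design(),
                                                   list(n_postdose = rep(0, 15)))),
               class = "gshmrs_param_error")
})

test_that("cohort truth means track the target time profile", {
  # noise-off generator moments: per-bin sample means of true GSH/Cr match
  # the targets within 2 SEM over many replicate cohorts
  d <- cohort_design()
  sems <- c(0.0046, 0.0039, 0.0057, 0.0053, 0.012)
  acc <- matrix(NA_real_, nrow = 1000, ncol = 5)
  for (s in seq_len(1000)) {
    tt <- truth_table(simulate_cohort(seed = s, spectra = FALSE))
    m <- tapply(tt$true_gsh_cr, tt$scan_index, mean)
    acc[s, ] <- m[as.character(0:4)]
  }
  grand <- colMeans(acc)
  for (b in 1:5) {
    expect_lt(abs(grand[b] - d$bin_means[b]), 2 * sems[b])
  }
})
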