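# shared fixtures, built in code

# a noiseless ON/OFF pair with no co-edited contaminants
clean_pair <- function(gsh_cr_true = 0.04, eff = 0.5) {
  simulate_megapress_pair(gsh_cr_true, eff, coedited = NULL,
                          acq = acq_params(), noise = noise_model(0))
}

# one full noisy scan quantified end to end; returns the fits and the ratio
quantify_one <- function(gsh_cr_true, noise_sd = 0.01, seed = 1, n_pairs = 8,
                         eff = 0.74) {
  set.seed(seed)
  scan <- simulate_megapress_scan(gsh_cr_true, eff,
                                  acq = acq_params(),
                                  noise = noise_model(noise_sd, 1, 0.1),
                                  n_pairs = n_pairs)
  prep <- preprocess_edited_scan(scan)
  d <- difference_edit(prep$on, prep$off)
  ed <- fit_edited_gsh(d)
  cr <- fit_reference_cr(prep$off)
  list(diff = d, edited = ed, cr = cr,
       ratio = gsh_cr_ratio(ed, cr, eff))
}

# PRESS basis on the study acquisition, built once per test run
press_basis_cached <- local({
  basis <- NULL
  function() {
    if (is.null(basis)) basis <<- make_basis_set()
    basis
  }
})

press_acq <- function() acq_params(te_ms = 36, n_averages = 64)

# truth-level cohort quantification: the statistics layer applied to the
# generator's ground truth plus a light multiplicative measurement layer
truth_level_quant <- function(seed, meas_bias = 0.03, meas_sd = 0.02) {
  co <- simulate_cohort(seed = seed, spectra = FALSE)
  q <- co$scans
  q$gsh_cr <- q$true_gsh_cr * (1 + rnorm(nrow(q), meas_bias, meas_sd))
  q$flag <- ifelse(!q$detectable_truth, "undetectable",
                   ifelse(q$corrupt, "insufficient_quality", "ok"))
  q$gsh_cr[q$flag != "ok"] <- NA
  q
}
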