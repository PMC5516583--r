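make_quant <- function(values, subjects, bins, flags = NULL) {
  tibble::tibble(
    subject_id = subjects, scan_index = bins,
    time_min = ifelse(bins == 0, 0, 10 * bins + 2),
    gsh_cr = values,
    flag = if (is.null(flags)) "ok" else flags
  )
}

test_that("imputation assigns min/2 to undetectable baselines only", {
  q <- make_quant(c(NA, 0.0080, 0.020, 0.030, NA, 0.012),
                  c("A", "A", "A", "B", "B", "B"),
                  c(0, 1, 2, 1, 0, 2),
                  c("undetectable", "ok", "ok", "ok", "undetectable", "ok"))
  out <- impute_undetectable(q)
  expect_equal(attr(out, "imputed_value"), 0.0080 / 2)
  expect_equal(out$gsh_cr[c(1, 5)], c(0.004, 0.004))
  # detectable measurements never change
  expect_identical(out$gsh_cr[-c(1, 5)], q$gsh_cr[-c(1, 5)])
  # non-baseline undetectables stay excluded, not imputed
  q2 <- make_quant(c(0.01, NA), c("A", "A"), c(0, 1), c("ok", "undetectable"))
  expect_true(is.na(impute_undetectable(q2)$gsh_cr[2]))
  # no undetectable baselines: identity
  q3 <- make_quant(c(0.01, 0.02), c("A", "A"), c(0, 1))
  expect_identical(impute_undetectable(q3)$gsh_cr, q3$gsh_cr)
  # nothing detectable anywhere: abort
  q4 <- make_quant(c(NA, NA), c("A", "A"), c(0, 1),
                   c("undetectable", "undetectable"))
  expect_error(impute_undetectable(q4), class = "gshmrs_data_error")
  # all default-cohort undetectable baselines receive one identical value
  qt <- impute_undetectable(truth_level_quant(21))
  imp <- qt$gsh_cr[qt$imputed]
  expect_equal(length(imp), 6)
  expect_equal(length(unique(imp)), 1)
})

test_that("time bins are labelled with midpoint means and SEMs", {
  q <- assign_time_bins(truth_level_quant(5))
  labs <- attr(q, "bin_labels")
  expect_equal(as.integer(as.character(labs$bin)), 0:5)
  got <- labs$time_mean[2:5]
  expect_equal(got, c(7.5, 19.9, 32.0, 44.7), tolerance = 1.5)
  # single subject: labels equal its own midpoints with zero SEM
  one <- make_quant(c(0.01, 0.02, 0.03), "A", 0:2)
  l1 <- attr(assign_time_bins(one), "bin_labels")
  expect_equal(l1$time_sem, rep(0, 3))
  expect_equal(l1$time_mean, one$time_min)
})

test_that("differences versus baseline do the per-subject subtraction", {
  q <- make_quant(c(0.0170, 0.0259), c("A", "A"), c(0, 1))
  d <- differences_vs_baseline(q)
  expect_equal(d$diff_vs_baseline, c(0, 0.0089), tolerance = 1e-12)
  # flat series: all zero
  flat <- make_quant(rep(0.02, 4), "A", 0:3)
  expect_equal(differences_vs_baseline(flat)$diff_vs_baseline, rep(0, 4))
  # complete data: mean of per-subject differences equals difference of means
  q2 <- make_quant(c(0.01, 0.03, 0.02, 0.06), c("A", "A", "B", "B"),
                   c(0, 1, 0, 1))
  d2 <- differences_vs_baseline(q2)
  expect_equal(mean(d2$diff_vs_baseline[d2$scan_index == 1]),
               mean(q2$gsh_cr[q2$scan_index == 1]) -
                 mean(q2$gsh_cr[q2$scan_index == 0]))
  # a subject without baseline is dropped with a message
  q3 <- make_quant(c(0.01, 0.02, 0.05), c("A", "A", "B"), c(0, 1, 1))
  expect_message(d3 <- differences_vs_baseline(q3), "without baseline")
  expect_false("B" %in% d3$subject_id)
})

test_that("Holm-Sidak step-down is monotone, bounded and correctly ordered", {
  p <- c(0.30, 0.001, 0.04, 0.012)
  adj <- holm_sidak(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # adjusted values preserve the ordering of the raw values
  expect_equal(order(adj), order(p))
  # smallest p gets the full-family Sidak exponent
  expect_equal(adj[2], 1 - (1 - 0.001)^4, tolerance = 1e-12)
  # never less conservative than unadjusted, never more than Holm-Bonferroni
  holm <- stats::p.adjust(p, "holm")
  expect_true(all(adj <= holm + 1e-12))
  # monotone non-decreasing after sorting by raw p
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("repeated-measures ANOVA matches closed forms", {
  # balanced 2-bin case: F equals the squared paired t statistic
  set.seed(1)
  vals0 <- rnorm(8, 0.02, 0.005)
  vals1 <- vals0 + rnorm(8, 0.01, 0.004)
  q <- make_quant(c(vals0, vals1), rep(sprintf("S%d", 1:8), 2),
                  rep(c(0, 1), each = 8))
  a <- rm_anova(q)
  tt <- t.test(vals1, vals0, paired = TRUE)
  expect_equal(a$f_statistic, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-8)

  # complete balanced table: F matches a brute-force sums-of-squares oracle
  set.seed(2)
  n <- 10; k <- 4
  y <- rnorm(n * k, rep(c(0.02, 0.025, 0.03, 0.028), each = n), 0.006) +
    rep(rnorm(n, 0, 0.004), k)
  q2 <- make_quant(y, rep(sprintf("S%d", 1:n), k), rep(0:(k - 1), each = n))
  a2 <- rm_anova(q2)
  m <- matrix(y, nrow = n)
  grand <- mean(m)
  ss_time <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - outer(rowMeans(m), colMeans(m), "+") + grand)^2)
  f_oracle <- (ss_time / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  expect_equal(a2$f_statistic, f_oracle, tolerance = 1e-8)

  expect_error(rm_anova(make_quant(c(0.1, 0.2), c("A", "A"), c(0, 1))),
               class = "gshmrs_data_error")
})

test_that("the time-effect test holds its size under a permuted null", {
  # permute each subject's levels across its own scans: exchangeable null
  base <- truth_level_quant(99)
  base <- impute_undetectable(base)
  base <- base[!is.na(base$gsh_cr), ]
  base <- base[order(base$subject_id, base$scan_index), ]
  hits <- 0
  n_rep <- 1000
  set.seed(123)
  for (r in seq_len(n_rep)) {
    q <- base
    q$gsh_cr <- unlist(lapply(split(q$gsh_cr, q$subject_id), sample),
                       use.names = FALSE)
    a <- rm_anova(assign_time_bins(q))
    hits <- hits + (a$p_value < 0.05)
  }
  expect_gte(hits / n_rep, 0.03)
  expect_lte(hits / n_rep, 0.07)
})

test_that("cohort summaries reproduce the reporting conventions", {
  # ratio-of-means percent change: 0.0457 vs 0.0170 prints as 269%
  expect_equal(round(percent_change(0.0457, 0.0170)), 269)
  expect_equal(percent_change(0.0457, 0.0170, "increase"),
               percent_change(0.0457, 0.0170) - 100)
  # constant cohort: 100% under the ratio convention
  flat <- make_quant(rep(0.02, 8), rep(c("A", "B"), 4),
                     rep(0:3, each = 2))
  s <- summarize_cohort(flat)
  expect_equal(attr(s, "percent_change"), 100)

  # summary rows carry n, mean, extremes and differences
  q <- truth_level_quant(7)
  q <- assign_time_bins(impute_undetectable(q))
  s2 <- suppressMessages(summarize_cohort(q))
  expect_equal(nrow(s2), 5)  # baseline + 4 reported bins (n >= 2)
  expect_true(all(s2$min <= s2$mean & s2$mean <= s2$max))
  expect_true(all(s2$n <= 15))
  expect_true(is.na(s2$mean_diff[1]))

  # summaries are invariant to subject ordering
  qr <- q[sample(nrow(q)), ]
  s3 <- suppressMessages(summarize_cohort(assign_time_bins(qr)))
  expect_equal(as.data.frame(s3), as.data.frame(s2), tolerance = 1e-12)
})
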