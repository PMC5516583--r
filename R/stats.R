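#' Impute undetectable baseline ratios
#'
#' Every baseline scan flagged undetectable is assigned the same value: the
#' lowest measured GSH/Cr ratio across all subjects and scans, divided by 2.
#' Non-baseline undetectables are excluded from analysis, not imputed.
#' Detectable measurements are never altered.
#'
#' @param quant A quantification tibble with columns `subject_id`,
#'   `scan_index`, `gsh_cr`, `flag`.
#' @return The tibble with imputed baseline `gsh_cr` values and a logical
#'   `imputed` column.
#' @export
impute_undetectable <- function(quant) {
  stopifnot(all(c("subject_id", "scan_index", "gsh_cr", "flag") %in% names(quant)))
  measured <- quant$gsh_cr[quant$flag == "ok" & !is.na(quant$gsh_cr)]
  if (length(measured) == 0) {
    abort("No detectable measurements anywhere in the cohort.",
          class = "gshmrs_data_error")
  }
  fill <- min(measured) / 2
  quant$imputed <- quant$flag == "undetectable" & quant$scan_index == 0
  quant$gsh_cr[quant$imputed] <- fill
  if ("gsh_absolute_iu" %in% names(quant) && "cr_corrected_iu" %in% names(quant)) {
    quant$gsh_absolute_iu[quant$imputed] <-
      fill * quant$cr_corrected_iu[quant$imputed]
  }
  attr(quant, "imputed_value") <- fill
  quant
}

#' Group scans into ordinal time bins
#'
#' Scans are grouped by post-dose ordinal index (baseline is bin 0) and each
#' bin is labelled with the mean (SEM) of its scan midpoints.
#'
#' @param quant A quantification tibble with `scan_index` and `time_min`.
#' @return The tibble with a `bin` factor added; the per-bin label table is
#'   in attribute `"bin_labels"` (bin, n, time_mean, time_sem, label).
#' @export
assign_time_bins <- function(quant) {
  quant$bin <- factor(quant$scan_index, levels = sort(unique(quant$scan_index)))
  labs <- quant |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      time_mean = mean(.data$time_min),
      time_sem = if (dplyr::n() > 1) sd(.data$time_min) / sqrt(dplyr::n()) else 0,
      .groups = "drop") |>
    dplyr::mutate(label = sprintf("%.1f (%.2f)", .data$time_mean, .data$time_sem))
  attr(quant, "bin_labels") <- labs
  quant
}

#' Per-subject differences versus baseline
#'
#' For every analyzable scan, the level minus the same subject's baseline
#' level (measured or imputed). Subjects without a baseline are dropped with
#' a message.
#'
#' @param quant Quantification tibble with `subject_id`, `scan_index` and the
#'   response column.
#' @param response Column to difference (default `"gsh_cr"`).
#' @return The tibble restricted to subjects with a baseline, with a
#'   `diff_vs_baseline` column added.
#' @export
differences_vs_baseline <- function(quant, response = "gsh_cr") {
  base <- quant |>
    dplyr::filter(.data$scan_index == 0, !is.na(.data[[response]])) |>
    dplyr::select("subject_id", baseline_value = dplyr::all_of(response))
  missing <- setdiff(unique(quant$subject_id), base$subject_id)
  if (length(missing) > 0) {
    rlang::inform(paste0("Excluding subject(s) without baseline: ",
                         paste(missing, collapse = ", ")))
    quant <- quant[!quant$subject_id %in% missing, ]
  }
  quant <- dplyr::left_join(quant, base, by = "subject_id")
  quant$diff_vs_baseline <- quant[[response]] - quant$baseline_value
  quant
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Step-down Sidak procedure: with `k` hypotheses ordered by increasing raw
#' p-value, the i-th is adjusted to `1 - (1 - p_(i))^(k - i + 1)` and the
#' adjusted values are made monotone non-decreasing and capped at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak <- function(p) {
  k <- sum(!is.na(p))
  ord <- order(p, na.last = TRUE)
  adj <- rep(NA_real_, length(p))
  running <- 0
  for (i in seq_len(k)) {
    j <- ord[i]
    a <- 1 - (1 - p[j])^(k - i + 1)
    running <- max(running, a)
    adj[j] <- min(running, 1)
  }
  adj
}

#' One-way repeated-measures ANOVA with Holm-Sidak comparisons vs baseline
#'
#' Fits the time effect as a within-subject one-way repeated-measures ANOVA.
#' With unbalanced data (dropped scans, subjects with fewer post-dose scans)
#' the primary analysis is the general-linear-model form with subject as a
#' blocking factor, using all available data; `complete_cases = TRUE`
#' restricts to subjects observed in every retained bin. Each post-dose bin
#' is then compared with baseline by a paired t-test on the subjects
#' contributing both, with Holm-Sidak step-down adjustment over that family.
#'
#' @param quant A binned quantification tibble (see [assign_time_bins()]).
#' @param response Response column (default `"gsh_cr"`).
#' @param min_subjects Bins with fewer contributing subjects are dropped.
#' @param complete_cases Use only subjects observed in every retained bin.
#' @param alpha Significance level for the comparison flags.
#' @return An object of class `gsh_rm_anova` with the omnibus `f_statistic`,
#'   `df`, `p_value`, and a `comparisons` tibble (bin, n pairs, mean
#'   difference, raw and adjusted p, significance flag).
#' @export
rm_anova <- function(quant, response = "gsh_cr", min_subjects = 2,
                     complete_cases = FALSE, alpha = 0.05) {
  if (!"bin" %in% names(quant)) quant <- assign_time_bins(quant)
  d <- quant[!is.na(quant[[response]]), c("subject_id", "bin", response)]
  names(d)[3] <- "y"
  keep_bins <- names(which(tapply(d$subject_id, d$bin, function(s) length(unique(s))) >= min_subjects))
  d <- d[d$bin %in% keep_bins, ]
  d$bin <- droplevels(d$bin)
  if (nlevels(d$bin) < 2 || length(unique(d$subject_id)) < 2) {
    abort("Need at least 2 time bins and 2 subjects.", class = "gshmrs_data_error")
  }
  if (complete_cases) {
    full <- names(which(tapply(d$bin, d$subject_id,
                               function(b) length(unique(b))) == nlevels(d$bin)))
    d <- d[d$subject_id %in% full, ]
  }
  d$subject_id <- factor(d$subject_id)
  if (all(tapply(d$y, d$subject_id, function(v) var(v) == 0))) {
    warn("Zero within-subject variance; the time effect is degenerate.")
  }
  fit <- lm(y ~ subject_id + bin, data = d)
  an <- anova(fit)
  f_stat <- an["bin", "F value"]
  p_val <- an["bin", "Pr(>F)"]
  dfs <- c(an["bin", "Df"], an["Residuals", "Df"])

  base <- d[d$bin == levels(d$bin)[1], c("subject_id", "y")]
  names(base)[2] <- "y0"
  comps <- purrr::map(setdiff(levels(d$bin), levels(d$bin)[1]), function(b) {
    v <- dplyr::inner_join(d[d$bin == b, c("subject_id", "y")], base,
                           by = "subject_id")
    delta <- v$y - v$y0
    n <- length(delta)
    if (n < 2 || sd(delta) == 0) {
      return(tibble(bin = b, n = n, mean_diff = mean(delta),
                    sem_diff = NA_real_, t = NA_real_, p = NA_real_))
    }
    tt <- mean(delta) / (sd(delta) / sqrt(n))
    tibble(bin = b, n = n, mean_diff = mean(delta),
           sem_diff = sd(delta) / sqrt(n), t = tt,
           p = 2 * pt(-abs(tt), n - 1))
  })
  comps <- dplyr::bind_rows(comps)
  comps$p_adj <- holm_sidak(comps$p)
  comps$significant <- !is.na(comps$p_adj) & comps$p_adj < alpha

  structure(list(f_statistic = f_stat, df = dfs, p_value = p_val,
                 comparisons = comps, response = response,
                 n_subjects = length(unique(d$subject_id)),
                 n_bins = nlevels(d$bin), alpha = alpha,
                 complete_cases = complete_cases),
            class = "gsh_rm_anova")
}

#' @export
print.gsh_rm_anova <- function(x, ...) {
  cat(sprintf(
    "<gsh_rm_anova> %s: F(%d, %d) = %.2f, p = %.3g (%d subjects, %d bins)\n",
    x$response, x$df[1], x$df[2], x$f_statistic, x$p_value,
    x$n_subjects, x$n_bins))
  cat("Holm-Sidak comparisons vs baseline:\n")
  print(as.data.frame(x$comparisons), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Percent change between two means
#'
#' The cohort reports the change from baseline to the final scan as the
#' ratio of means times 100 (so 0.0457 vs 0.0170 prints as a "269% increase");
#' the usual increase convention (`ratio - 1`) is also returned.
#'
#' @param mean_final,mean_baseline The two means.
#' @param convention `"ratio_of_means"` or `"increase"`.
#' @return Percent value under the chosen convention.
#' @examples
#' percent_change(0.0457, 0.0170) # 269 (rounded)
#' @export
percent_change <- function(mean_final, mean_baseline,
                           convention = c("ratio_of_means", "increase")) {
  convention <- match.arg(convention)
  r <- 100 * mean_final / mean_baseline
  if (convention == "increase") r - 100 else r
}

#' Cohort summary table
#'
#' One row per time bin in the observed-cohort format: time label
#' (mean midpoint with SEM), number of contributing subjects, mean (SEM),
#' min, max of the level, and the mean (SEM) of per-subject differences
#' versus baseline. Bins with fewer than `min_n` subjects are omitted.
#'
#' @param quant A quantification tibble (binned and imputed as desired).
#' @param response Response column (default `"gsh_cr"`).
#' @param min_n Minimum subjects per reported bin (default 2).
#' @return A tibble of summary rows; attributes `percent_change` (ratio of
#'   means x 100, baseline to final reported bin) and
#'   `percent_increase` (same minus 100).
#' @export
summarize_cohort <- function(quant, response = "gsh_cr", min_n = 2) {
  if (!"bin" %in% names(quant)) quant <- assign_time_bins(quant)
  quant <- differences_vs_baseline(quant, response)
  d <- quant[!is.na(quant[[response]]), ]
  out <- d |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      time_mean = mean(.data$time_min),
      time_sem = if (dplyr::n() > 1) sd(.data$time_min) / sqrt(dplyr::n()) else 0,
      mean = mean(.data[[response]]),
      sem = if (dplyr::n() > 1) sd(.data[[response]]) / sqrt(dplyr::n()) else NA_real_,
      min = min(.data[[response]]),
      max = max(.data[[response]]),
      mean_diff = mean(.data$diff_vs_baseline),
      sem_diff = if (dplyr::n() > 1) sd(.data$diff_vs_baseline) / sqrt(dplyr::n())
                 else NA_real_,
      .groups = "drop") |>
    dplyr::filter(.data$n >= min_n)
  out$mean_diff[out$bin == levels(quant$bin)[1]] <- NA_real_
  out$sem_diff[out$bin == levels(quant$bin)[1]] <- NA_real_
  pc <- percent_change(out$mean[nrow(out)], out$mean[1])
  attr(out, "percent_change") <- pc
  attr(out, "percent_increase") <- pc - 100
  out
}
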