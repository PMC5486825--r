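# Group comparisons of histogram metrics between binary prognostic
# subgroups: per-arm normality gate, Welch t-test or Mann-Whitney U, and
# Holm-Bonferroni step-down correction within each outcome family.

#' Compare two samples with an automatic parametric / non-parametric gate
#'
#' Normality is assessed per arm with Shapiro-Wilk at alpha = 0.05; if both
#' arms pass (and have at least 3 non-constant observations), a two-sided
#' Welch t-test is used, otherwise a two-sided Mann-Whitney U test.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param force `"auto"` (default) applies the normality gate; `"t"` or
#'   `"mann_whitney"` forces a branch.
#' @return list: `test_used`, `p_raw`, and a `summary` with per-arm n,
#'   mean and SD.
#' @export
choose_and_run_test <- function(a, b, force = c("auto", "t", "mann_whitney")) {
  force <- match.arg(force)
  if (length(a) < 2 || length(b) < 2)
    input_error("both arms need at least 2 observations")
  arm_normal <- function(x) {
    if (length(x) < 3 || length(unique(x)) < 3) return(FALSE)
    stats::shapiro.test(x)$p.value > 0.05
  }
  use_t <- switch(force,
                  auto = arm_normal(a) && arm_normal(b),
                  t = TRUE,
                  mann_whitney = FALSE)
  p <- if (use_t) {
    stats::t.test(a, b, var.equal = FALSE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }
  # degenerate all-tie samples (e.g. a clipped-at-zero minimum in every
  # case) carry no evidence of a difference
  if (is.na(p)) p <- 1
  list(test_used = if (use_t) "t" else "mann_whitney",
       p_raw = p,
       summary = list(n_a = length(a), mean_a = mean(a), sd_a = stats::sd(a),
                      n_b = length(b), mean_b = mean(b), sd_b = stats::sd(b)))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the p-values ascending and sets
#' `adj_(i) = min(1, max_{j <= i} (m - j + 1) * p_(j))`, returning the
#' adjusted values in the original order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    input_error("p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  stepped <- cummax((m - seq_len(m) + 1) * p_values[ord])
  adj <- pmin(1, stepped)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Default metric subset for prognostic comparisons
#'
#' Volume, the classical first-order metrics, and the most commonly
#' reported percentiles - 13 metrics, limiting the number of tests per
#' outcome family.
#' @return character vector of metric column names.
#' @export
outcome_metric_subset <- function() {
  c("volume_cm3", "min", "max", "mean", "median", "sd", "skew", "kurt",
    "p5", "p30", "p45", "p70", "p95")
}

#' Compare metrics between prognostic subgroups with Holm correction
#'
#' For each delineation method (reader-averaged) and each binary outcome,
#' every metric in `metric_subset` is compared between the two arms with
#' [choose_and_run_test()]; Holm-Bonferroni is applied within each
#' (method, outcome) family. Outcomes with an arm below 2 observations are
#' skipped with a message.
#'
#' @param metrics data.frame from [cohort_metrics()].
#' @param labels data.frame of binary labels with a `case_id` column, as
#'   from [generate_cohort()].
#' @param metric_subset metric columns to test.
#' @param force test forcing, as in [choose_and_run_test()].
#' @return data.frame: one row per method x outcome x metric with group
#'   summaries, `test_used`, `p_raw`, `p_holm` and `significant`
#'   (p_holm <= 0.05).
#' @export
outcome_table <- function(metrics, labels,
                          metric_subset = outcome_metric_subset(),
                          force = "auto") {
  avg <- reader_average(metrics)
  outcomes <- setdiff(names(labels), "case_id")
  rows <- list()
  for (method in unique(avg$method)) {
    sub <- avg[avg$method == method, , drop = FALSE]
    lab <- labels[match(sub$case_id, labels$case_id), , drop = FALSE]
    if (anyNA(lab$case_id)) input_error("labels do not cover all cases")
    for (oc in outcomes) {
      g <- lab[[oc]]
      if (sum(g == 0) < 2 || sum(g == 1) < 2) {
        message("outcome ", oc, " skipped for method ", method,
                ": an arm has fewer than 2 cases")
        next
      }
      fam <- lapply(metric_subset, function(m) {
        res <- choose_and_run_test(sub[[m]][g == 0], sub[[m]][g == 1],
                                   force = force)
        data.frame(method = method, outcome = oc, metric = m,
                   n_neg = res$summary$n_a, mean_neg = res$summary$mean_a,
                   sd_neg = res$summary$sd_a,
                   n_pos = res$summary$n_b, mean_pos = res$summary$mean_b,
                   sd_pos = res$summary$sd_b,
                   test_used = res$test_used, p_raw = res$p_raw,
                   stringsAsFactors = FALSE)
      })
      fam <- do.call(rbind, fam)
      fam$p_holm <- holm_bonferroni(fam$p_raw)
      fam$significant <- fam$p_holm <= 0.05
      rows[[paste(method, oc)]] <- fam
    }
  }
  if (length(rows) == 0) {
    return(data.frame(method = character(0), outcome = character(0),
                      metric = character(0), n_neg = integer(0),
                      mean_neg = numeric(0), sd_neg = numeric(0),
                      n_pos = integer(0), mean_pos = numeric(0),
                      sd_pos = numeric(0), test_used = character(0),
                      p_raw = numeric(0), p_holm = numeric(0),
                      significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
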