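# Agreement statistics: ICC(A,1) (two-way model, absolute agreement, single
# measures) from its variance-component mean squares, Bland-Altman bias and
# limits of agreement, the per-metric inter-reader/inter-method ICC table,
# and the percentile sweep that identifies the non-precise histogram
# surrogate of the precise mean ADC.

#' ICC for absolute agreement of single measures, ICC(A,1)
#'
#' Two-way crossed design (every rater rates every subject). The point
#' estimate of McGraw & Wong's ICC(A,1) is identical under the mixed and
#' random rater models, so one computation serves both. The mean squares
#' are computed from the two-way ANOVA decomposition:
#' \deqn{ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' with MSR the subject (row), MSC the rater (column) and MSE the residual
#' mean square.
#'
#' @param ratings numeric matrix, subjects x raters, no missing cells,
#'   n >= 2 rows and k >= 2 columns.
#' @return list of class `icc_result`: `icc`, `ms_rows`, `ms_cols`,
#'   `ms_error`, `n`, `k`.
#' @export
icc_absolute_single <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) input_error("ratings must be at least 2 x 2")
  if (anyNA(ratings) || any(!is.finite(ratings)))
    input_error("ratings must be finite with no missing cells")
  grand <- mean(ratings)
  if (all(ratings == ratings[1]))
    input_error("ICC undefined: all ratings identical (zero total variance)")
  rm_ <- rowMeans(ratings)
  cm_ <- colMeans(ratings)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  structure(list(icc = icc, ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n = n, k = k), class = "icc_result")
}

#' Bland-Altman agreement between two paired measurements
#'
#' Differences are taken as `d = x - y`; the bias is `mean(d)` and the 95%
#' limits of agreement are `bias +/- 1.96 * sd(d)` (n-1 SD).
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, and `means`/`diffs` for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) input_error("x and y must have equal length")
  if (length(x) < 2) input_error("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n = length(d), means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

# NA when the ICC is undefined (zero total variance), e.g. the non-precise
# minimum when every VOI reaches the clipped-at-zero air floor
safe_icc <- function(mat) {
  tryCatch(icc_absolute_single(mat)$icc, error = function(e) NA_real_)
}

sweep_candidates <- function() {
  c("mean", "min", paste0("p", percentile_probs()), "max")
}

# numeric tie-break rank: percentiles by distance to the 50th (lower wins
# ties), then mean, then min, then max
candidate_tiebreak_rank <- function(metric) {
  vapply(metric, function(m) {
    if (grepl("^p[0-9]+$", m)) {
      p <- as.numeric(sub("^p", "", m))
      abs(p - 50) * 1000 + p
    } else {
      1e6 + match(m, c("mean", "median", "min", "max"))
    }
  }, numeric(1))
}

reshape_metric <- function(metrics, method, metric) {
  sub <- metrics[metrics$method == method, c("case_id", "reader", metric)]
  wide <- stats::reshape(sub, idvar = "case_id", timevar = "reader",
                         direction = "wide")
  wide[order(wide$case_id), , drop = FALSE]
}

#' Percentile sweep: which non-precise metric tracks the precise mean ADC?
#'
#' For every candidate non-precise histogram metric (mean, min, max and
#' every fifth percentile) and each of the four reader pairings
#' (precise-mean of R1 or R2 against the candidate metric of R3 or R4),
#' computes ICC(A,1) on the n x 2 case matrix. The best metric maximises
#' the pair-averaged ICC; ties prefer the percentile closest to the 50th,
#' then the lower percentile.
#'
#' @param metrics data.frame from [cohort_metrics()].
#' @return data.frame of class `sweep_table`: one row per candidate metric
#'   with the four pairwise ICCs and their average, ordered as the
#'   candidate list; attributes `best_metric` and `best_icc_range` (min and
#'   max of the best metric's four pairwise ICCs).
#' @export
percentile_sweep <- function(metrics) {
  pre <- reshape_metric(metrics, "precise", "mean")
  if (nrow(pre) < 2) input_error("need >= 2 complete cases for the sweep")
  pre_readers <- sort(sub("^mean\\.", "", names(pre)[-1]))
  non_readers <- sort(unique(metrics$reader[metrics$method == "nonprecise"]))
  rows <- lapply(sweep_candidates(), function(m) {
    nonp <- reshape_metric(metrics, "nonprecise", m)
    stopifnot(identical(pre$case_id, nonp$case_id))
    iccs <- c()
    for (pr in pre_readers) for (nr in non_readers) {
      mat <- cbind(pre[[paste0("mean.", pr)]], nonp[[paste0(m, ".", nr)]])
      iccs[paste(pr, nr, sep = "_")] <- safe_icc(mat)
    }
    data.frame(metric = m, t(iccs), icc_avg = mean(iccs),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ord <- order(-tab$icc_avg, candidate_tiebreak_rank(tab$metric),
               na.last = TRUE)
  best <- tab$metric[ord[1]]
  best_row <- tab[tab$metric == best, grep("^R", names(tab)), drop = FALSE]
  attr(tab, "best_metric") <- best
  attr(tab, "best_icc_range") <- range(as.numeric(best_row))
  class(tab) <- c("sweep_table", "data.frame")
  tab
}

#' Per-metric inter-reader and inter-method ICC table
#'
#' For every metric column: ICC(A,1) between the two precise readers,
#' between the two non-precise readers, and between the two methods after
#' averaging each method's readers.
#'
#' @param metrics data.frame from [cohort_metrics()].
#' @param metric_cols metric columns to tabulate (default: volume and all
#'   histogram metrics).
#' @return data.frame with columns `metric`, `icc_precise`,
#'   `icc_nonprecise`, `icc_between`.
#' @export
interreader_table <- function(metrics,
                              metric_cols = c("volume_cm3", "min", "max",
                                              "mean", "median", "sd", "skew",
                                              "kurt",
                                              paste0("p", percentile_probs()))) {
  avg <- reader_average(metrics)
  rows <- lapply(metric_cols, function(m) {
    pre <- reshape_metric(metrics, "precise", m)
    nonp <- reshape_metric(metrics, "nonprecise", m)
    between <- cbind(avg[[m]][avg$method == "precise"],
                     avg[[m]][avg$method == "nonprecise"])
    data.frame(metric = m,
               icc_precise = safe_icc(as.matrix(pre[, -1])),
               icc_nonprecise = safe_icc(as.matrix(nonp[, -1])),
               icc_between = safe_icc(between),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
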