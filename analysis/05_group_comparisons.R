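#!/usr/bin/env Rscript
# Stage 5 - histogram metrics vs prognostic subgroups.
#
# Reader-averaged metrics are compared between the two arms of each binary
# outcome (cN, cMRF, differentiation, response, metastasis) with a Welch t
# or Mann-Whitney test per the per-arm normality gate, and Holm-Bonferroni
# correction within each (method, outcome) family of 13 metrics.

library(adchist)

metrics <- read.csv("results/metrics.csv", stringsAsFactors = FALSE)
labels <- read.csv("results/labels.csv", stringsAsFactors = FALSE)

ot <- outcome_table(metrics, labels)
for (m in unique(ot$method))
  write.csv(ot[ot$method == m, ],
            sprintf("results/outcome_table_%s.csv", m), row.names = FALSE)

sig <- ot[ot$significant, ]
if (nrow(sig) == 0) {
  message("no metric reached Holm-corrected significance for any outcome")
} else {
  for (i in seq_len(nrow(sig)))
    message(sprintf(
      "significant after Holm: %s / %s / %s (p_raw %.4g, p_holm %.4g)",
      sig$method[i], sig$outcome[i], sig$metric[i],
      sig$p_raw[i], sig$p_holm[i]))
}
message(sprintf("%d comparisons written to results/outcome_table_*.csv",
                nrow(ot)))
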