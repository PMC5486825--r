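#!/usr/bin/env Rscript
# Stage 3 - first-order histogram metrics per VOI.
#
# Transfers each reader's VOI onto the fitted ADC map and extracts the full
# metric set (min, max, mean, median, SD, skewness, kurtosis, every fifth
# percentile, VOI volume). One row per (case, method, reader) goes to
# results/metrics.csv; a reader-level summary in the layout of a cohort
# description table goes to results/cohort_metrics_by_reader.csv.

library(adchist)

cohort_dir <- "scratch/cohort"
ids <- sort(sub("_dwi\\.nii\\.gz$", "",
                basename(list.files(cohort_dir,
                                    pattern = "_dwi\\.nii\\.gz$"))))
stopifnot(length(ids) > 0)

readers <- list(c("precise", "R1"), c("precise", "R2"),
                c("nonprecise", "R3"), c("nonprecise", "R4"))
rows <- list()
for (id in ids) {
  amap <- read_adc_map(file.path(cohort_dir, paste0(id, "_adc.nii.gz")),
                       file.path(cohort_dir, paste0(id, "_adc_valid.nii.gz")))
  for (r in readers) {
    voi <- read_voi_mask(file.path(cohort_dir,
                                   sprintf("%s_mask_%s_%s.nii.gz",
                                           id, r[1], r[2])), r[1], r[2])
    rows[[paste(id, r[2])]] <-
      cbind(data.frame(case_id = id, stringsAsFactors = FALSE),
            voi_metrics(amap, voi))
  }
}
metrics <- do.call(rbind, rows)
rownames(metrics) <- NULL
write.csv(metrics, "results/metrics.csv", row.names = FALSE)

by_reader <- aggregate(
  metrics[c("volume_cm3", "mean", "min", "max", "sd", "skew", "kurt",
            "p5", "p45", "p95")],
  by = list(method = metrics$method, reader = metrics$reader), FUN = mean)
write.csv(by_reader, "results/cohort_metrics_by_reader.csv",
          row.names = FALSE)

message(sprintf("%d metric rows written to results/metrics.csv", nrow(metrics)))
for (i in seq_len(nrow(by_reader)))
  message(sprintf(
    "  %-10s %s: volume %5.2f cm^3, mean ADC %.2f, SD %.2f, p45 %.2f",
    by_reader$method[i], by_reader$reader[i], by_reader$volume_cm3[i],
    by_reader$mean[i], by_reader$sd[i], by_reader$p45[i]))
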