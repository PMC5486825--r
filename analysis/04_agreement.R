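#!/usr/bin/env Rscript
# Stage 4 - inter-reader and inter-method agreement.
#
# From results/metrics.csv: ICC(A,1) per metric within and between
# delineation methods, Bland-Altman bias and limits of agreement for the
# reader-averaged mean ADC, and the percentile sweep that asks which
# non-precise histogram metric best stands in for the precise mean ADC.

library(adchist)

metrics <- read.csv("results/metrics.csv", stringsAsFactors = FALSE)

inter <- interreader_table(metrics)
write.csv(inter, "results/interreader_icc.csv", row.names = FALSE)

sweep <- percentile_sweep(metrics)
write.csv(as.data.frame(sweep), "results/sweep_table.csv", row.names = FALSE)
best <- attr(sweep, "best_metric")
rng <- attr(sweep, "best_icc_range")

avg <- reader_average(metrics)
pre <- avg[avg$method == "precise", ]
non <- avg[avg$method == "nonprecise", ]
ba_mean <- bland_altman(pre$mean, non$mean)
ba_best <- bland_altman(pre$mean, non[[best]])
ba <- data.frame(
  comparison = c("precise mean vs nonprecise mean",
                 paste("precise mean vs nonprecise", best)),
  bias = c(ba_mean$bias, ba_best$bias),
  sd_diff = c(ba_mean$sd_diff, ba_best$sd_diff),
  loa_low = c(ba_mean$loa_low, ba_best$loa_low),
  loa_high = c(ba_mean$loa_high, ba_best$loa_high))
write.csv(ba, "results/bland_altman.csv", row.names = FALSE)

pdf("results/bland_altman.pdf", width = 9, height = 4.5)
par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
for (i in 1:2) {
  b <- list(ba_mean, ba_best)[[i]]
  plot(b$means, b$diffs, pch = 19, cex = 0.7,
       xlab = expression("mean of methods (" * 10^-3 ~ mm^2 / s * ")"),
       ylab = "difference (precise - nonprecise)",
       main = ba$comparison[i], cex.main = 0.85)
  abline(h = c(b$bias, b$loa_low, b$loa_high), lty = c(1, 2, 2))
}
dev.off()

mean_row <- inter[inter$metric == "mean", ]
message(sprintf("within-method ICC (mean ADC): precise %.2f, non-precise %.2f",
                mean_row$icc_precise, mean_row$icc_nonprecise))
message(sprintf("between-method ICC (mean ADC): %.2f", mean_row$icc_between))
message(sprintf(
  "best non-precise surrogate for the precise mean ADC: %s (ICC %.2f-%.2f; non-precise mean alone: %.2f)",
  best, rng[1], rng[2], sweep$icc_avg[sweep$metric == "mean"]))
message(sprintf("Bland-Altman bias (mean vs mean): %.3f, LoA [%.3f, %.3f]",
                ba_mean$bias, ba_mean$loa_low, ba_mean$loa_high))
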