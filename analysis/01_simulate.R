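#!/usr/bin/env Rscript
# Stage 1 - simulate the synthetic DWI cohort.
#
# Generates 37 pelvic phantom cases under the default acquisition (b = 0,
# 25, 50, 100, 500, 1000 s/mm^2; 1.82 x 2.26 mm in-plane, 5.5 mm slice
# spacing), each with an ellipsoidal rectal tumor, contaminating tissues,
# two precise and two non-precise reader delineations, plus binary
# prognostic labels whose only true imaging signal is on tumor volume.
# Per-case NIfTI volumes go to scratch/cohort (regenerable, not tracked);
# the label table and a cohort summary go to results/.

library(adchist)

seed <- 42L
n_cases <- 37L
cohort_dir <- "scratch/cohort"
dir.create(cohort_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- phantom_config(seed = seed)
cohort <- generate_cohort(cfg, n_cases, outcome_effect = 2.5)

for (cs in cohort$cases) write_phantom_case(cs, cohort_dir)
write.csv(cohort$labels, "results/labels.csv", row.names = FALSE)

vols <- vapply(cohort$cases, function(cs) {
  sum(cs$label_map == 1) * prod(cs$dwi$voxel_spacing) / 1000
}, numeric(1))
summary_df <- data.frame(
  n_cases = n_cases, master_seed = seed,
  tumor_volume_cm3_mean = mean(vols), tumor_volume_cm3_sd = sd(vols),
  tumor_volume_cm3_min = min(vols), tumor_volume_cm3_max = max(vols),
  cN_positive = sum(cohort$labels$cN), cMRF_positive = sum(cohort$labels$cMRF))
write.csv(summary_df, "results/cohort_summary.csv", row.names = FALSE)

message(sprintf(
  "Simulated %d cases (seed %d): tumor volume %.2f +/- %.2f cm^3 (range %.2f-%.2f), %d cN+, %d cMRF+",
  n_cases, seed, mean(vols), sd(vols), min(vols), max(vols),
  sum(cohort$labels$cN), sum(cohort$labels$cMRF)))
message("NIfTI volumes in ", cohort_dir, "; labels in results/labels.csv")
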