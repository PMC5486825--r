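#!/usr/bin/env Rscript
# Stage 2 - fit voxelwise ADC maps.
#
# Reads every simulated DWI series (4-D NIfTI + bval sidecar) written by
# stage 1 and inverts the mono-exponential decay model by log-linear OLS at
# every voxel. ADC maps and fit-validity masks are written back next to the
# inputs.

library(adchist)

cohort_dir <- "scratch/cohort"
dwis <- sort(list.files(cohort_dir, pattern = "_dwi\\.nii\\.gz$",
                        full.names = TRUE))
stopifnot(length(dwis) > 0)

tumor_means <- numeric(0)
for (f in dwis) {
  id <- sub("_dwi\\.nii\\.gz$", "", basename(f))
  dwi <- read_dwi(f, file.path(cohort_dir, paste0(id, ".bval")))
  amap <- compute_adc_map(dwi)
  write_adc_map(amap,
                file.path(cohort_dir, paste0(id, "_adc.nii.gz")),
                file.path(cohort_dir, paste0(id, "_adc_valid.nii.gz")))
  labels <- RNifti::readNifti(file.path(cohort_dir,
                                        paste0(id, "_labels.nii.gz")))
  tumor_means <- c(tumor_means, mean(amap$adc[labels == 1]) * 1000)
}

message(sprintf(
  "Fitted %d ADC maps; tumor-label mean ADC %.2f +/- %.2f x 10^-3 mm^2/s",
  length(dwis), mean(tumor_means), sd(tumor_means)))
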