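test_that("phantom generation is bit-identical under a fixed seed", {
  cfg <- tiny_config()
  a <- build_phantom_case(cfg, 123L, "c1")
  b <- build_phantom_case(cfg, 123L, "c1")
  expect_identical(a, b)
  c2 <- build_phantom_case(cfg, 124L, "c1")
  expect_false(identical(a$dwi$signal, c2$dwi$signal))
})

test_that("noise-free signal follows the mono-exponential decay model", {
  expect_equal(1000 * exp(-1000 * 1.44e-3), 236.9, tolerance = 1e-3)
  cfg <- tiny_config(noise_sigma = 0)
  case <- build_phantom_case(cfg, 5L)
  v <- which(case$label_map == 1)[1]
  s0 <- cfg$tissue_params$s0[cfg$tissue_params$label == 1]
  expect_equal(case$dwi$signal[v + (seq_along(cfg$b_values) - 1) * length(case$label_map)],
               s0 * exp(-cfg$b_values * case$truth_adc$adc[v]),
               tolerance = 1e-12)
})

test_that("simulated signals are non-negative magnitudes", {
  case <- build_phantom_case(tiny_config(noise_sigma = 25), 9L)
  expect_true(all(case$dwi$signal >= 0))
})

test_that("tumor truth ADC matches the configured distribution", {
  tp <- default_tissue_params()
  tp$adc_sd[tp$tissue == "tumor"] <- 4.0e-4
  tp$adc_case_sd[tp$tissue == "tumor"] <- 0
  cfg <- phantom_config(tissue_params = tp)
  vals <- unlist(lapply(1:6, function(i) {
    cs <- build_phantom_case(cfg, 100L + i)
    cs$truth_adc$adc[cs$label_map == 1]
  }))
  se <- 4.0e-4 / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1.44e-3), 3 * se)
  expect_equal(sd(vals), 4.0e-4, tolerance = 0.05)
})

test_that("precise masks reproduce the tumor at zero jitter and perturb its boundary otherwise", {
  cfg <- tiny_config()
  case <- build_phantom_case(cfg, 21L)
  tumor <- case$label_map == 1

  m0 <- draw_precise_mask(case, 0, 1L)
  expect_identical(m0$mask, tumor)
  expect_equal(compute_volume(m0), sum(tumor) * prod(cfg$voxel_spacing) / 1000)

  # inter-reader overlap at the calibrated default jitter, on the default
  # tumor geometry
  case <- build_phantom_case(phantom_config(), 21L)
  tumor <- case$label_map == 1
  mA <- draw_precise_mask(case, 0.2, 11L)
  mB <- draw_precise_mask(case, 0.2, 12L)
  expect_false(identical(mA$mask, mB$mask))
  expect_gt(dice_coefficient(mA$mask, mB$mask), 0.8)
  # the eroded tumor core survives any jitter
  b <- adchist:::slice_boundaries(tumor)
  core <- tumor & !b$inner
  expect_true(all(mA$mask[core]))
  expect_true(all(mB$mask[core]))
})

test_that("non-precise masks contain the tumor cross-section and mix tissues", {
  cfg <- tiny_config(reader_jitter = 0)
  case <- build_phantom_case(cfg, 33L)
  tumor <- case$label_map == 1

  m0 <- draw_nonprecise_mask(case, 0, 1L)
  expect_true(all(m0$mask[tumor]))

  m <- case$nonprecise_masks$R3
  expect_true(all(m$mask[tumor]))          # precise (= tumor) nested inside
  expect_gte(length(unique(case$label_map[m$mask])), 2)
  expect_gt(sum(m$mask), sum(tumor))
})

test_that("oversized tumors are rejected with the offending semi-axis named", {
  expect_error(phantom_config(tumor_semiaxes = list(x = c(7, 60), y = c(7, 13),
                                                    z = c(6, 12))),
               "semi-axis x")
})

test_that("cohorts have unique ids, complete binary labels, and reject n < 2", {
  cfg <- tiny_config()
  coh <- generate_cohort(cfg, 6)
  expect_length(unique(vapply(coh$cases, `[[`, character(1), "case_id")), 6)
  expect_identical(sort(names(coh$labels)),
                   sort(c("case_id", "cN", "cMRF", "differentiation",
                          "response", "metastasis")))
  expect_true(all(unlist(coh$labels[, -1]) %in% 0:1))
  expect_error(generate_cohort(cfg, 1), "n_cases")
})

test_that("NIfTI export round-trips signal, b-values and spacing", {
  dir <- withr::local_tempdir()
  case <- build_phantom_case(tiny_config(), 77L, "rt")
  write_phantom_case(case, dir)
  dwi <- read_dwi(file.path(dir, "rt_dwi.nii.gz"), file.path(dir, "rt.bval"))
  expect_equal(dwi$b_values, case$dwi$b_values)
  expect_equal(dwi$voxel_spacing, case$dwi$voxel_spacing, tolerance = 1e-6)
  expect_equal(dwi$signal, case$dwi$signal, tolerance = 1e-6,
               ignore_attr = TRUE)
})
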