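make_map <- function(values, valid = TRUE, spacing = c(1, 1, 1)) {
  arr <- array(values, c(length(values), 1, 1))
  structure(list(adc = arr / 1000, voxel_spacing = spacing,
                 fit_valid = array(rep_len(valid, length(values)),
                                   dim = dim(arr))),
            class = "adc_map")
}
make_mask <- function(sel, n, spacing = c(1, 1, 1), method = "precise") {
  m <- array(FALSE, c(n, 1, 1)); m[sel] <- TRUE
  structure(list(mask = m, method = method, reader_id = "R1",
                 voxel_spacing = spacing), class = "voi_mask")
}

test_that("VOI extraction is a direct lookup that excludes invalid fits", {
  map <- make_map(c(1.2, 1.4, 1.6, 9.9))
  voi <- make_mask(1:3, 4)
  expect_equal(sort(extract_voi_values(map, voi)$values), c(1.2, 1.4, 1.6))

  map$fit_valid[2] <- FALSE
  s <- extract_voi_values(map, voi)
  expect_equal(sort(s$values), c(1.2, 1.6))
  expect_equal(s$n_excluded, 1)

  expect_error(extract_voi_values(map, make_mask(1, 5)), "do not match")
  map$fit_valid[] <- FALSE
  expect_error(extract_voi_values(map, voi), "valid ADC fit")
})

test_that("histogram metrics match closed-form values on simple samples", {
  m <- compute_histogram_metrics(c(1, 2, 3), voxel_volume_mm3 = 10)
  expect_equal(m$mean, 2)
  expect_equal(m$median, 2)
  expect_equal(m$min, 1)
  expect_equal(m$max, 3)
  expect_equal(m$skew, 0)
  expect_equal(m$volume_cm3, 0.03)
  expect_equal(m$n_voxels, 3)

  # skewness/kurtosis undefined below 3 values
  m2 <- compute_histogram_metrics(c(1, 2), 1)
  expect_true(is.na(m2$skew) && is.na(m2$kurt))

  expect_error(compute_histogram_metrics(numeric(0), 1), "empty")
})

test_that("kurtosis uses the Pearson convention and moments match e1071", {
  set.seed(3)
  z <- rnorm(1e5)
  m <- compute_histogram_metrics(z, 1)
  expect_equal(m$kurt, 3, tolerance = 0.1 / 3)
  expect_lt(abs(m$skew), 0.05)

  x <- rgamma(500, shape = 2)
  mx <- compute_histogram_metrics(x, 1)
  expect_equal(mx$skew, e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(mx$kurt, e1071::kurtosis(x, type = 1) + 3, tolerance = 1e-12)
})

test_that("percentiles interpolate linearly and match a brute-force oracle", {
  m <- compute_histogram_metrics(0:100, 1)
  expect_equal(m$p45, 45)
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(5:200, 1))
    m <- compute_histogram_metrics(x, 1)
    for (p in seq(5, 95, 5))
      expect_equal(m[[paste0("p", p)]], percentile_bruteforce(x, p / 100),
                   tolerance = 1e-12)
  }
})

test_that("metric invariances: permutation, shift, percentile monotonicity", {
  set.seed(15)
  for (i in 1:15) {
    x <- rlnorm(sample(10:300, 1))
    a <- compute_histogram_metrics(x, 2)
    b <- compute_histogram_metrics(sample(x), 2)
    expect_equal(a, b)

    shift <- runif(1, -5, 5)
    s <- compute_histogram_metrics(x + shift, 2)
    for (f in c("min", "max", "mean", "median", paste0("p", seq(5, 95, 5))))
      expect_equal(s[[f]], a[[f]] + shift, tolerance = 1e-9)
    for (f in c("sd", "skew", "kurt"))
      expect_equal(s[[f]], a[[f]], tolerance = 1e-7)

    q <- unlist(a[paste0("p", seq(5, 95, 5))])
    expect_true(all(diff(q) >= 0))
    expect_true(a$min <= q[1] && q[length(q)] <= a$max)
    expect_equal(a$median, a$p50)
  }
})

test_that("volume counts every delineated voxel, valid fit or not", {
  expect_equal(compute_volume(make_mask(1:100, 120,
                                        spacing = c(1.82, 2.26, 5.5))),
               2.262, tolerance = 1e-3)
  expect_equal(compute_volume(make_mask(integer(0), 10)), 0)

  map <- make_map(rep(1.5, 10), valid = c(rep(TRUE, 7), rep(FALSE, 3)))
  voi <- make_mask(1:10, 10)
  row <- voi_metrics(map, voi)
  expect_equal(row$n_voxels, 7)
  expect_equal(row$n_excluded, 3)
  expect_equal(row$volume_cm3, 10 * 1 / 1000)
})

test_that("non-precise VOIs are wider and higher-ADC than precise on a phantom case", {
  case <- build_phantom_case(phantom_config(), 42L)
  amap <- compute_adc_map(case$dwi)
  p <- voi_metrics(amap, case$precise_masks$R1)
  np <- voi_metrics(amap, case$nonprecise_masks$R3)
  expect_gt(np$sd, p$sd)
  expect_gt(np$volume_cm3, p$volume_cm3)
  expect_lt(np$min, p$min + 1e-9)
})
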