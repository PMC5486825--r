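test_that("ICC(A,1) limits: perfect agreement, pure noise, degenerate input", {
  x <- cbind(c(1, 2, 3, 4, 8), c(1, 2, 3, 4, 8))
  expect_equal(icc_absolute_single(x)$icc, 1)

  set.seed(2)
  noise <- matrix(rnorm(5000 * 2), ncol = 2)   # no subject effect
  expect_lt(abs(icc_absolute_single(noise)$icc), 0.05)

  expect_error(icc_absolute_single(matrix(3, 4, 2)), "identical")
  expect_error(icc_absolute_single(matrix(1:4, 2, 2) * NA), "finite")
  expect_error(icc_absolute_single(matrix(1:3, 3, 1)), "at least 2 x 2")
})

test_that("ICC formula matches the brute-force variance-components oracle", {
  fixed <- matrix(c(9, 2, 5, 8, 2, 8,
                    10, 4, 6, 9, 4, 7), ncol = 2)
  expect_equal(icc_absolute_single(fixed)$icc, icc_bruteforce(fixed),
               tolerance = 1e-12)

  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:30, 1); k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)) +
                  rep(rnorm(n, sd = runif(1, 0, 2)), k), n, k)
    r <- icc_absolute_single(x)
    expect_equal(r$icc, icc_bruteforce(x), tolerance = 1e-10)
    # internal consistency with its own mean squares
    expect_equal(r$icc,
                 (r$ms_rows - r$ms_error) /
                   (r$ms_rows + (r$k - 1) * r$ms_error +
                      (r$k / r$n) * (r$ms_cols - r$ms_error)),
                 tolerance = 1e-12)
  }
})

test_that("ICC is shift-invariant and scale-invariant", {
  set.seed(5)
  for (i in 1:20) {
    x <- matrix(rnorm(12, sd = 2) + rep(rnorm(6), 2), 6, 2)
    base <- icc_absolute_single(x)$icc
    expect_equal(icc_absolute_single(x + 7.3)$icc, base, tolerance = 1e-10)
    expect_equal(icc_absolute_single(x * 2.6)$icc, base, tolerance = 1e-10)
  }
})

test_that("Bland-Altman bias and limits follow the d = x - y convention", {
  x <- c(1.2, 1.5, 1.9, 2.2)
  b <- bland_altman(x, x)
  expect_equal(c(b$bias, b$loa_low, b$loa_high), c(0, 0, 0))

  b <- bland_altman(x, x + 0.07)
  expect_equal(b$bias, -0.07)
  expect_equal(b$sd_diff, 0)

  b <- bland_altman(c(0.9, 1.0, 1.1), c(1, 1, 1))   # d = {-0.1, 0, 0.1}
  expect_equal(b$bias, 0)
  expect_equal(b$sd_diff, 0.1)
  expect_equal(b$loa_high, 1.96 * 0.1)
  expect_equal(b$loa_low, -1.96 * 0.1)

  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("about 95% of normal differences fall inside the limits of agreement", {
  set.seed(9)
  x <- rnorm(2000, 1.5, 0.2)
  y <- x + rnorm(2000, 0.05, 0.1)
  b <- bland_altman(x, y)
  cover <- mean(b$diffs >= b$loa_low & b$diffs <= b$loa_high)
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("a perfect surrogate drives every sweep ICC to 1 with the tie rule", {
  set.seed(4)
  n <- 10
  meanadc <- rnorm(n, 1.44, 0.25)
  rows <- list()
  for (r in c("R1", "R2", "R3", "R4")) {
    method <- if (r %in% c("R1", "R2")) "precise" else "nonprecise"
    df <- data.frame(case_id = sprintf("c%02d", 1:n), method = method,
                     reader = r, stringsAsFactors = FALSE)
    for (m in c("mean", "min", "max", paste0("p", seq(5, 95, 5))))
      df[[m]] <- meanadc
    rows[[r]] <- df
  }
  met <- do.call(rbind, rows)
  sw <- percentile_sweep(met)
  expect_true(all(abs(sw$icc_avg - 1) < 1e-12))
  expect_equal(attr(sw, "best_metric"), "p50")   # percentile nearest 50 wins
  expect_equal(attr(sw, "best_icc_range"), c(1, 1))
})

test_that("identical precise and non-precise masks make the mean its own best surrogate", {
  cfg <- tiny_config(margin_mm = 0, reader_jitter = 0)
  coh <- generate_cohort(cfg, 8)
  met <- cohort_metrics(coh$cases)
  # bounding ellipse of an ellipsoid cross-section at zero margin is the
  # cross-section itself, so the two methods coincide
  expect_equal(met$mean[met$method == "precise"],
               met$mean[met$method == "nonprecise"], tolerance = 1e-12)
  sw <- percentile_sweep(met)
  expect_equal(attr(sw, "best_metric"), "mean")
  expect_equal(sw$icc_avg[sw$metric == "mean"], 1, tolerance = 1e-9)

  it <- interreader_table(met, metric_cols = c("mean", "sd", "p45"))
  expect_true(all(abs(it$icc_precise - 1) < 1e-9))
  expect_true(all(abs(it$icc_nonprecise - 1) < 1e-9))
})

test_that("sweep output is deterministic for a fixed cohort seed", {
  cfg <- tiny_config(seed = 6L)
  met1 <- cohort_metrics(generate_cohort(cfg, 5)$cases)
  met2 <- cohort_metrics(generate_cohort(cfg, 5)$cases)
  expect_identical(percentile_sweep(met1), percentile_sweep(met2))
})
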