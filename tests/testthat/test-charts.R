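test_that("internal-control normalization divides by the panel mean", {
  expect_equal(normalize_to_internal_controls(
    400, internal_controls(100, 100, 100, 100)), 4.0)
  expect_equal(normalize_to_internal_controls(
    0, internal_controls(10, 20, 30, 40)), 0.0)
  expect_equal(normalize_to_internal_controls(
    300, internal_controls(100, 200, 300, 400)), 1.2)
  expect_equal(normalize_to_internal_controls(
    300, internal_controls(100, 200, 300, 400), scale = 10), 12)
  expect_error(normalize_to_internal_controls(
    100, internal_controls(0, 0, 0, 0)), "undefined normalization")
})

test_that("limits are mean +/- 3 sample SD and invert exactly", {
  s <- control_series("X", "fusion_reads", c(10, 10, 10))
  lim <- derive_limits(s)
  expect_equal(lim$lower, 10)
  expect_equal(lim$upper, 10)
  expect_error(derive_limits(control_series("X", "fusion_reads", 5)),
               "insufficient baseline")

  # a baseline with mean 1565 and sd 346.667 reproduces the established
  # 525-2605 range for the normalized CCDC6-RET control
  m <- 1565; sdev <- 346.667
  s2 <- control_series("CCDC6-RET", "fusion_reads", c(m - sdev, m, m + sdev))
  lim2 <- derive_limits(s2)
  expect_equal(lim2$lower, m - 3 * sdev, tolerance = 1e-12)
  expect_equal(lim2$upper, m + 3 * sdev, tolerance = 1e-12)

  # symmetric values: mean is exactly the centre
  s3 <- control_series("Y", "cna_fold_change", c(2, 3, 4, 3, 2, 4))
  expect_equal(derive_limits(s3)$mean, 3)

  expect_equal(recover_mean_sd(control_limits_from_range("a", 525, 2605)),
               list(mean = 1565, sd = 346.667), tolerance = 1e-4)
  expect_equal(recover_mean_sd(control_limits_from_range("b", 1.73, 3.18)),
               list(mean = 2.455, sd = 0.2417), tolerance = 1e-3)
  expect_equal(recover_mean_sd(control_limits_from_range("c", 7, 7)),
               list(mean = 7, sd = 0))
})

test_that("derive/recover round-trips and scales over random baselines", {
  set.seed(77)
  for (i in 1:50) {
    v <- rnorm(sample(2:12, 1), mean = runif(1, 1, 5000),
               sd = runif(1, 0, 300))
    s <- control_series("Z", "fusion_reads", v)
    lim <- derive_limits(s)
    rec <- recover_mean_sd(lim)
    expect_equal(rec$mean, mean(v), tolerance = 1e-9)
    expect_equal(rec$sd, sd(v), tolerance = 1e-9)

    # scale equivariance: c * values scales every limit component by c
    cc <- runif(1, 0.1, 10)
    lim2 <- derive_limits(control_series("Z", "fusion_reads", cc * v))
    expect_equal(lim2$mean, cc * lim$mean, tolerance = 1e-9 * cc)
    expect_equal(lim2$sd, cc * lim$sd, tolerance = 1e-8 * max(1, lim$sd))
    expect_equal(lim2$lower, cc * lim$lower, tolerance = 1e-7)
    expect_equal(lim2$upper, cc * lim$upper, tolerance = 1e-7)
  }
})

test_that("point classification is closed-interval against the limits", {
  lim <- control_limits_from_range("CCDC6-RET", 525, 2605)
  expect_identical(evaluate_point(2605, lim), "in_control")
  expect_identical(evaluate_point(525, lim), "in_control")
  expect_identical(evaluate_point(2600, lim), "in_control")
  expect_identical(evaluate_point(2606, lim), "out_of_control_high")
  lim2 <- control_limits_from_range("EML4-ALK", 2880, 7474)
  expect_identical(evaluate_point(2879, lim2), "out_of_control_low")
})

test_that("every established QC range accepts its midpoint", {
  ref <- reference_control_limits()
  expect_identical(nrow(ref), 5L)
  for (i in seq_len(nrow(ref))) {
    lim <- control_limits_from_range(ref$analyte_id[i], ref$lower[i],
                                     ref$upper[i])
    expect_identical(evaluate_point((ref$lower[i] + ref$upper[i]) / 2, lim),
                     "in_control")
  }
})

test_that("control charts render to file", {
  s <- control_series("CCDC6-RET", "fusion_reads",
                      c(1500, 1600, 1400, 1700, 1550, 1450, 1620))
  f <- tempfile(fileext = ".png")
  lim <- plot_control_chart(s, file = f)
  expect_true(file.exists(f))
  expect_s3_class(lim, "control_limits")
  unlink(f)
})
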