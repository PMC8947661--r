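test_that("replicate summaries use sample SD and report-style rounding", {
  s <- replicate_summary(c(49, 46, 31))
  expect_equal(s$mean, 42)
  expect_identical(s$display_mean, "42")
  expect_identical(s$display_cv, "23.0")

  s2 <- replicate_summary(c(5.64, 5.08), mean_decimals = 2)
  expect_identical(s2$display_mean, "5.36")
  expect_identical(s2$display_cv, "7.4")

  # the two-replicate row separates the SD conventions: population SD
  # would print 8.6, sample SD prints the reported 12.1
  expect_identical(replicate_summary(c(549, 652))$display_cv, "12.1")

  expect_equal(replicate_summary(c(4, 4, 4))$cv_percent, 0)
  expect_true(is.na(replicate_summary(7)$sd))
  expect_error(replicate_summary(c(-1, 1)), "mean is zero")

  # display rounding is half away from zero: a .5 mean rounds up
  expect_identical(replicate_summary(c(549, 652))$display_mean, "601")
  expect_equal(round_half_up(600.5, 0), 601)
  expect_equal(round_half_up(-600.5, 0), -601)
  expect_equal(round_half_up(2.345, 2), 2.35)
})

test_that("summary agrees with a brute-force oracle on random vectors", {
  set.seed(123)
  for (i in 1:1000) {
    v <- runif(sample(2:10, 1), -100, 100)
    if (abs(mean(v)) < 1e-6) next
    s <- replicate_summary(v)
    o <- oracle_summary(v)
    expect_equal(s$mean, o$mean, tolerance = 1e-9)
    expect_equal(s$sd, o$sd, tolerance = 1e-9)
    expect_equal(s$cv_percent, o$cv, tolerance = 1e-9)
  }
})

test_that("detection rates exclude invalid calls from the denominator", {
  ros1 <- load_ros1_series()
  r <- detection_rate_by_dilution(ros1)
  expect_true(all(r$fraction == 1))

  erbb2 <- load_erbb2_series()
  r2 <- detection_rate_by_dilution(erbb2)
  expect_equal(r2$fraction, c(1, 1, 1, 0, 0))

  mixed <- dilution_series("fusion", "X", data.frame(
    dilution = c("D1", "D1", "D1", "D2", "D2"),
    replicate = paste0("R", c(1, 2, 3, 1, 2)),
    measurement = c(10, 12, 99, 5, 6), p_value = NA_real_,
    call = c("detected", "detected", "invalid", "invalid", "invalid"),
    stringsAsFactors = FALSE))
  expect_warning(r3 <- detection_rate_by_dilution(mixed), "no valid")
  expect_equal(r3$valid_total, c(2, 0))
  expect_true(is.na(r3$fraction[2]))
  expect_true(r3$flagged[2])
})

test_that("LOD is the lowest dilution still at 100% detection", {
  lod <- determine_lod(load_ros1_series())
  expect_identical(lod$lod_dilution, "D5")
  expect_equal(lod$lod_value, 42)

  lod2 <- determine_lod(load_erbb2_series())
  expect_identical(lod2$lod_dilution, "D3")
  expect_equal(lod2$lod_value, 1.40)

  # consistency: the LOD value equals the replicate-summary mean there
  ros1 <- load_ros1_series()
  d5 <- ros1$rows$measurement[ros1$rows$dilution == "D5"]
  expect_equal(lod$lod_value, replicate_summary(d5)$mean)

  # a single fully-detected dilution followed by misses returns it
  one <- dilution_series("fusion", "X", data.frame(
    dilution = c("D1", "D1", "D2", "D2"), replicate = c("R1", "R2", "R1", "R2"),
    measurement = c(50, 60, 1, 0), p_value = NA_real_,
    call = c("detected", "detected", "not_detected", "not_detected"),
    stringsAsFactors = FALSE))
  expect_identical(determine_lod(one)$lod_dilution, "D1")

  none <- dilution_series("fusion", "X", data.frame(
    dilution = c("D1", "D1", "D2"), replicate = c("R1", "R2", "R1"),
    measurement = c(50, 1, 1), p_value = NA_real_,
    call = c("detected", "not_detected", "not_detected"),
    stringsAsFactors = FALSE))
  expect_warning(lodn <- determine_lod(none), "LOD undefined")
  expect_true(is.na(lodn$lod_dilution))
})

test_that("LOD verification needs every expected variant detected", {
  calls <- data.frame(target_id = c("EGFR", "ERBB2", "MET"),
                      call = "detected", stringsAsFactors = FALSE)
  res <- verify_at_lod(calls, calls$target_id)
  expect_true(res$pass)
  expect_equal(res$fraction_detected, 1)

  calls$call[2] <- "not_detected"
  res2 <- verify_at_lod(calls, calls$target_id)
  expect_false(res2$pass)
  expect_equal(res2$fraction_detected, 2 / 3, tolerance = 1e-12)
})

test_that("specificity pools per-sample counts conservatively", {
  coh <- make_negative_cohort(12, 95, 12, assay_profile(seed = 19L))
  sp <- specificity(coh, 95, 12)
  expect_identical(sp$fusion$overall_assayed,
                   sum(sp$fusion$per_sample$assayed))
  expect_identical(sp$cna$overall_detected, sum(sp$cna$per_sample$detected))

  # a single detection among 1140: pooled 99.9%, that donor 98.9%
  ct <- cohort_call_table(coh)
  i <- which(ct$variant_kind == "fusion" & ct$sample_id == "NHD4")[1]
  ct$call[i] <- "detected"
  sp2 <- specificity(ct, 95, 12)
  expect_equal(sp2$fusion$overall_specificity_percent, 99.9)
  per <- sp2$fusion$per_sample
  expect_equal(per$specificity_percent[per$sample_id == "NHD4"], 98.9)

  # QC-failed samples are excluded with a warning, shrinking the pool
  expect_warning(sp3 <- specificity(ct, 95, 12, qc_failed = "NHD1"),
                 "NHD1")
  expect_identical(sp3$fusion$overall_assayed, 11L * 95L)
})

test_that("hit rate rounds to one decimal, half away from zero", {
  expect_equal(hit_rate(18, 18), 100.0)
  expect_equal(hit_rate(28, 29), 96.6)
  expect_equal(hit_rate(0, 5), 0.0)
  expect_error(hit_rate(6, 5))
})

test_that("precision analysis separates within-run and between-run CVs", {
  # identical measurements: every CV 0, hit rate 100%
  st <- make_precision_study(assay_profile(seed = 41L),
                             precision_design(
                               within_run_cv = c(fusion = 1e-12, cna = 1e-12),
                               between_run_cv = c(fusion = 1e-12,
                                                  cna = 1e-12)))
  pr <- precision_analysis(st)
  expect_equal(pr$fusion$hit$percent, 100)
  expect_equal(pr$fusion$average_repeatability_cv, 0, tolerance = 1e-6)
  expect_equal(pr$cna$average_intermediate_cv, 0, tolerance = 1e-6)

  # a sub-threshold event is a miss and leaves that run's CV cell
  st2 <- make_precision_study(
    assay_profile(seed = 41L),
    miss_events = data.frame(target_id = "CDK6", run = 3),
    censored_events = data.frame(target_id = "MYC", run = 4))
  pr2 <- precision_analysis(st2)
  expect_identical(pr2$cna$hit$expected, 29L)
  expect_identical(pr2$cna$hit$detected, 28L)
  expect_equal(pr2$cna$hit$percent, 96.6)
  cdk6 <- pr2$cna$intermediate[pr2$cna$intermediate$target_id == "CDK6", ]
  expect_identical(cdk6$n_runs, 3L)  # the missed run is out of the CV

  # grouped breakdowns exist for day / operator / instrument
  pr3 <- precision_analysis(st2, extra_groupings = c("day", "operator",
                                                     "instrument"))
  expect_true(all(c("by_day", "by_operator", "by_instrument") %in%
                    names(pr3$fusion)))
})
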