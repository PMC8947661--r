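test_that("fusion count simulation is seeded, ranged and mean-calibrated", {
  p <- assay_profile(seed = 7L)
  expect_identical(simulate_fusion_counts(p, 5, 20),
                   simulate_fusion_counts(p, 5, 20))
  expect_false(identical(simulate_fusion_counts(p, 5, 20, seed = 1L),
                         simulate_fusion_counts(p, 5, 20, seed = 2L)))
  expect_error(simulate_fusion_counts(p, 0, 5), "out of range")
  expect_error(simulate_fusion_counts(p, 6, 5), "out of range")

  # degenerate profile with a single near-zero dilution: all counts 0
  p0 <- assay_profile(fusion_count_mean_at_neat = 1e-12,
                      dilution_factors = 1e-300,
                      tumor_fraction_per_dilution = 0)
  expect_true(all(simulate_fusion_counts(p0, 1, 50) == 0))

  # Monte-Carlo mean at the lowest dilution within 3 SE of the
  # configured 42-copy level
  x <- simulate_fusion_counts(p, 5, 1000)
  mu <- p$fusion_count_mean_at_neat * p$dilution_factors[5]
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(1000))
  expect_equal(mu, 42, tolerance = 1e-12)
})

test_that("CNA ratio simulation attenuates toward 1 and is calibrated", {
  p <- assay_profile(seed = 7L)

  # no tumor fraction, no noise: exactly 1.0 and a non-significant p
  pflat <- assay_profile(tumor_fraction_per_dilution = 0,
                         dilution_factors = 1, ratio_noise_sd = 0)
  sim <- simulate_cna_ratio(pflat, 1, 10)
  expect_true(all(sim$fold_change == 1))
  expect_true(all(sim$p_value == 1))

  # dilution-3 mean calibrated to 1.40, recovered within 3 SE
  sim3 <- simulate_cna_ratio(p, 3, 1000)
  expect_lt(abs(mean(sim3$fold_change) - 1.40),
            3 * sd(sim3$fold_change) / sqrt(1000))

  # dilutions 4-5 are below detectability: the joint ratio+p gate fires
  # in fewer than 5% of replicates
  th <- qc_thresholds()
  for (i in 4:5) {
    simi <- simulate_cna_ratio(p, i, 1000)
    frac <- mean(simi$fold_change >= th$cna_min_ratio &
                   simi$p_value < th$cna_max_p)
    expect_lt(frac, 0.05)
  }
})

test_that("simulated means shrink monotonically along the dilution order", {
  p <- assay_profile(seed = 13L)
  fus_means <- vapply(1:5, function(i)
    mean(simulate_fusion_counts(p, i, 500)), numeric(1))
  expect_true(all(diff(fus_means) < 0))
  cna_means <- vapply(1:5, function(i)
    mean(simulate_cna_ratio(p, i, 500)$fold_change), numeric(1))
  expect_true(all(diff(cna_means) <= 0))
  expect_true(all(cna_means >= 1 - 3 * p$ratio_noise_sd))
})

test_that("dilution series carry the requested replicate structure", {
  p <- assay_profile(seed = 5L)
  for (kind in c("fusion", "cna")) {
    s <- make_dilution_series(p, kind, c(2, 3, 3, 3, 3))
    expect_s3_class(s, "dilution_series")
    expect_identical(nrow(s$rows), 14L)
    expect_identical(as.character(unique(s$rows$dilution)), paste0("D", 1:5))
  }
  expect_error(make_dilution_series(p, "fusion", c(0, 0, 0, 0, 0)),
               "empty series")
  expect_error(make_dilution_series(p, "fusion", c(2, 3, 3)),
               "one entry per dilution")
  # determinism end to end
  expect_identical(make_dilution_series(p, "cna", c(2, 3, 3, 3, 3)),
                   make_dilution_series(p, "cna", c(2, 3, 3, 3, 3)))
})

test_that("negative cohorts have the right shape and no signal", {
  p <- assay_profile(seed = 3L)
  coh <- make_negative_cohort(12, 95, 12, p)
  expect_length(coh, 12)
  ct <- cohort_call_table(coh)
  expect_identical(nrow(ct), 12L * (95L + 12L))
  expect_identical(sum(ct$variant_kind == "fusion"), 12L * 95L)
  expect_true(all(vapply(coh, function(s) s$role == "nhd", logical(1))))
  expect_true(all(vapply(coh, function(s)
    fusion_sample_valid(s$controls), logical(1))))

  # single sample, zero noise: nothing can be called
  pq <- assay_profile(background_fusion_mean = 0, ratio_noise_sd = 0,
                      seed = 3L)
  c1 <- make_negative_cohort(1, 1, 1, pq)
  expect_identical(sum(cohort_call_table(c1)$call == "detected"), 0L)
})

test_that("background-only cohorts stay detection-free across 100 draws", {
  # soundness of the negative-control generator: at default background and
  # noise no target should ever clear the call gates
  p <- assay_profile(seed = 17L)
  total <- 0L
  for (k in 1:100) {
    coh <- make_negative_cohort(12, 95, 12, p, seed = 50000L + k)
    total <- total + sum(cohort_call_table(coh)$call == "detected")
  }
  expect_identical(total, 0L)
})

test_that("NTC samples carry zero true-variant signal", {
  p <- assay_profile(seed = 23L)
  batch <- make_batch(p, n_clinical = 1)
  roles <- vapply(batch, function(s) s$role, character(1))
  ntc <- batch[[which(roles == "ntc")]]
  expect_true(all(ntc$fusion_rows$molecular_copies == 0))
  expect_true(all(ntc$cna_rows$fold_change <= 1))
  expect_true(evaluate_ntc(ntc$metrics, 0))
})

test_that("precision studies follow the runs x days x operators design", {
  p <- assay_profile(seed = 29L)
  st <- make_precision_study(p)
  # 3 fusion specimens x (3 within-run + 3 further runs) = 18 rows
  expect_identical(sum(st$variant_kind == "fusion"), 18L)
  expect_identical(sum(st$variant_kind == "cna"), 30L)
  expect_equal(sort(unique(st$run)), c(1, 2, 3, 4))
  expect_equal(sort(unique(st$operator)), c(1, 2))
  expect_equal(sort(unique(st$instrument)), c(1, 2))
  # fusion and CNA arms run on different day schedules sharing days 3-5
  expect_equal(sort(unique(st$day[st$variant_kind == "fusion"])),
               c(2, 3, 4, 5))
  expect_equal(sort(unique(st$day[st$variant_kind == "cna"])),
               c(1, 3, 4, 5))
  # repeatability run is the triplicate one
  expect_equal(max(st$replicate[st$run == 1]), 3)
  expect_true(all(st$replicate[st$run > 1] == 1))
  expect_identical(make_precision_study(p), make_precision_study(p))

  miss <- data.frame(target_id = "CDK6", run = 3)
  cens <- data.frame(target_id = "MYC", run = 4)
  st2 <- make_precision_study(p, miss_events = miss, censored_events = cens)
  expect_false(all(st2$qc_pass))
  expect_lt(st2$measurement[st2$target_id == "CDK6" & st2$run == 3],
            qc_thresholds()$cna_min_ratio)
})

test_that("precision generator recovers its configured within-run CV", {
  # independent oracle: expected value of the triplicate sample CV under
  # the lognormal measurement model at 20% within-run CV
  cv <- 0.20
  sdl <- sqrt(log(1 + cv^2))
  set.seed(9001)
  oracle <- mean(replicate(20000, {
    x <- rlnorm(3, 0, sdl)
    sd(x) / mean(x)
  })) * 100

  p <- assay_profile(seed = 31L)
  des <- precision_design(within_run_cv = c(fusion = cv, cna = 0.02))
  cells <- unlist(lapply(1:200, function(k) {
    st <- make_precision_study(p, des, seed = 60000L + k)
    pr <- precision_analysis(st)
    pr$fusion$repeatability$cv_percent
  }))
  se <- sd(cells) / sqrt(length(cells))
  expect_lt(abs(mean(cells) - oracle), 3 * se)
})
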