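test_that("sample gates use inclusive minima and a strict MAPD maximum", {
  th <- qc_thresholds()
  at_boundary <- sample_metrics(1e7, 95, 1500, 80, 80, 80, 0.39)
  expect_true(evaluate_sample_qc(at_boundary, th)$pass)

  one_short <- sample_metrics(9999999, 97, 2500, 90, 100, 90, 0.2)
  res <- evaluate_sample_qc(one_short, th)
  expect_false(res$pass)
  expect_identical(res$failed_gates, "mapped_reads")

  # MAPD exactly at the limit fails: the rule is strictly below
  at_mapd <- sample_metrics(1.5e7, 97, 2500, 90, 100, 90, 0.4)
  res <- evaluate_sample_qc(at_mapd, th)
  expect_false(res$pass)
  expect_identical(res$failed_gates, "mapd")

  expect_error(sample_metrics(NA, 97, 2500, 90, 100, 90, 0.2),
               "missing or non-finite")
})

test_that("fusion validity needs one control from each pair", {
  th <- qc_thresholds()
  expect_true(fusion_sample_valid(internal_controls(3, 0, 0, 3), th))
  expect_false(fusion_sample_valid(internal_controls(2, 2, 100, 100), th))
  expect_false(fusion_sample_valid(internal_controls(100, 100, 2, 2), th))
  expect_false(fusion_sample_valid(internal_controls(0, 0, 0, 0), th))
})

test_that("fusion calls gate on copies and internal-control validity", {
  th <- qc_thresholds()
  expect_identical(call_fusion(31, valid_controls(), th), "detected")
  expect_identical(call_fusion(3, valid_controls(), th), "detected")
  expect_identical(call_fusion(2, valid_controls(), th), "not_detected")
  expect_identical(call_fusion(100, internal_controls(0, 0, 0, 0), th),
                   "invalid")
  expect_identical(call_fusion(c(0, 2, 3, 500), valid_controls(), th),
                   c("not_detected", "not_detected", "detected", "detected"))
})

test_that("CNA calls gate on ratio, p-value and MAPD validity", {
  th <- qc_thresholds()
  expect_identical(call_cna(1.40, 1e-6, 0.2, th), "detected")
  expect_identical(call_cna(1.15, 1e-9, 0.2, th), "detected")  # inclusive
  expect_identical(call_cna(1.14, 1e-9, 0.2, th), "not_detected")
  expect_identical(call_cna(1.40, 1e-5, 0.2, th), "not_detected")  # strict p
  expect_identical(call_cna(5.0, 1e-9, 0.45, th), "invalid")
  expect_identical(call_cna(5.0, 1e-9, 0.4, th), "invalid")  # at limit
})

test_that("NTC acceptance is (reads OR read length) AND variant-free", {
  th <- qc_thresholds()
  m <- function(reads, len) sample_metrics(reads, 50, 10, 20, len, 70, 1.0)
  expect_true(evaluate_ntc(m(5e6, 60), 0, th))
  expect_true(evaluate_ntc(m(7e6, 30), 0, th))
  expect_false(evaluate_ntc(m(5e6, 30), 1, th))
  expect_false(evaluate_ntc(m(7e6, 60), 0, th))
  expect_true(evaluate_ntc(m(6e6, 45), 0, th))  # boundaries inclusive
})

test_that("positive control requires every expected target detected", {
  obs <- data.frame(
    target_id = c("EML4-ALK", "CCDC6-RET", "CD74-ROS1", "ERBB2", "MYC"),
    call = "detected", stringsAsFactors = FALSE)
  expected <- obs$target_id
  expect_true(evaluate_positive_control(expected, obs)$pass)

  obs2 <- obs
  obs2$call[2] <- "not_detected"
  res <- evaluate_positive_control(expected, obs2)
  expect_false(res$pass)
  expect_match(res$reasons, "CCDC6-RET", all = FALSE)

  res <- evaluate_positive_control(expected, obs[-3, ])
  expect_false(res$pass)
  expect_match(res$reasons, "CD74-ROS1.*absent", all = FALSE)
})

test_that("batch verdict conjoins positive-control and NTC acceptance", {
  p <- assay_profile(seed = 11L)
  batch <- make_batch(p, n_clinical = 2)
  v <- evaluate_batch(batch, reference_control_limits()$analyte_id)
  expect_true(v$positive_control_pass)
  expect_true(v$ntc_pass)
  expect_true(v$batch_pass)
  expect_identical(v$batch_pass, v$positive_control_pass && v$ntc_pass)

  # break the positive control: the verdict cites it
  broken <- batch
  pc_idx <- which(vapply(broken, function(s) s$role, character(1)) ==
                    "positive_control")
  broken[[pc_idx]]$fusion_rows$molecular_copies[1] <- 0
  v2 <- evaluate_batch(broken, reference_control_limits()$analyte_id)
  expect_false(v2$batch_pass)
  expect_match(v2$reasons, "positive control", all = FALSE)

  # duplicated or missing control roles are configuration errors
  expect_error(evaluate_batch(c(batch, batch[2]), "EML4-ALK"),
               "exactly one ntc")
  expect_error(evaluate_batch(batch[-pc_idx], "EML4-ALK"),
               "exactly one positive_control")
})

test_that("every observation gets exactly one of the three call states", {
  th <- qc_thresholds()
  set.seed(401)
  states <- c("detected", "not_detected", "invalid")
  for (i in 1:200) {
    ctrl <- internal_controls(sample(0:5, 1), sample(0:5, 1),
                              sample(0:5, 1), sample(0:5, 1))
    cf <- call_fusion(sample(0:10, 1), ctrl, th)
    expect_length(cf, 1)
    expect_true(cf %in% states)
    cc <- call_cna(runif(1, 0.5, 6), runif(1, 1e-12, 1),
                   runif(1, 0, 0.8), th)
    expect_true(cc %in% states)
  }
})

test_that("raising a threshold never turns a call into detected", {
  set.seed(402)
  base <- qc_thresholds()
  rank_call <- function(x) match(x, c("invalid", "not_detected", "detected"))
  for (i in 1:100) {
    copies <- sample(0:10, 1)
    ctrl <- internal_controls(sample(0:6, 1), sample(0:6, 1),
                              sample(0:6, 1), sample(0:6, 1))
    stricter <- qc_thresholds(fusion_min_copies = base$fusion_min_copies + 1,
                              internal_control_min_copies =
                                base$internal_control_min_copies + 1)
    expect_lte(rank_call(call_fusion(copies, ctrl, stricter)),
               max(rank_call(call_fusion(copies, ctrl, base)), 2))
    if (call_fusion(copies, ctrl, base) != "detected") {
      expect_true(call_fusion(copies, ctrl, stricter) != "detected")
    }
    fold <- runif(1, 0.9, 2)
    pv <- runif(1, 1e-9, 1e-3)
    stricter2 <- qc_thresholds(cna_min_ratio = base$cna_min_ratio + 0.2)
    if (call_cna(fold, pv, 0.2, base) != "detected") {
      expect_true(call_cna(fold, pv, 0.2, stricter2) != "detected")
    }
  }
})
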