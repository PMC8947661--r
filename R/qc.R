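#' QC threshold configuration
#'
#' One object holds every decision threshold used by the rule engine:
#' sample-level sequencing gates, the copy-number (CNA) call gate, the
#' fusion/skipping call gate, the internal-control validity gate and the
#' no-template-control (NTC) acceptance gate. Defaults are the assay's
#' validated values; every one can be overridden here or via a YAML file
#' (see [read_thresholds()]). No threshold is hard-coded at a call site.
#'
#' Boundary semantics: the six sample sequencing gates are inclusive
#' (`>=` the minimum), MAPD is strict (`< max_mapd`), the CNA p-value is
#' strict (`< cna_max_p`), and the CNA ratio gate is inclusive
#' (`>= cna_min_ratio`, following the reported call tables; see the
#' methods vignette for the discrepancy in the prose threshold).
#'
#' @param min_mapped_reads minimum total mapped reads per sample.
#' @param min_coverage_uniformity minimum coverage uniformity, percent.
#' @param min_median_mol_cov minimum median molecular (UMI family) coverage.
#' @param min_mol_uniformity minimum molecular-based uniformity, percent.
#' @param min_mean_read_length minimum mean read length, base pairs.
#' @param min_aq20 minimum percent of bases at AQ20 (error <= 1%).
#' @param max_mapd maximum median absolute pairwise difference (strict).
#' @param cna_min_ratio minimum CNA fold change for a detected call.
#' @param cna_max_p maximum CNA p-value for a detected call (strict).
#' @param fusion_min_copies minimum molecular copies for a fusion call.
#' @param internal_control_min_copies minimum molecular count for an
#'   internal process control to count as present.
#' @param ntc_max_reads NTC acceptance: maximum total mapped reads.
#' @param ntc_max_read_length NTC acceptance: maximum mean read length, bp.
#' @return an object of class `qc_thresholds` (a named list).
#' @export
#' @examples
#' th <- qc_thresholds()
#' th$cna_min_ratio
qc_thresholds <- function(min_mapped_reads = 1e7,
                          min_coverage_uniformity = 95,
                          min_median_mol_cov = 1500,
                          min_mol_uniformity = 80,
                          min_mean_read_length = 80,
                          min_aq20 = 80,
                          max_mapd = 0.4,
                          cna_min_ratio = 1.15,
                          cna_max_p = 1e-5,
                          fusion_min_copies = 3,
                          internal_control_min_copies = 3,
                          ntc_max_reads = 6e6,
                          ntc_max_read_length = 45) {
  th <- list(
    min_mapped_reads = min_mapped_reads,
    min_coverage_uniformity = min_coverage_uniformity,
    min_median_mol_cov = min_median_mol_cov,
    min_mol_uniformity = min_mol_uniformity,
    min_mean_read_length = min_mean_read_length,
    min_aq20 = min_aq20,
    max_mapd = max_mapd,
    cna_min_ratio = cna_min_ratio,
    cna_max_p = cna_max_p,
    fusion_min_copies = fusion_min_copies,
    internal_control_min_copies = internal_control_min_copies,
    ntc_max_reads = ntc_max_reads,
    ntc_max_read_length = ntc_max_read_length
  )
  bad <- names(th)[!vapply(th, function(v) is_scalar_num(v) && v > 0, logical(1))]
  if (length(bad)) {
    stop("qc_thresholds: all thresholds must be positive finite scalars; bad: ",
         paste(bad, collapse = ", "))
  }
  structure(th, class = "qc_thresholds")
}

#' Per-sample sequencing and molecular QC metrics
#'
#' @param total_mapped_reads total mapped reads (count).
#' @param coverage_uniformity coverage uniformity, percent in \[0, 100\].
#' @param median_molecular_coverage median UMI molecular-family coverage.
#' @param molecular_uniformity molecular-based uniformity, percent.
#' @param mean_read_length mean read length, base pairs.
#' @param aq20_fraction percent of bases at AQ20.
#' @param mapd median absolute pairwise difference (copy-number noise), >= 0.
#' @return an object of class `sample_qc_metrics`.
#' @export
sample_metrics <- function(total_mapped_reads,
                           coverage_uniformity,
                           median_molecular_coverage,
                           molecular_uniformity,
                           mean_read_length,
                           aq20_fraction,
                           mapd) {
  m <- list(
    total_mapped_reads = total_mapped_reads,
    coverage_uniformity = coverage_uniformity,
    median_molecular_coverage = median_molecular_coverage,
    molecular_uniformity = molecular_uniformity,
    mean_read_length = mean_read_length,
    aq20_fraction = aq20_fraction,
    mapd = mapd
  )
  missing <- names(m)[!vapply(m, is_scalar_num, logical(1))]
  if (length(missing)) {
    stop("sample_metrics: missing or non-finite metric(s): ",
         paste(missing, collapse = ", "))
  }
  for (p in c("coverage_uniformity", "molecular_uniformity", "aq20_fraction")) {
    if (m[[p]] < 0 || m[[p]] > 100) stop("sample_metrics: ", p, " must be in [0, 100]")
  }
  if (m$mapd < 0) stop("sample_metrics: mapd must be >= 0")
  if (m$total_mapped_reads < 0) stop("sample_metrics: total_mapped_reads must be >= 0")
  structure(m, class = "sample_qc_metrics")
}

#' Internal process-control panel
#'
#' Molecular counts of the two expression controls (TBP, HMBS) and the two
#' MET wild-type exon-junction controls (E6-E7, E11-E12) that certify RNA
#' integrity for fusion/skipping calling and normalize fusion reads.
#'
#' @param tbp,hmbs,met_e6_e7,met_e11_e12 nonnegative molecular counts.
#' @return an object of class `internal_control_panel`.
#' @export
internal_controls <- function(tbp, hmbs, met_e6_e7, met_e11_e12) {
  p <- list(tbp = tbp, hmbs = hmbs, met_e6_e7 = met_e6_e7,
            met_e11_e12 = met_e11_e12)
  bad <- names(p)[!vapply(p, function(v) is_scalar_num(v) && v >= 0, logical(1))]
  if (length(bad)) {
    stop("internal_controls: counts must be nonnegative finite scalars; bad: ",
         paste(bad, collapse = ", "))
  }
  structure(p, class = "internal_control_panel")
}

# gate table for one sample: each row records the decision and the
# threshold it used, so logs can show both verbatim.
sample_gate_table <- function(metrics, thresholds) {
  stopifnot(inherits(metrics, "sample_qc_metrics"),
            inherits(thresholds, "qc_thresholds"))
  ge <- function(gate, value, thr) {
    data.frame(gate = gate, value = value, threshold = thr,
               comparator = ">=", pass = value >= thr,
               stringsAsFactors = FALSE)
  }
  rbind(
    ge("mapped_reads", metrics$total_mapped_reads, thresholds$min_mapped_reads),
    ge("coverage_uniformity", metrics$coverage_uniformity, thresholds$min_coverage_uniformity),
    ge("median_molecular_coverage", metrics$median_molecular_coverage, thresholds$min_median_mol_cov),
    ge("molecular_uniformity", metrics$molecular_uniformity, thresholds$min_mol_uniformity),
    ge("mean_read_length", metrics$mean_read_length, thresholds$min_mean_read_length),
    ge("aq20_fraction", metrics$aq20_fraction, thresholds$min_aq20),
    data.frame(gate = "mapd", value = metrics$mapd, threshold = thresholds$max_mapd,
               comparator = "<", pass = metrics$mapd < thresholds$max_mapd,
               stringsAsFactors = FALSE)
  )
}

#' Evaluate sample-level QC gates
#'
#' Applies the seven sample-level gates: total mapped reads, coverage
#' uniformity, median molecular coverage, molecular uniformity, mean read
#' length, AQ20 fraction (all inclusive minima) and MAPD (strict maximum).
#' A sample failing any gate is excluded from downstream analyses.
#'
#' @param metrics a [sample_metrics()] object (a missing or non-finite
#'   metric is a validation error, never a silent pass).
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `pass` (logical), `failed_gates` (character) and
#'   `gates` (data frame of every decision with its threshold).
#' @export
#' @examples
#' m <- sample_metrics(1e7, 95, 1500, 80, 80, 80, 0.2)
#' evaluate_sample_qc(m)$pass  # boundary values pass: gates are inclusive
evaluate_sample_qc <- function(metrics, thresholds = qc_thresholds()) {
  gates <- sample_gate_table(metrics, thresholds)
  list(pass = all(gates$pass),
       failed_gates = gates$gate[!gates$pass],
       gates = gates)
}

#' Fusion/skipping sample validity from internal controls
#'
#' A sample is valid for fusion/skipping calling when at least one
#' expression control (TBP or HMBS) *and* at least one MET wild-type exon
#' junction (E6-E7 or E11-E12) reach the minimum molecular count.
#'
#' @param controls an [internal_controls()] panel.
#' @param thresholds a [qc_thresholds()] object.
#' @return logical scalar.
#' @export
fusion_sample_valid <- function(controls, thresholds = qc_thresholds()) {
  stopifnot(inherits(controls, "internal_control_panel"))
  k <- thresholds$internal_control_min_copies
  max(controls$tbp, controls$hmbs) >= k &&
    max(controls$met_e6_e7, controls$met_e11_e12) >= k
}

#' Call a fusion/skipping observation
#'
#' `invalid` when the internal-control validity gate fails (irrespective of
#' the measured copies); otherwise `detected` iff the molecular copy count
#' reaches the fusion gate (default 3 copies).
#'
#' @param copies nonnegative molecular copy count(s); vectorized.
#' @param controls the sample's [internal_controls()] panel.
#' @param thresholds a [qc_thresholds()] object.
#' @return character vector in `{"detected", "not_detected", "invalid"}`.
#' @export
call_fusion <- function(copies, controls, thresholds = qc_thresholds()) {
  stopifnot(is.numeric(copies), all(is.finite(copies)), all(copies >= 0))
  if (!fusion_sample_valid(controls, thresholds)) {
    return(rep("invalid", length(copies)))
  }
  ifelse(copies >= thresholds$fusion_min_copies, "detected", "not_detected")
}

#' Call a copy-number amplification observation
#'
#' `invalid` when the sample's MAPD gate fails (MAPD >= the maximum);
#' otherwise `detected` iff the fold change reaches the ratio gate *and*
#' the p-value is below the significance gate.
#'
#' @param fold_change positive fold change(s); vectorized.
#' @param p_value p-value(s) in (0, 1\]; recycled against `fold_change`.
#' @param mapd the sample's MAPD (scalar or vector).
#' @param thresholds a [qc_thresholds()] object.
#' @return character vector in `{"detected", "not_detected", "invalid"}`.
#' @export
#' @examples
#' call_cna(1.40, 1e-6, 0.2)  # "detected"
call_cna <- function(fold_change, p_value, mapd, thresholds = qc_thresholds()) {
  stopifnot(is.numeric(fold_change), all(fold_change > 0, na.rm = TRUE),
            is.numeric(p_value), all(p_value > 0 & p_value <= 1, na.rm = TRUE),
            is.numeric(mapd), all(mapd >= 0))
  n <- max(length(fold_change), length(p_value), length(mapd))
  fold_change <- rep_len(fold_change, n)
  p_value <- rep_len(p_value, n)
  mapd <- rep_len(mapd, n)
  ifelse(mapd >= thresholds$max_mapd, "invalid",
         ifelse(fold_change >= thresholds$cna_min_ratio &
                  p_value < thresholds$cna_max_p,
                "detected", "not_detected"))
}

#' Evaluate a no-template control
#'
#' The NTC passes when it looks empty — total mapped reads at or below the
#' NTC read ceiling *or* mean read length at or below the NTC length
#' ceiling — and carries zero detected variants. The metric disjunction and
#' the conjunction with variant-freedom follow the batch acceptance rule.
#'
#' @param metrics the NTC's [sample_metrics()].
#' @param detected_variant_count number of detected variant calls in the NTC.
#' @param thresholds a [qc_thresholds()] object.
#' @return logical scalar.
#' @export
evaluate_ntc <- function(metrics, detected_variant_count,
                         thresholds = qc_thresholds()) {
  stopifnot(inherits(metrics, "sample_qc_metrics"),
            is_count(detected_variant_count))
  looks_empty <- metrics$total_mapped_reads <= thresholds$ntc_max_reads ||
    metrics$mean_read_length <= thresholds$ntc_max_read_length
  looks_empty && detected_variant_count == 0
}

#' Evaluate the batch positive control
#'
#' The positive control passes only when *every* expected variant target is
#' called `detected`. An expected target absent from the observed table is
#' a failure with a reason, not an error.
#'
#' @param expected_variants nonempty character vector of expected target ids.
#' @param observed_calls data frame with columns `target_id` and `call`.
#' @return list with `pass` (logical) and `reasons` (character).
#' @export
evaluate_positive_control <- function(expected_variants, observed_calls) {
  stopifnot(is.character(expected_variants), length(expected_variants) > 0,
            is.data.frame(observed_calls),
            all(c("target_id", "call") %in% names(observed_calls)))
  reasons <- character(0)
  for (tid in expected_variants) {
    hit <- observed_calls$call[observed_calls$target_id == tid]
    if (length(hit) == 0L) {
      reasons <- c(reasons, sprintf(
        "positive control: expected target %s absent from call table", tid))
    } else if (!any(hit == "detected")) {
      reasons <- c(reasons, sprintf(
        "positive control: expected target %s not detected (call: %s)",
        tid, paste(unique(hit), collapse = "/")))
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Fill call status on a simulated or parsed sample
#'
#' Applies [call_fusion()] to the sample's fusion rows (using its internal
#' controls) and [call_cna()] to its CNA rows (using its MAPD).
#'
#' @param sample a `simulated_sample` (see [make_negative_cohort()]) or any
#'   list with `metrics`, `controls`, `fusion_rows`, `cna_rows`.
#' @param thresholds a [qc_thresholds()] object.
#' @return the sample with `call` columns filled.
#' @export
call_sample_observations <- function(sample, thresholds = qc_thresholds()) {
  if (!is.null(sample$fusion_rows) && nrow(sample$fusion_rows)) {
    sample$fusion_rows$call <- call_fusion(
      sample$fusion_rows$molecular_copies, sample$controls, thresholds)
  }
  if (!is.null(sample$cna_rows) && nrow(sample$cna_rows)) {
    sample$cna_rows$call <- call_cna(
      sample$cna_rows$fold_change, sample$cna_rows$p_value,
      sample$metrics$mapd, thresholds)
  }
  sample
}

# count detected calls across both variant classes of one sample
sample_detected_count <- function(sample) {
  n <- 0L
  if (!is.null(sample$fusion_rows) && nrow(sample$fusion_rows)) {
    n <- n + sum(sample$fusion_rows$call == "detected", na.rm = TRUE)
  }
  if (!is.null(sample$cna_rows) && nrow(sample$cna_rows)) {
    n <- n + sum(sample$cna_rows$call == "detected", na.rm = TRUE)
  }
  n
}

#' Evaluate a batch of samples against its controls
#'
#' A batch must contain exactly one positive control and exactly one NTC
#' (a missing or duplicated control role is a configuration error). The
#' batch passes only when the positive control shows every expected variant
#' as detected and the NTC is acceptably empty.
#'
#' @param samples list of samples (as produced by the simulator or parsed
#'   from disk), each with `sample_id`, `role`, `metrics`, `controls`,
#'   `fusion_rows`, `cna_rows`. Roles: `clinical`, `positive_control`,
#'   `ntc`, `nhd`.
#' @param expected_pc_variants character vector of target ids the positive
#'   control must show as detected.
#' @param thresholds a [qc_thresholds()] object.
#' @return an object of class `batch_verdict`: list with
#'   `positive_control_pass`, `ntc_pass`, `batch_pass`
#'   (`= positive_control_pass && ntc_pass`), `reasons`, and `sample_qc`
#'   (per-sample gate results).
#' @export
evaluate_batch <- function(samples, expected_pc_variants,
                           thresholds = qc_thresholds()) {
  stopifnot(is.list(samples), length(samples) > 0)
  roles <- vapply(samples, function(s) s$role, character(1))
  if (sum(roles == "positive_control") != 1L) {
    stop("evaluate_batch: configuration error: batch must contain exactly one positive_control (found ",
         sum(roles == "positive_control"), ")")
  }
  if (sum(roles == "ntc") != 1L) {
    stop("evaluate_batch: configuration error: batch must contain exactly one ntc (found ",
         sum(roles == "ntc"), ")")
  }
  samples <- lapply(samples, call_sample_observations, thresholds = thresholds)
  names(samples) <- vapply(samples, function(s) s$sample_id, character(1))

  reasons <- character(0)

  pc <- samples[[which(roles == "positive_control")]]
  pc_obs <- rbind(
    data.frame(target_id = pc$fusion_rows$target_id, call = pc$fusion_rows$call,
               stringsAsFactors = FALSE),
    data.frame(target_id = pc$cna_rows$target_id, call = pc$cna_rows$call,
               stringsAsFactors = FALSE)
  )
  pc_res <- evaluate_positive_control(expected_pc_variants, pc_obs)
  reasons <- c(reasons, pc_res$reasons)

  ntc <- samples[[which(roles == "ntc")]]
  ntc_pass <- evaluate_ntc(ntc$metrics, sample_detected_count(ntc), thresholds)
  if (!ntc_pass) {
    reasons <- c(reasons, sprintf(
      "ntc: failed acceptance (reads %s vs <= %s, read length %s vs <= %s, detected variants %d)",
      format(ntc$metrics$total_mapped_reads), format(thresholds$ntc_max_reads),
      format(ntc$metrics$mean_read_length), format(thresholds$ntc_max_read_length),
      sample_detected_count(ntc)))
  }

  sample_qc <- lapply(samples, function(s) evaluate_sample_qc(s$metrics, thresholds))

  structure(list(
    positive_control_pass = pc_res$pass,
    ntc_pass = ntc_pass,
    batch_pass = pc_res$pass && ntc_pass,
    reasons = reasons,
    sample_qc = sample_qc,
    samples = samples
  ), class = "batch_verdict")
}

#' @export
print.batch_verdict <- function(x, ...) {
  cat("Batch verdict:", if (x$batch_pass) "PASS" else "FAIL", "\n")
  cat("  positive control:", if (x$positive_control_pass) "pass" else "fail", "\n")
  cat("  NTC:             ", if (x$ntc_pass) "pass" else "fail", "\n")
  if (length(x$reasons)) cat(paste0("  - ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}
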