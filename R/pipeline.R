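# Stage orchestration. The pipeline's on-disk convention inside `out_dir`:
#   sim/ batch_metrics.tsv, batch_calls.tsv, manifest.yaml,
#        cohort_calls.tsv, cohort_metrics.tsv,
#        fusion_series.tsv, cna_series.tsv, precision_study.tsv,
#        control_baseline.tsv
#   reports/ batch_verdict.json, sample_qc.json, sensitivity.json,
#        specificity.json + specificity_<kind>.tsv, precision.json,
#        control_limits.json, pipeline.log

log_line <- function(log_path, fmt, ...) {
  line <- sprintf(fmt, ...)
  if (!is.null(log_path)) cat(line, "\n", sep = "", file = log_path,
                              append = TRUE)
  invisible(line)
}

# every gate decision is logged with the exact threshold it used
log_gate_table <- function(log_path, sample_id, gates) {
  for (i in seq_len(nrow(gates))) {
    log_line(log_path,
             "sample=%s gate=%s value=%s comparator=%s threshold=%s pass=%s",
             sample_id, gates$gate[i],
             format(gates$value[i], scientific = FALSE, trim = TRUE),
             gates$comparator[i],
             format(gates$threshold[i], scientific = FALSE, trim = TRUE),
             gates$pass[i])
  }
}

series_to_table <- function(series) {
  cbind(series$rows,
        data.frame(variant_kind = series$variant_kind,
                   target_id = series$target_id, stringsAsFactors = FALSE))
}

series_from_table <- function(df) {
  dilution_series(df$variant_kind[1], df$target_id[1],
                  df[, c("dilution", "replicate", "measurement", "p_value",
                         "call")])
}

write_series_table <- function(series, path) {
  df <- series_to_table(series)
  df$dilution <- as.character(df$dilution)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num_col)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_series_table <- function(path) {
  df <- read_tsv_checked(path, c("dilution", "replicate", "measurement",
                                 "p_value", "call", "variant_kind",
                                 "target_id"))
  df$measurement <- numeric_column(df, "measurement", path, allow_na = TRUE)
  df$p_value <- numeric_column(df, "p_value", path, allow_na = TRUE)
  series_from_table(df)
}

stage_simulate <- function(profile, thresholds, out_dir, log_path) {
  sim_dir <- file.path(out_dir, "sim")
  dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)

  batch <- make_batch(profile, n_clinical = 4, seed = profile$seed,
                      thresholds = thresholds)
  write_sample_metrics_table(batch_metrics_table(batch),
                             file.path(sim_dir, "batch_metrics.tsv"))
  write_call_table(cohort_call_table(batch),
                   file.path(sim_dir, "batch_calls.tsv"))
  ref <- reference_control_limits()
  yaml::write_yaml(list(
    batch_id = "SIMBATCH1",
    samples = lapply(batch, function(s) list(sample_id = s$sample_id,
                                             role = s$role)),
    metrics = "batch_metrics.tsv",
    calls = "batch_calls.tsv",
    expected_variants = as.list(ref$analyte_id)
  ), file.path(sim_dir, "manifest.yaml"))

  cohort <- make_negative_cohort(12, 95, 12, profile,
                                 derive_seed(profile$seed, 11), thresholds)
  write_call_table(cohort_call_table(cohort),
                   file.path(sim_dir, "cohort_calls.tsv"))
  write_sample_metrics_table(batch_metrics_table(cohort),
                             file.path(sim_dir, "cohort_metrics.tsv"))

  reps <- rep(3L, length(profile$dilution_factors))
  reps[1] <- 2L
  write_series_table(make_dilution_series(profile, "fusion", reps,
                                          derive_seed(profile$seed, 12),
                                          thresholds),
                     file.path(sim_dir, "fusion_series.tsv"))
  write_series_table(make_dilution_series(profile, "cna", reps,
                                          derive_seed(profile$seed, 13),
                                          thresholds),
                     file.path(sim_dir, "cna_series.tsv"))

  study <- make_precision_study(profile, precision_design(),
                                derive_seed(profile$seed, 14))
  sdf <- as.data.frame(study)
  num <- vapply(sdf, is.numeric, logical(1))
  sdf[num] <- lapply(sdf[num], fmt_num_col)
  utils::write.table(sdf, file.path(sim_dir, "precision_study.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")

  # 7-run positive-control baseline for the chart stage
  base <- do.call(rbind, lapply(1:7, function(r) {
    pc <- make_positive_control(profile, derive_seed(profile$seed, 20 + r),
                                thresholds)
    rbind(data.frame(analyte_id = pc$fusion_rows$target_id,
                     kind = "fusion_reads", run = r,
                     value = pc$fusion_rows$molecular_copies,
                     stringsAsFactors = FALSE),
          data.frame(analyte_id = pc$cna_rows$target_id,
                     kind = "cna_fold_change", run = r,
                     value = pc$cna_rows$fold_change,
                     stringsAsFactors = FALSE))
  }))
  base$value <- fmt_num_col(base$value)
  utils::write.table(base, file.path(sim_dir, "control_baseline.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  log_line(log_path, "stage=simulate out=%s seed=%d", sim_dir, profile$seed)
  0L
}

stage_qc <- function(manifest, thresholds, out_dir, log_path) {
  rep_dir <- file.path(out_dir, "reports")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  metrics_df <- read_sample_metrics_table(manifest$metrics)
  calls_df <- read_call_table(manifest$calls)
  samples <- samples_from_tables(metrics_df, calls_df)
  expected <- manifest$expected_variants %||%
    reference_control_limits()$analyte_id
  verdict <- evaluate_batch(samples, expected, thresholds)
  for (s in names(verdict$sample_qc)) {
    log_gate_table(log_path, s, verdict$sample_qc[[s]]$gates)
  }
  log_line(log_path, "stage=qc batch=%s batch_pass=%s", manifest$batch_id,
           verdict$batch_pass)
  write_json_report(list(
    batch_id = manifest$batch_id,
    positive_control_pass = verdict$positive_control_pass,
    ntc_pass = verdict$ntc_pass,
    batch_pass = verdict$batch_pass,
    reasons = verdict$reasons
  ), file.path(rep_dir, "batch_verdict.json"))
  write_json_report(
    lapply(verdict$sample_qc, function(q) list(pass = q$pass,
                                               failed_gates = q$failed_gates,
                                               gates = q$gates)),
    file.path(rep_dir, "sample_qc.json"))
  if (verdict$batch_pass) 0L else 2L
}

stage_sensitivity <- function(out_dir, log_path) {
  rep_dir <- file.path(out_dir, "reports")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (kind in c("fusion", "cna")) {
    path <- file.path(out_dir, "sim", paste0(kind, "_series.tsv"))
    series <- read_series_table(path)
    lod <- determine_lod(series)
    dec <- if (kind == "fusion") 0 else 2
    summaries <- lapply(split(series$rows, series$rows$dilution), function(r) {
      vals <- r$measurement[r$call == "detected"]
      if (!length(vals)) return(NULL)
      s <- replicate_summary(vals, mean_decimals = dec)
      list(n = s$n, mean = s$mean, cv_percent = s$cv_percent,
           display_mean = s$display_mean, display_cv = s$display_cv)
    })
    out[[kind]] <- list(target_id = series$target_id,
                        lod_dilution = lod$lod_dilution,
                        lod_value = lod$lod_value,
                        detection_rate = lod$detection_rate_by_dilution,
                        replicate_summaries =
                          summaries[!vapply(summaries, is.null, logical(1))])
    log_line(log_path, "stage=sensitivity kind=%s lod=%s value=%s", kind,
             lod$lod_dilution, format(lod$lod_value))
  }
  write_json_report(out, file.path(rep_dir, "sensitivity.json"))
  0L
}

stage_specificity <- function(out_dir, log_path) {
  rep_dir <- file.path(out_dir, "reports")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  calls <- read_call_table(file.path(out_dir, "sim", "cohort_calls.tsv"))
  n_fus <- length(unique(calls$target_id[calls$variant_kind == "fusion"]))
  n_cna <- length(unique(calls$target_id[calls$variant_kind == "cna"]))
  spec <- specificity(calls, n_fus, n_cna)
  for (kind in names(spec)) {
    utils::write.table(spec[[kind]]$per_sample,
                       file.path(rep_dir, paste0("specificity_", kind,
                                                 ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line(log_path,
             "stage=specificity kind=%s assayed=%d detected=%d percent=%s",
             kind, spec[[kind]]$overall_assayed,
             spec[[kind]]$overall_detected,
             format(spec[[kind]]$overall_specificity_percent))
  }
  write_json_report(lapply(spec, function(x) list(
    per_sample = x$per_sample, overall_assayed = x$overall_assayed,
    overall_detected = x$overall_detected,
    overall_specificity_percent = x$overall_specificity_percent
  )), file.path(rep_dir, "specificity.json"))
  0L
}

stage_precision <- function(out_dir, thresholds, log_path) {
  rep_dir <- file.path(out_dir, "reports")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "sim", "precision_study.tsv")
  df <- read_tsv_checked(path, c("variant_kind", "specimen_id", "target_id",
                                 "run", "day", "operator", "instrument",
                                 "replicate", "measurement", "p_value",
                                 "qc_pass"))
  for (col in c("run", "day", "operator", "instrument", "replicate",
                "measurement", "p_value")) {
    df[[col]] <- numeric_column(df, col, path, allow_na = TRUE)
  }
  df$qc_pass <- df$qc_pass == "TRUE"
  res <- precision_analysis(df, thresholds,
                            extra_groupings = c("day", "operator",
                                                "instrument"))
  for (kind in names(res)) {
    log_line(log_path, "stage=precision kind=%s hit=%d/%d percent=%s", kind,
             res[[kind]]$hit$detected, res[[kind]]$hit$expected,
             format(res[[kind]]$hit$percent))
  }
  write_json_report(res, file.path(rep_dir, "precision.json"))
  0L
}

stage_chart <- function(out_dir, log_path, render_png = FALSE) {
  rep_dir <- file.path(out_dir, "reports")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "sim", "control_baseline.tsv")
  df <- read_tsv_checked(path, c("analyte_id", "kind", "run", "value"))
  df$value <- numeric_column(df, "value", path)
  out <- lapply(split(df, df$analyte_id), function(a) {
    s <- control_series(a$analyte_id[1], a$kind[1],
                        a$value[order(as.numeric(a$run))])
    lim <- derive_limits(s)
    if (render_png) {
      plot_control_chart(s, lim, file = file.path(
        rep_dir, paste0("chart_", gsub("[^A-Za-z0-9]", "_",
                                       a$analyte_id[1]), ".png")))
    }
    log_line(log_path, "stage=chart analyte=%s lower=%s upper=%s",
             a$analyte_id[1], format(lim$lower), format(lim$upper))
    list(analyte_id = lim$analyte_id, mean = lim$mean, sd = lim$sd,
         lower = lim$lower, upper = lim$upper)
  })
  write_json_report(out, file.path(rep_dir, "control_limits.json"))
  0L
}

#' Run the validation pipeline
#'
#' Ties the stages together over one output directory: `simulate` writes
#' synthetic batch, cohort, dilution-series, precision-study and
#' control-baseline tables under `out_dir/sim`; `qc` evaluates a batch
#' manifest; `sensitivity`, `specificity`, `precision` and `chart`
#' compute their reports from the tables under `out_dir/sim`; `all` runs
#' everything in order on freshly simulated data. Every gate decision is
#' logged with the threshold it used (`out_dir/reports/pipeline.log`).
#'
#' @param command one of `simulate`, `qc`, `sensitivity`, `specificity`,
#'   `precision`, `chart`, `all`.
#' @param out_dir working directory for tables and reports.
#' @param manifest a [read_run_manifest()] object or YAML path (required
#'   for `qc`; `all` uses the simulated batch's manifest).
#' @param profile an [assay_profile()] or YAML path.
#' @param thresholds a [qc_thresholds()] object or YAML path.
#' @param seed optional integer overriding the profile seed.
#' @param render_png render control-chart PNGs in the chart stage.
#' @return invisible integer status: 0 pass, 2 batch QC fail, 3 input or
#'   stage error (with a message).
#' @export
run_pipeline <- function(command = c("all", "simulate", "qc", "sensitivity",
                                     "specificity", "precision", "chart"),
                         out_dir, manifest = NULL,
                         profile = assay_profile(),
                         thresholds = qc_thresholds(),
                         seed = NULL, render_png = FALSE) {
  command <- match.arg(command)
  status <- tryCatch({
    if (is.character(profile)) profile <- read_assay_profile(profile)
    if (is.character(thresholds)) thresholds <- read_thresholds(thresholds)
    if (is.character(manifest)) manifest <- read_run_manifest(manifest)
    if (!is.null(seed)) profile$seed <- as.integer(seed)
    dir.create(file.path(out_dir, "reports"), recursive = TRUE,
               showWarnings = FALSE)
    log_path <- file.path(out_dir, "reports", "pipeline.log")

    run_qc <- function() {
      mf <- manifest %||%
        read_run_manifest(file.path(out_dir, "sim", "manifest.yaml"))
      stage_qc(mf, thresholds, out_dir, log_path)
    }
    switch(command,
      simulate = stage_simulate(profile, thresholds, out_dir, log_path),
      qc = run_qc(),
      sensitivity = stage_sensitivity(out_dir, log_path),
      specificity = stage_specificity(out_dir, log_path),
      precision = stage_precision(out_dir, thresholds, log_path),
      chart = stage_chart(out_dir, log_path, render_png),
      all = {
        stage_simulate(profile, thresholds, out_dir, log_path)
        qc_status <- run_qc()
        stage_sensitivity(out_dir, log_path)
        stage_specificity(out_dir, log_path)
        stage_precision(out_dir, thresholds, log_path)
        stage_chart(out_dir, log_path, render_png)
        qc_status
      })
  }, error = function(e) {
    message("run_pipeline: ", conditionMessage(e))
    3L
  })
  invisible(as.integer(status))
}
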