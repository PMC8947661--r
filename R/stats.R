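#' Replicate summary: mean, SD and CV
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation (`100 * sd / mean`) of replicate measurements, plus display
#' strings rounded half-away-from-zero to the requested decimals (the
#' convention used on the assay's validation report tables). The CV is
#' computed from the unrounded mean and SD.
#'
#' @param values nonempty numeric vector; SD and CV require n >= 2.
#' @param mean_decimals decimals for the displayed mean.
#' @param cv_decimals decimals for the displayed CV.
#' @return an object of class `replicate_summary`: `n`, `mean`, `sd`,
#'   `cv_percent`, `display_mean`, `display_cv`.
#' @export
#' @examples
#' s <- replicate_summary(c(49, 46, 31))
#' s$display_mean  # "42"
#' s$display_cv    # "23.0"
replicate_summary <- function(values, mean_decimals = 0, cv_decimals = 1) {
  stopifnot(is.numeric(values), length(values) >= 1, all(is.finite(values)))
  n <- length(values)
  m <- mean(values)
  s <- if (n >= 2) stats::sd(values) else NA_real_
  if (m == 0 && any(values != 0)) {
    stop("replicate_summary: CV undefined, mean is zero with nonzero values")
  }
  cv <- if (is.na(s)) NA_real_
        else if (m == 0) 0
        else 100 * s / m
  structure(list(
    n = n, mean = m, sd = s, cv_percent = cv,
    display_mean = fmt_fixed(m, mean_decimals),
    display_cv = if (is.na(cv)) NA_character_ else fmt_fixed(cv, cv_decimals)
  ), class = "replicate_summary")
}

#' Detection rate per dilution
#'
#' Fraction of QC-valid replicates called `detected` at each dilution.
#' `invalid` calls are excluded from the denominator; a dilution with no
#' valid replicate is flagged and gets an undefined rate.
#'
#' @param series a [dilution_series()].
#' @return data frame with columns `dilution`, `detected`, `valid_total`,
#'   `fraction`, `flagged`.
#' @export
detection_rate_by_dilution <- function(series) {
  stopifnot(inherits(series, "dilution_series"), nrow(series$rows) > 0)
  labs <- levels(series$rows$dilution)
  out <- do.call(rbind, lapply(labs, function(d) {
    r <- series$rows[series$rows$dilution == d, ]
    valid <- sum(r$call != "invalid")
    det <- sum(r$call == "detected")
    data.frame(dilution = d, detected = det, valid_total = valid,
               fraction = if (valid > 0) det / valid else NA_real_,
               flagged = valid == 0 & nrow(r) > 0,
               stringsAsFactors = FALSE)
  }))
  out <- out[out$valid_total > 0 | out$flagged, , drop = FALSE]
  if (any(out$flagged)) {
    warning("detection_rate_by_dilution: dilution(s) with no valid replicate: ",
            paste(out$dilution[out$flagged], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Determine the limit of detection from a dilution series
#'
#' The LOD dilution is the lowest concentration still showing 100%
#' detection among QC-valid replicates, counting down from the most
#' concentrated point (a dip below 100% stops the search, matching the
#' "determined consistently at dilutions 1 through k" reading). The LOD
#' value is the mean measurement of the valid replicates at that dilution.
#'
#' @param series a [dilution_series()] with at least two dilutions.
#' @return an object of class `lod_result`: `lod_dilution` (label or
#'   `NA`), `lod_value`, `detection_rate_by_dilution`.
#' @export
determine_lod <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  if (length(unique(series$rows$dilution)) < 2L) {
    stop("determine_lod: need at least two dilutions")
  }
  rates <- detection_rate_by_dilution(series)
  full <- !is.na(rates$fraction) & rates$fraction == 1
  if (!length(full) || !full[1]) {
    warning("determine_lod: no leading dilution with 100% detection; LOD undefined")
    return(structure(list(lod_dilution = NA_character_,
                          lod_value = NA_real_,
                          detection_rate_by_dilution = rates),
                     class = "lod_result"))
  }
  k <- match(FALSE, full, nomatch = length(full) + 1L) - 1L
  lab <- rates$dilution[k]
  r <- series$rows[series$rows$dilution == lab & series$rows$call != "invalid", ]
  structure(list(lod_dilution = lab,
                 lod_value = mean(r$measurement),
                 detection_rate_by_dilution = rates),
            class = "lod_result")
}

#' Verify detection of expected variants at the LOD
#'
#' @param calls data frame with `target_id` and `call`.
#' @param expected nonempty character vector of expected target ids.
#' @return list with `fraction_detected` and `pass`
#'   (`pass` iff every expected target is detected).
#' @export
verify_at_lod <- function(calls, expected) {
  stopifnot(is.data.frame(calls), all(c("target_id", "call") %in% names(calls)),
            is.character(expected), length(expected) > 0)
  det <- vapply(expected, function(tid) {
    any(calls$call[calls$target_id == tid] == "detected")
  }, logical(1))
  list(fraction_detected = mean(det), pass = all(det))
}

#' Flatten a simulated cohort into one call table
#'
#' @param cohort list of `simulated_sample` objects.
#' @return data frame with columns `sample_id`, `target_id`,
#'   `variant_kind`, `measurement`, `p_value`, `call`, `tbp`, `hmbs`,
#'   `met_e6_e7`, `met_e11_e12`.
#' @export
cohort_call_table <- function(cohort) {
  stopifnot(is.list(cohort), length(cohort) > 0)
  do.call(rbind, lapply(cohort, function(s) {
    rbind(
      data.frame(sample_id = s$sample_id,
                 target_id = s$fusion_rows$target_id,
                 variant_kind = "fusion",
                 measurement = s$fusion_rows$molecular_copies,
                 p_value = NA_real_, call = s$fusion_rows$call,
                 tbp = s$controls$tbp, hmbs = s$controls$hmbs,
                 met_e6_e7 = s$controls$met_e6_e7,
                 met_e11_e12 = s$controls$met_e11_e12,
                 stringsAsFactors = FALSE),
      data.frame(sample_id = s$sample_id,
                 target_id = s$cna_rows$target_id,
                 variant_kind = "cna",
                 measurement = s$cna_rows$fold_change,
                 p_value = s$cna_rows$p_value, call = s$cna_rows$call,
                 tbp = s$controls$tbp, hmbs = s$controls$hmbs,
                 met_e6_e7 = s$controls$met_e6_e7,
                 met_e11_e12 = s$controls$met_e11_e12,
                 stringsAsFactors = FALSE)
    )
  }))
}

# one variant kind's specificity block
specificity_one_kind <- function(calls, kind, n_targets) {
  k <- calls[calls$variant_kind == kind, , drop = FALSE]
  ids <- unique(calls$sample_id)
  per <- do.call(rbind, lapply(ids, function(sid) {
    rows <- k[k$sample_id == sid, , drop = FALSE]
    if (nrow(rows) != n_targets) {
      stop(sprintf("specificity: sample %s has %d %s rows, expected %d",
                   sid, nrow(rows), kind, n_targets))
    }
    det <- sum(rows$call == "detected")
    data.frame(sample_id = sid, assayed = as.integer(n_targets),
               detected = as.integer(det),
               specificity_percent =
                 round_half_up(100 * (n_targets - det) / n_targets, 1),
               stringsAsFactors = FALSE)
  }))
  oa <- sum(per$assayed)
  od <- sum(per$detected)
  structure(list(per_sample = per, overall_assayed = oa,
                 overall_detected = od,
                 overall_specificity_percent =
                   round_half_up(100 * (oa - od) / oa, 1)),
            class = "specificity_result")
}

#' Analytic specificity of a negative cohort
#'
#' Per-sample and pooled specificity
#' (`100 * (assayed - detected) / assayed`) for each variant kind.
#' Every sample is expected to have passed sample-level and
#' internal-control QC; samples named in `qc_failed` are excluded with a
#' warning.
#'
#' @param samples a cohort call table (see [cohort_call_table()]) or a
#'   list of `simulated_sample` objects.
#' @param n_fusion_targets fusion/skipping targets assayed per sample.
#' @param n_cna_targets CNA targets assayed per sample.
#' @param qc_failed optional character vector of sample ids to exclude.
#' @return list with `fusion` and `cna`, each a `specificity_result`
#'   (`per_sample` data frame plus pooled counts and percent).
#' @export
specificity <- function(samples, n_fusion_targets, n_cna_targets,
                        qc_failed = NULL) {
  calls <- if (is.data.frame(samples)) samples else cohort_call_table(samples)
  stopifnot(all(c("sample_id", "variant_kind", "call") %in% names(calls)),
            is_count(n_fusion_targets), is_count(n_cna_targets))
  if (!is.null(qc_failed) && length(qc_failed)) {
    drop <- intersect(unique(calls$sample_id), qc_failed)
    if (length(drop)) {
      warning("specificity: excluding QC-failed sample(s): ",
              paste(drop, collapse = ", "))
      calls <- calls[!calls$sample_id %in% drop, , drop = FALSE]
    }
  }
  list(fusion = specificity_one_kind(calls, "fusion", n_fusion_targets),
       cna = specificity_one_kind(calls, "cna", n_cna_targets))
}

#' Hit rate percentage
#'
#' `100 * detected / expected`, rounded half-away-from-zero to one
#' decimal.
#'
#' @param detected detected count (0 <= detected <= expected).
#' @param expected expected count (>= 1).
#' @return numeric scalar percent.
#' @export
#' @examples
#' hit_rate(28, 29)  # 96.6
hit_rate <- function(detected, expected) {
  stopifnot(is_count(detected), is_count(expected), expected >= 1,
            detected <= expected)
  round_half_up(100 * detected / expected, 1)
}

# detection flag per precision-study row
precision_detected <- function(study, thresholds) {
  ifelse(study$variant_kind == "fusion",
         study$measurement >= thresholds$fusion_min_copies,
         study$measurement >= thresholds$cna_min_ratio &
           study$p_value < thresholds$cna_max_p)
}

# CV of per-group means for one event; groups with a single value are used
# as-is, the CV needs >= 2 groups
cv_over_groups <- function(df, group_var) {
  means <- tapply(df$measurement, df[[group_var]], mean)
  if (length(means) < 2L) return(NA_real_)
  100 * stats::sd(means) / mean(means)
}

precision_one_kind <- function(study, kind, thresholds, repeat_run) {
  k <- study[study$variant_kind == kind, , drop = FALSE]
  k$detected <- precision_detected(k, thresholds)
  usable <- k[k$qc_pass, , drop = FALSE]
  hit <- list(detected = sum(usable$detected),
              expected = nrow(usable),
              percent = hit_rate(sum(usable$detected), nrow(usable)))

  # CV cells use detected, QC-passing measurements only: a censored
  # event-run never contributes; a sub-threshold miss is dropped from
  # that run's CV but still counted against the hit rate.
  good <- usable[usable$detected, , drop = FALSE]
  events <- unique(good[, c("specimen_id", "target_id")])

  rep_cv <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    g <- good[good$specimen_id == events$specimen_id[i] &
                good$target_id == events$target_id[i] &
                good$run == repeat_run, , drop = FALSE]
    cv <- if (nrow(g) >= 2) 100 * stats::sd(g$measurement) / mean(g$measurement)
          else NA_real_
    if (is.na(cv) && nrow(g) > 0) {
      warning(sprintf("precision: <2 repeatability values for %s/%s, CV skipped",
                      events$specimen_id[i], events$target_id[i]))
    }
    data.frame(specimen_id = events$specimen_id[i],
               target_id = events$target_id[i], n = nrow(g),
               cv_percent = cv, stringsAsFactors = FALSE)
  }))

  int_cv <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    g <- good[good$specimen_id == events$specimen_id[i] &
                good$target_id == events$target_id[i], , drop = FALSE]
    data.frame(specimen_id = events$specimen_id[i],
               target_id = events$target_id[i],
               n_runs = length(unique(g$run)),
               cv_percent = cv_over_groups(g, "run"),
               stringsAsFactors = FALSE)
  }))

  summarize <- function(cvs) {
    v <- cvs$cv_percent[!is.na(cvs$cv_percent)]
    list(average = if (length(v)) mean(v) else NA_real_,
         range = if (length(v)) range(v) else c(NA_real_, NA_real_))
  }
  rs <- summarize(rep_cv)
  is <- summarize(int_cv)
  list(hit = hit, repeatability = rep_cv, intermediate = int_cv,
       average_repeatability_cv = rs$average,
       repeatability_range = rs$range,
       average_intermediate_cv = is$average,
       intermediate_range = is$range,
       events = events, data = k)
}

#' Repeatability and intermediate-precision analysis
#'
#' For each variant kind: the hit rate (detected / expected detection
#' opportunities, with QC-censored event-runs excluded from the expected
#' count and sub-threshold events counted as misses); the repeatability CV
#' per event (CV of the within-run replicate measurements of the
#' repeatability run); the intermediate-precision CV per event (CV of the
#' per-run mean measurements across runs); and averages and ranges across
#' events. Additional groupings (by day, operator or instrument) compute
#' the CV of per-level means.
#'
#' @param study a [make_precision_study()] table (or any data frame with
#'   its columns).
#' @param thresholds a [qc_thresholds()] object supplying the call gates.
#' @param repeat_run which run is the repeatability (triplicate) run.
#' @param extra_groupings character subset of
#'   `c("day", "operator", "instrument")` for additional CV breakdowns.
#' @return an object of class `precision_result`: list with `fusion` and
#'   `cna` components (each carrying `hit`, `repeatability`,
#'   `intermediate`, averages and ranges) and optional `by_<grouping>`
#'   tables.
#' @export
precision_analysis <- function(study, thresholds = qc_thresholds(),
                               repeat_run = 1L,
                               extra_groupings = character(0)) {
  req <- c("variant_kind", "specimen_id", "target_id", "run", "day",
           "operator", "instrument", "replicate", "measurement", "qc_pass")
  if (!all(req %in% names(study))) {
    stop("precision_analysis: study table missing column(s): ",
         paste(setdiff(req, names(study)), collapse = ", "))
  }
  stopifnot(all(extra_groupings %in% c("day", "operator", "instrument")))
  out <- list()
  for (kind in intersect(c("fusion", "cna"), unique(study$variant_kind))) {
    res <- precision_one_kind(study, kind, thresholds, repeat_run)
    for (g in extra_groupings) {
      good <- res$data[res$data$qc_pass & res$data$detected, , drop = FALSE]
      res[[paste0("by_", g)]] <- do.call(rbind, lapply(
        seq_len(nrow(res$events)), function(i) {
          gg <- good[good$specimen_id == res$events$specimen_id[i] &
                       good$target_id == res$events$target_id[i], ,
                     drop = FALSE]
          data.frame(specimen_id = res$events$specimen_id[i],
                     target_id = res$events$target_id[i],
                     cv_percent = cv_over_groups(gg, g),
                     stringsAsFactors = FALSE)
        }))
    }
    res$data <- NULL
    out[[kind]] <- res
  }
  structure(out, class = "precision_result")
}
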