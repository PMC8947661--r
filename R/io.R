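# Interchange formats: tab-separated UTF-8 tables with '.' decimals
# (mirroring vendor-export style), YAML configuration, JSON reports.

# full-precision text for a numeric column; NA stays a bare "NA"
fmt_num_col <- function(v) {
  out <- formatC(v, digits = 17, format = "g")
  out[is.na(v)] <- "NA"
  trimws(out)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("parse error in ", path, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

# convert a character column to numeric; a non-numeric, non-missing cell is
# a row-level error reported with its file line number (header = line 1)
numeric_column <- function(df, col, path, allow_na = FALSE) {
  x <- df[[col]]
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("parse error in %s: non-numeric '%s' value(s) at line(s) %s",
                 path, col, paste(bad + 1L, collapse = ", ")))
  }
  if (!allow_na && anyNA(out)) {
    stop(sprintf("parse error in %s: missing '%s' value(s) at line(s) %s",
                 path, col, paste(which(is.na(out)) + 1L, collapse = ", ")))
  }
  out
}

#' Write a variant-call table
#'
#' Tab-separated, UTF-8, one row per target per sample. Required columns:
#' `sample_id`, `target_id`, `variant_kind`, `measurement`, `p_value`;
#' the four internal-control count columns and any extra columns are
#' preserved. Reals are written with full precision (round trip to at
#' least 1e-12).
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(x, path) {
  req <- c("sample_id", "target_id", "variant_kind", "measurement", "p_value")
  missing <- setdiff(req, names(x))
  if (length(missing)) {
    stop("write_call_table: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], fmt_num_col)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a variant-call table
#'
#' Inverse of [write_call_table()]. Unknown columns are preserved as
#' character; `variant_kind` is validated; a missing required column or a
#' non-numeric measurement is a parse error naming the column (and line).
#'
#' @param path TSV path.
#' @return data frame of typed observations.
#' @export
read_call_table <- function(path) {
  req <- c("sample_id", "target_id", "variant_kind", "measurement", "p_value")
  df <- read_tsv_checked(path, req)
  bad_kind <- setdiff(unique(df$variant_kind), c("fusion", "cna"))
  if (length(bad_kind)) {
    stop("parse error in ", path, ": unknown variant_kind value(s): ",
         paste(bad_kind, collapse = ", "))
  }
  # measurement and p_value may be missing on not-detected export rows
  df$measurement <- numeric_column(df, "measurement", path, allow_na = TRUE)
  df$p_value <- numeric_column(df, "p_value", path, allow_na = TRUE)
  for (col in intersect(c("tbp", "hmbs", "met_e6_e7", "met_e11_e12"),
                        names(df))) {
    df[[col]] <- numeric_column(df, col, path, allow_na = TRUE)
  }
  df
}

metrics_columns <- function() {
  c("total_mapped_reads", "coverage_uniformity", "median_molecular_coverage",
    "molecular_uniformity", "mean_read_length", "aq20_fraction", "mapd")
}

#' Write a sample-metrics table
#'
#' Columns: `sample_id`, `role`, plus the seven sequencing/molecular QC
#' metrics.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metrics_table <- function(x, path) {
  req <- c("sample_id", "role", metrics_columns())
  missing <- setdiff(req, names(x))
  if (length(missing)) {
    stop("write_sample_metrics_table: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], fmt_num_col)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample-metrics table
#'
#' @param path TSV path.
#' @return data frame; metric columns numeric.
#' @export
read_sample_metrics_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "role", metrics_columns()))
  for (col in metrics_columns()) df[[col]] <- numeric_column(df, col, path)
  df
}

# flatten a cohort/batch into the two interchange tables
batch_metrics_table <- function(samples) {
  do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, role = s$role,
               total_mapped_reads = s$metrics$total_mapped_reads,
               coverage_uniformity = s$metrics$coverage_uniformity,
               median_molecular_coverage = s$metrics$median_molecular_coverage,
               molecular_uniformity = s$metrics$molecular_uniformity,
               mean_read_length = s$metrics$mean_read_length,
               aq20_fraction = s$metrics$aq20_fraction,
               mapd = s$metrics$mapd, stringsAsFactors = FALSE)
  }))
}

# rebuild sample objects from the two interchange tables
samples_from_tables <- function(metrics_df, calls_df) {
  lapply(seq_len(nrow(metrics_df)), function(i) {
    sid <- metrics_df$sample_id[i]
    m <- metrics_df[i, ]
    calls <- calls_df[calls_df$sample_id == sid, , drop = FALSE]
    fus <- calls[calls$variant_kind == "fusion", , drop = FALSE]
    cna <- calls[calls$variant_kind == "cna", , drop = FALSE]
    ctrl <- if (nrow(calls) &&
                all(c("tbp", "hmbs", "met_e6_e7", "met_e11_e12") %in%
                      names(calls))) {
      internal_controls(calls$tbp[1], calls$hmbs[1], calls$met_e6_e7[1],
                        calls$met_e11_e12[1])
    } else internal_controls(0, 0, 0, 0)
    new_simulated_sample(
      sample_id = sid, role = m$role,
      metrics = sample_metrics(m$total_mapped_reads, m$coverage_uniformity,
                               m$median_molecular_coverage,
                               m$molecular_uniformity, m$mean_read_length,
                               m$aq20_fraction, m$mapd),
      controls = ctrl,
      fusion_rows = data.frame(target_id = fus$target_id,
                               molecular_copies = fus$measurement,
                               call = NA_character_, stringsAsFactors = FALSE),
      cna_rows = data.frame(target_id = cna$target_id,
                            fold_change = cna$measurement,
                            p_value = cna$p_value, call = NA_character_,
                            stringsAsFactors = FALSE)
    )
  })
}

#' Write / read QC thresholds as versioned YAML
#'
#' @param thresholds a [qc_thresholds()] object.
#' @param path YAML path.
#' @return `write_thresholds()`: `path` invisibly; `read_thresholds()`:
#'   a `qc_thresholds` object (file values override defaults).
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  yaml::write_yaml(list(schema_version = 1,
                        thresholds = unclass(thresholds)), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  th <- cfg$thresholds %||% cfg
  th$schema_version <- NULL
  unknown <- setdiff(names(th), names(formals(qc_thresholds)))
  if (length(unknown)) {
    stop("read_thresholds: unknown threshold key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  do.call(qc_thresholds, th)
}

#' Write / read an assay simulation profile as YAML
#'
#' @param profile an [assay_profile()].
#' @param path YAML path.
#' @return `write_assay_profile()`: `path` invisibly;
#'   `read_assay_profile()`: an `assay_profile`.
#' @export
write_assay_profile <- function(profile, path) {
  stopifnot(inherits(profile, "assay_profile"))
  p <- unclass(profile)
  p$control_count_means <- as.list(p$control_count_means)
  yaml::write_yaml(list(schema_version = 1, profile = p), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_assay_profile
#' @export
read_assay_profile <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- cfg$profile %||% cfg
  p$schema_version <- NULL
  if (!is.null(p$control_count_means)) {
    p$control_count_means <- unlist(p$control_count_means)
  }
  unknown <- setdiff(names(p), names(formals(assay_profile)))
  if (length(unknown)) {
    stop("read_assay_profile: unknown profile key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  do.call(assay_profile, p)
}

#' Read a run manifest
#'
#' YAML describing one batch: `batch_id`, a `samples` list (each entry
#' `sample_id`, `role`), paths to the batch's `metrics` and `calls`
#' tables, optional `thresholds` and `profile` config paths, and the
#' positive control's `expected_variants`. A batch must declare exactly
#' one `positive_control` and one `ntc`.
#'
#' @param path YAML path.
#' @return an object of class `run_manifest`.
#' @export
read_run_manifest <- function(path) {
  if (!file.exists(path)) stop("read_run_manifest: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (field in c("batch_id", "samples", "metrics", "calls")) {
    if (is.null(cfg[[field]])) {
      stop("read_run_manifest: ", path, " is missing field '", field, "'")
    }
  }
  roles <- vapply(cfg$samples, function(s) s$role %||% "clinical",
                  character(1))
  if (sum(roles == "positive_control") != 1L || sum(roles == "ntc") != 1L) {
    stop("read_run_manifest: configuration error: manifest must declare exactly one positive_control and one ntc")
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  structure(list(batch_id = cfg$batch_id, samples = cfg$samples,
                 metrics = resolve(cfg$metrics), calls = resolve(cfg$calls),
                 thresholds = resolve(cfg$thresholds),
                 profile = resolve(cfg$profile),
                 expected_variants = unlist(cfg$expected_variants)),
            class = "run_manifest")
}

#' Write a JSON report
#'
#' All pipeline stage reports use this writer: unboxed scalars, full
#' numeric precision, `NA` as null.
#'
#' @param x report object (lists/data frames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}
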