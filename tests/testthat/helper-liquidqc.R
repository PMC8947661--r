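# Fixture loaders and independent oracles shared across test files.

extdata <- function(name) {
  path <- system.file("extdata", name, package = "liquidqc")
  if (!nzchar(path)) stop("fixture not found: ", name)
  path
}

# the assay's published five-point fusion dilution series (molecular copies)
load_ros1_series <- function() {
  df <- read.delim(extdata("ros1_dilution_series.tsv"),
                   stringsAsFactors = FALSE)
  dilution_series("fusion", "SLC34A2-ROS1",
                  data.frame(dilution = df$dilution, replicate = df$replicate,
                             measurement = df$molecular_copies,
                             p_value = NA_real_, call = df$call,
                             stringsAsFactors = FALSE),
                  dilution_levels = paste0("D", 1:5))
}

# the published CNA dilution series (fold change; dilutions 4-5 undetected)
load_erbb2_series <- function() {
  df <- read.delim(extdata("erbb2_dilution_series.tsv"),
                   stringsAsFactors = FALSE)
  dilution_series("cna", "ERBB2",
                  data.frame(dilution = df$dilution, replicate = df$replicate,
                             measurement = df$fold_change,
                             p_value = NA_real_, call = df$call,
                             stringsAsFactors = FALSE),
                  dilution_levels = paste0("D", 1:5))
}

# brute-force mean / sample SD / CV, written from the definitions
oracle_summary <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  ss <- 0
  for (x in v) ss <- ss + (x - m)^2
  s <- sqrt(ss / (n - 1))
  list(mean = m, sd = s, cv = 100 * s / m)
}

# independent re-statement of the sample-level QC predicate
oracle_sample_pass <- function(m, th) {
  m$total_mapped_reads >= th$min_mapped_reads &&
    m$coverage_uniformity >= th$min_coverage_uniformity &&
    m$median_molecular_coverage >= th$min_median_mol_cov &&
    m$molecular_uniformity >= th$min_mol_uniformity &&
    m$mean_read_length >= th$min_mean_read_length &&
    m$aq20_fraction >= th$min_aq20 &&
    m$mapd < th$max_mapd
}

# independent re-statement of the variant-level and NTC predicates
oracle_fusion_call <- function(copies, ctrl, th) {
  pair1 <- max(ctrl$tbp, ctrl$hmbs) >= th$internal_control_min_copies
  pair2 <- max(ctrl$met_e6_e7, ctrl$met_e11_e12) >=
    th$internal_control_min_copies
  if (!(pair1 && pair2)) return("invalid")
  if (copies >= th$fusion_min_copies) "detected" else "not_detected"
}

oracle_cna_call <- function(fold, p, mapd, th) {
  if (mapd >= th$max_mapd) return("invalid")
  if (fold >= th$cna_min_ratio && p < th$cna_max_p) "detected"
  else "not_detected"
}

oracle_ntc_pass <- function(reads, read_len, n_detected, th) {
  (reads <= th$ntc_max_reads || read_len <= th$ntc_max_read_length) &&
    n_detected == 0
}

passing_metrics <- function(mapd = 0.2) {
  sample_metrics(1.5e7, 97, 2500, 90, 100, 90, mapd)
}

valid_controls <- function() internal_controls(100, 100, 100, 100)
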