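#' Assay simulation profile
#'
#' Parameterizes the synthetic assay-output generator: molecular-family
#' counts for fusion/skipping targets along a dilution series, CNA fold
#' changes that attenuate toward 1.0 with dilution, internal
#' process-control counts and sample-level metrics. Defaults are
#' calibrated to the assay's validated dilution behaviour: fusion series
#' means 601/293/157/82/42 molecular copies and CNA series means
#' 5.36/2.30/1.40 with dilutions 4-5 below the 1.15-fold call gate.
#'
#' Counts are negative binomial with a quadratic dispersion parameter
#' (`variance = mu + dispersion * mu^2`); `count_dispersion = 0`
#' degenerates to Poisson. Observed replicate CVs at these count levels
#' exceed pure-Poisson CV, so overdispersion is configurable. The CNA
#' measurement model is
#' `fold_change = 1 + (cna_true_gain - 1) * tumor_fraction + N(0, ratio_noise_sd)`,
#' floored at `fold_change_floor`; its p-value is a documented stand-in,
#' see [cna_p_value()].
#'
#' @param fusion_count_mean_at_neat mean molecular-family count of the
#'   fusion target in the undiluted (neat) admixture.
#' @param dilution_factors strictly decreasing factors in (0, 1\], one per
#'   dilution point, scaling the neat fusion mean.
#' @param count_dispersion nonnegative NB dispersion; 0 = Poisson.
#' @param control_count_means mean molecular counts of the four internal
#'   process controls (TBP, HMBS, MET E6-E7, MET E11-E12).
#' @param cna_true_gain fold change of the amplified cell line at tumor
#'   fraction 1 (>= 1).
#' @param tumor_fraction_per_dilution non-increasing fractions in \[0, 1\],
#'   same length as `dilution_factors`.
#' @param ratio_noise_sd additive Gaussian noise SD on the fold change.
#' @param fold_change_floor minimum reportable fold change (> 0).
#' @param background_fusion_mean mean molecular-family count per fusion
#'   target in variant-free material (spurious UMI families).
#' @param mapd_mean,mapd_sd sample MAPD distribution (normal, floored at
#'   0.01).
#' @param seed default integer seed for operations on this profile; every
#'   generator also takes an explicit `seed` argument.
#' @return an object of class `assay_profile`.
#' @export
#' @examples
#' p <- assay_profile()
#' round(p$fusion_count_mean_at_neat * p$dilution_factors)
assay_profile <- function(fusion_count_mean_at_neat = 601,
                          dilution_factors = c(601, 293, 157, 82, 42) / 601,
                          count_dispersion = 0.02,
                          control_count_means = c(tbp = 1500, hmbs = 1200,
                                                  met_e6_e7 = 800,
                                                  met_e11_e12 = 600),
                          cna_true_gain = 5.36,
                          tumor_fraction_per_dilution =
                            c(1, 1.30 / 4.36, 0.40 / 4.36, 0.02, 0.01),
                          ratio_noise_sd = 0.02,
                          fold_change_floor = 0.01,
                          background_fusion_mean = 0.01,
                          mapd_mean = 0.2,
                          mapd_sd = 0.03,
                          seed = 1L) {
  stopifnot(is_scalar_num(fusion_count_mean_at_neat),
            fusion_count_mean_at_neat > 0,
            is.numeric(dilution_factors), length(dilution_factors) >= 1,
            all(dilution_factors > 0), all(dilution_factors <= 1),
            is_scalar_num(count_dispersion), count_dispersion >= 0,
            is.numeric(control_count_means), length(control_count_means) == 4,
            all(control_count_means > 0),
            is_scalar_num(cna_true_gain), cna_true_gain >= 1,
            is.numeric(tumor_fraction_per_dilution),
            all(tumor_fraction_per_dilution >= 0),
            all(tumor_fraction_per_dilution <= 1),
            is_scalar_num(ratio_noise_sd), ratio_noise_sd >= 0,
            is_scalar_num(fold_change_floor), fold_change_floor > 0,
            is_scalar_num(background_fusion_mean), background_fusion_mean >= 0,
            is_scalar_num(mapd_mean), mapd_mean > 0,
            is_scalar_num(mapd_sd), mapd_sd >= 0,
            is_count(abs(seed)))
  if (length(dilution_factors) > 1 && any(diff(dilution_factors) >= 0)) {
    stop("assay_profile: dilution_factors must be strictly decreasing")
  }
  if (length(tumor_fraction_per_dilution) != length(dilution_factors)) {
    stop("assay_profile: tumor_fraction_per_dilution must match dilution_factors in length")
  }
  if (any(diff(tumor_fraction_per_dilution) > 0)) {
    stop("assay_profile: tumor_fraction_per_dilution must be non-increasing")
  }
  names(control_count_means) <- c("tbp", "hmbs", "met_e6_e7", "met_e11_e12")
  structure(list(
    fusion_count_mean_at_neat = fusion_count_mean_at_neat,
    dilution_factors = dilution_factors,
    count_dispersion = count_dispersion,
    control_count_means = control_count_means,
    cna_true_gain = cna_true_gain,
    tumor_fraction_per_dilution = tumor_fraction_per_dilution,
    ratio_noise_sd = ratio_noise_sd,
    fold_change_floor = fold_change_floor,
    background_fusion_mean = background_fusion_mean,
    mapd_mean = mapd_mean,
    mapd_sd = mapd_sd,
    seed = as.integer(seed)
  ), class = "assay_profile")
}

# NB counts with variance mu + dispersion*mu^2; dispersion 0 -> Poisson.
sim_counts <- function(n, mu, dispersion) {
  if (mu <= 0) return(integer(n))
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

check_dilution_index <- function(profile, dilution_index) {
  if (!is_count(dilution_index) || dilution_index < 1 ||
      dilution_index > length(profile$dilution_factors)) {
    stop("dilution_index out of range: must be an integer in 1..",
         length(profile$dilution_factors))
  }
}

#' Simulate fusion/skipping molecular-family counts at one dilution
#'
#' Counts are drawn with mean
#' `fusion_count_mean_at_neat * dilution_factors[dilution_index]` under the
#' profile's dispersion. Identical `profile` and `seed` give identical
#' vectors.
#'
#' @param profile an [assay_profile()].
#' @param dilution_index dilution point, 1 = most concentrated.
#' @param n_replicates number of replicate draws (>= 1).
#' @param seed integer seed; defaults to the profile's.
#' @return integer vector of nonnegative molecular-family counts.
#' @export
simulate_fusion_counts <- function(profile, dilution_index, n_replicates,
                                   seed = profile$seed) {
  stopifnot(inherits(profile, "assay_profile"))
  check_dilution_index(profile, dilution_index)
  stopifnot(is_count(n_replicates), n_replicates >= 1)
  mu <- profile$fusion_count_mean_at_neat *
    profile$dilution_factors[dilution_index]
  with_seed(derive_seed(seed, 100 + dilution_index),
            sim_counts(n_replicates, mu, profile$count_dispersion))
}

#' Stand-in p-value for a CNA fold change
#'
#' The vendor caller's p-value definition is opaque; the simulator owns
#' this documented stand-in: a one-sided normal tail probability of the
#' standardized excess of the fold change over 1.0,
#' `p = P(Z >= (fold_change - 1) / noise_sd)`, with `p = 1` exactly when
#' there is no excess, clamped to be positive. It preserves the property
#' the call gate needs: large amplification excess relative to noise gives
#' a small p-value.
#'
#' @param fold_change numeric vector of fold changes.
#' @param noise_sd reference noise SD (the profile's `ratio_noise_sd`).
#' @return numeric vector of p-values in (0, 1\].
#' @export
cna_p_value <- function(fold_change, noise_sd) {
  stopifnot(is.numeric(fold_change), is_scalar_num(noise_sd), noise_sd >= 0)
  excess <- pmax(fold_change - 1, 0)
  se <- max(noise_sd, 1e-12)
  p <- ifelse(excess <= 0, 1, stats::pnorm(excess / se, lower.tail = FALSE))
  pmax(p, 1e-300)
}

#' Simulate CNA fold changes and p-values at one dilution
#'
#' `fold_change = 1 + (cna_true_gain - 1) * tumor_fraction + N(0, sd)`,
#' floored at the profile's minimum; p-values from [cna_p_value()].
#'
#' @inheritParams simulate_fusion_counts
#' @return data frame with columns `fold_change` and `p_value`.
#' @export
simulate_cna_ratio <- function(profile, dilution_index, n_replicates,
                               seed = profile$seed) {
  stopifnot(inherits(profile, "assay_profile"))
  check_dilution_index(profile, dilution_index)
  stopifnot(is_count(n_replicates), n_replicates >= 1)
  tf <- profile$tumor_fraction_per_dilution[dilution_index]
  fold <- with_seed(derive_seed(seed, 200 + dilution_index), {
    pmax(1 + (profile$cna_true_gain - 1) * tf +
           stats::rnorm(n_replicates, 0, profile$ratio_noise_sd),
         profile$fold_change_floor)
  })
  data.frame(fold_change = fold,
             p_value = cna_p_value(fold, profile$ratio_noise_sd))
}

# draw one internal-control panel (or n as a data frame)
simulate_internal_controls <- function(profile, n = 1, seed = profile$seed) {
  mus <- profile$control_count_means
  with_seed(derive_seed(seed, 300), {
    out <- vapply(mus, function(mu) sim_counts(n, mu, profile$count_dispersion),
                  numeric(n))
    if (n == 1L) out <- t(out)
    as.data.frame(out)
  })
}

# passing sample metrics for a given role; ntc draws an empty-looking lane
simulate_sample_metrics <- function(profile, seed = profile$seed,
                                    role = "clinical") {
  with_seed(derive_seed(seed, 400), {
    if (role == "ntc") {
      sample_metrics(
        total_mapped_reads = round(stats::runif(1, 5e5, 3e6)),
        coverage_uniformity = stats::runif(1, 20, 60),
        median_molecular_coverage = round(stats::runif(1, 0, 50)),
        molecular_uniformity = stats::runif(1, 10, 50),
        mean_read_length = stats::runif(1, 25, 40),
        aq20_fraction = stats::runif(1, 50, 80),
        mapd = stats::runif(1, 0.5, 1.5)
      )
    } else {
      sample_metrics(
        total_mapped_reads = round(stats::runif(1, 1.2e7, 1.8e7)),
        coverage_uniformity = stats::runif(1, 96, 99.5),
        median_molecular_coverage = round(stats::runif(1, 2000, 4000)),
        molecular_uniformity = stats::runif(1, 85, 95),
        mean_read_length = stats::runif(1, 90, 110),
        aq20_fraction = stats::runif(1, 85, 95),
        mapd = max(stats::rnorm(1, profile$mapd_mean, profile$mapd_sd), 0.01)
      )
    }
  })
}

#' Dilution-series container
#'
#' @param variant_kind `"fusion"` or `"cna"`.
#' @param target_id the measured target.
#' @param rows data frame with columns `dilution`, `replicate`,
#'   `measurement`, `p_value`, `call`; dilution labels are ordered with
#'   the most concentrated point first.
#' @param dilution_levels optional explicit ordering of dilution labels.
#' @return an object of class `dilution_series`.
#' @export
dilution_series <- function(variant_kind, target_id, rows,
                            dilution_levels = unique(rows$dilution)) {
  variant_kind <- match.arg(variant_kind, c("fusion", "cna"))
  req <- c("dilution", "replicate", "measurement", "call")
  if (!all(req %in% names(rows))) {
    stop("dilution_series: rows must have columns ",
         paste(req, collapse = ", "))
  }
  if (nrow(rows) == 0L) stop("dilution_series: empty series rejected")
  if (!"p_value" %in% names(rows)) rows$p_value <- NA_real_
  rows$dilution <- factor(rows$dilution, levels = dilution_levels)
  structure(list(variant_kind = variant_kind, target_id = target_id,
                 rows = rows), class = "dilution_series")
}

#' Simulate a full dilution series with calls
#'
#' Generates replicate measurements at every dilution point and runs them
#' through the call gates ([call_fusion()] / [call_cna()]) with
#' per-replicate simulated internal controls (fusion) or MAPD (CNA), so
#' the series carries everything downstream sensitivity analysis needs.
#'
#' @param profile an [assay_profile()].
#' @param variant_kind `"fusion"` or `"cna"`.
#' @param replicates_per_dilution integer vector, one count per dilution
#'   (total must be >= 1).
#' @param seed integer seed; defaults to the profile's.
#' @param thresholds a [qc_thresholds()] object for the calls.
#' @param target_id measured target id; defaults to the calibration
#'   target of each kind.
#' @return a [dilution_series()].
#' @export
#' @examples
#' s <- make_dilution_series(assay_profile(), "fusion", c(2, 3, 3, 3, 3))
#' nrow(s$rows)  # 14
make_dilution_series <- function(profile, variant_kind = c("fusion", "cna"),
                                 replicates_per_dilution,
                                 seed = profile$seed,
                                 thresholds = qc_thresholds(),
                                 target_id = NULL) {
  stopifnot(inherits(profile, "assay_profile"))
  variant_kind <- match.arg(variant_kind)
  nd <- length(profile$dilution_factors)
  if (length(replicates_per_dilution) != nd) {
    stop("make_dilution_series: replicates_per_dilution must have one entry per dilution (",
         nd, ")")
  }
  stopifnot(all(vapply(replicates_per_dilution, is_count, logical(1))))
  if (sum(replicates_per_dilution) < 1) {
    stop("make_dilution_series: empty series rejected")
  }
  target_id <- target_id %||%
    if (variant_kind == "fusion") "SLC34A2-ROS1" else "ERBB2"

  rows <- do.call(rbind, lapply(seq_len(nd), function(i) {
    r <- replicates_per_dilution[i]
    if (r == 0L) return(NULL)
    if (variant_kind == "fusion") {
      copies <- simulate_fusion_counts(profile, i, r, seed)
      panels <- simulate_internal_controls(profile, r,
                                           derive_seed(seed, 500 + i))
      call <- vapply(seq_len(r), function(j) {
        call_fusion(copies[j],
                    internal_controls(panels$tbp[j], panels$hmbs[j],
                                      panels$met_e6_e7[j],
                                      panels$met_e11_e12[j]),
                    thresholds)
      }, character(1))
      data.frame(dilution = paste0("D", i),
                 replicate = paste0("R", seq_len(r)),
                 measurement = as.numeric(copies),
                 p_value = NA_real_, call = call,
                 stringsAsFactors = FALSE)
    } else {
      sim <- simulate_cna_ratio(profile, i, r, seed)
      mapd <- with_seed(derive_seed(seed, 600 + i),
                        pmax(stats::rnorm(r, profile$mapd_mean,
                                          profile$mapd_sd), 0.01))
      data.frame(dilution = paste0("D", i),
                 replicate = paste0("R", seq_len(r)),
                 measurement = sim$fold_change,
                 p_value = sim$p_value,
                 call = call_cna(sim$fold_change, sim$p_value, mapd,
                                 thresholds),
                 stringsAsFactors = FALSE)
    }
  }))
  dilution_series(variant_kind, target_id, rows,
                  dilution_levels = paste0("D", seq_len(nd)))
}

# CNA gene content of the panel (12 genes)
cna_panel_genes <- function() {
  c("CCND1", "CCND2", "CCND3", "CDK4", "CDK6", "EGFR",
    "ERBB2", "FGFR1", "FGFR2", "FGFR3", "MET", "MYC")
}

new_simulated_sample <- function(sample_id, role, metrics, controls,
                                 fusion_rows, cna_rows) {
  structure(list(sample_id = sample_id, role = role, metrics = metrics,
                 controls = controls, fusion_rows = fusion_rows,
                 cna_rows = cna_rows), class = "simulated_sample")
}

#' Simulate a normal-healthy-donor (negative) cohort
#'
#' Samples carry valid internal controls and passing sequencing metrics
#' but background-only signal: fusion targets draw spurious molecular
#' families at the profile's background mean, and CNA fold changes
#' fluctuate around 1.0 with the profile's noise, so that no target should
#' pass the call gates. Calls are filled through the QC engine.
#'
#' @param n_samples number of donors (>= 1).
#' @param n_fusion_targets fusion/skipping targets assayed per sample.
#' @param n_cna_targets CNA targets assayed per sample.
#' @param profile an [assay_profile()].
#' @param seed integer seed; defaults to the profile's.
#' @param thresholds a [qc_thresholds()] object.
#' @return list of `simulated_sample` objects with role `"nhd"`.
#' @export
#' @examples
#' cohort <- make_negative_cohort(2, 5, 3, assay_profile(seed = 7))
#' sum(cohort_call_table(cohort)$call == "detected")
make_negative_cohort <- function(n_samples, n_fusion_targets, n_cna_targets,
                                 profile = assay_profile(),
                                 seed = profile$seed,
                                 thresholds = qc_thresholds()) {
  stopifnot(is_count(n_samples), n_samples >= 1,
            is_count(n_fusion_targets), n_fusion_targets >= 1,
            is_count(n_cna_targets), n_cna_targets >= 1,
            inherits(profile, "assay_profile"))
  fus_ids <- sprintf("FUS_T%03d", seq_len(n_fusion_targets))
  genes <- cna_panel_genes()
  cna_ids <- if (n_cna_targets <= length(genes)) genes[seq_len(n_cna_targets)]
             else c(genes, sprintf("CNA_T%03d",
                                   seq_len(n_cna_targets - length(genes))))
  lapply(seq_len(n_samples), function(s) {
    sseed <- derive_seed(seed, 1000 + s)
    metrics <- simulate_sample_metrics(profile, sseed, role = "clinical")
    panel <- simulate_internal_controls(profile, 1, derive_seed(sseed, 1))
    controls <- internal_controls(panel$tbp[1], panel$hmbs[1],
                                  panel$met_e6_e7[1], panel$met_e11_e12[1])
    copies <- with_seed(derive_seed(sseed, 2),
                        sim_counts(n_fusion_targets,
                                   profile$background_fusion_mean,
                                   profile$count_dispersion))
    fold <- with_seed(derive_seed(sseed, 3),
                      pmax(1 + stats::rnorm(n_cna_targets, 0,
                                            profile$ratio_noise_sd),
                           profile$fold_change_floor))
    smp <- new_simulated_sample(
      sample_id = sprintf("NHD%d", s), role = "nhd",
      metrics = metrics, controls = controls,
      fusion_rows = data.frame(target_id = fus_ids,
                               molecular_copies = as.numeric(copies),
                               call = NA_character_,
                               stringsAsFactors = FALSE),
      cna_rows = data.frame(target_id = cna_ids,
                            fold_change = fold,
                            p_value = cna_p_value(fold,
                                                  profile$ratio_noise_sd),
                            call = NA_character_,
                            stringsAsFactors = FALSE)
    )
    call_sample_observations(smp, thresholds)
  })
}

# analytic positive control: strong signal on the monitored fusion
# transcripts and CNA genes, drawn around the established control-chart
# centres so the chart module sees realistic baselines.
make_positive_control <- function(profile = assay_profile(),
                                  seed = profile$seed,
                                  thresholds = qc_thresholds()) {
  ref <- reference_control_limits()
  fus <- ref[ref$kind == "fusion_reads", ]
  cna <- ref[ref$kind == "cna_fold_change", ]
  metrics <- simulate_sample_metrics(profile, derive_seed(seed, 4), "clinical")
  panel <- simulate_internal_controls(profile, 1, derive_seed(seed, 5))
  controls <- internal_controls(panel$tbp[1], panel$hmbs[1],
                                panel$met_e6_e7[1], panel$met_e11_e12[1])
  fus_vals <- with_seed(derive_seed(seed, 6), {
    stats::rnorm(nrow(fus), (fus$lower + fus$upper) / 2,
                 (fus$upper - fus$lower) / 6)
  })
  cna_vals <- with_seed(derive_seed(seed, 7), {
    stats::rnorm(nrow(cna), (cna$lower + cna$upper) / 2,
                 (cna$upper - cna$lower) / 6)
  })
  smp <- new_simulated_sample(
    sample_id = "PC", role = "positive_control", metrics = metrics,
    controls = controls,
    fusion_rows = data.frame(target_id = fus$analyte_id,
                             molecular_copies = pmax(round(fus_vals), 0),
                             call = NA_character_, stringsAsFactors = FALSE),
    cna_rows = data.frame(target_id = cna$analyte_id,
                          fold_change = pmax(cna_vals,
                                             profile$fold_change_floor),
                          p_value = cna_p_value(pmax(cna_vals, 0.01),
                                                profile$ratio_noise_sd),
                          call = NA_character_, stringsAsFactors = FALSE)
  )
  call_sample_observations(smp, thresholds)
}

# no-template control: empty lane, zero true-variant counts by invariant
make_ntc <- function(profile = assay_profile(), seed = profile$seed,
                     thresholds = qc_thresholds()) {
  metrics <- simulate_sample_metrics(profile, derive_seed(seed, 8), "ntc")
  smp <- new_simulated_sample(
    sample_id = "NTC", role = "ntc", metrics = metrics,
    controls = internal_controls(0, 0, 0, 0),
    fusion_rows = data.frame(
      target_id = c("EML4-ALK", "CCDC6-RET", "CD74-ROS1"),
      molecular_copies = 0, call = NA_character_, stringsAsFactors = FALSE),
    cna_rows = data.frame(
      target_id = c("ERBB2", "MYC"), fold_change = profile$fold_change_floor,
      p_value = 1, call = NA_character_, stringsAsFactors = FALSE)
  )
  call_sample_observations(smp, thresholds)
}

#' Simulate one processing batch (positive control + NTC + clinical)
#'
#' @param profile an [assay_profile()].
#' @param n_clinical number of clinical (background-only) samples.
#' @param seed integer seed.
#' @param thresholds a [qc_thresholds()] object.
#' @return list of samples suitable for [evaluate_batch()].
#' @export
make_batch <- function(profile = assay_profile(), n_clinical = 4,
                       seed = profile$seed, thresholds = qc_thresholds()) {
  stopifnot(is_count(n_clinical))
  clin <- if (n_clinical > 0) {
    cl <- make_negative_cohort(n_clinical, 95, 12, profile,
                               derive_seed(seed, 9), thresholds)
    lapply(seq_along(cl), function(i) {
      cl[[i]]$sample_id <- sprintf("CLIN%d", i)
      cl[[i]]$role <- "clinical"
      cl[[i]]
    })
  } else list()
  c(list(make_positive_control(profile, seed, thresholds),
         make_ntc(profile, seed, thresholds)), clin)
}

#' Precision study design
#'
#' The repeatability arm measures each specimen in triplicate within run 1;
#' the intermediate-precision arm spans `n_runs` runs on different days
#' with alternating operators and instruments, one replicate per run in
#' runs 2..n. Three fusion specimens carry a single fusion each at high /
#' medium / low level; two CNA specimens carry five amplification events
#' (two high, three low, the lows near the assay's 1.40-fold LOD).
#'
#' @param n_fusion_specimens,n_cna_events,repeat_replicates,n_runs,n_operators,n_instruments
#'   design sizes (all >= 1).
#' @param fusion_levels named numeric: molecular-copy level per fusion
#'   specimen.
#' @param cna_events data frame with `specimen`, `target_id`, `level`
#'   (fold change) per CNA event.
#' @param within_run_cv named numeric (`fusion`, `cna`): within-run
#'   coefficient of variation of the measurement.
#' @param between_run_cv named numeric (`fusion`, `cna`): run-to-run CV.
#' @return an object of class `precision_design`.
#' @export
precision_design <- function(n_fusion_specimens = 3,
                             n_cna_events = 5,
                             repeat_replicates = 3,
                             n_runs = 4,
                             n_operators = 2,
                             n_instruments = 2,
                             fusion_levels = c(FUS_HIGH = 600, FUS_MED = 150,
                                               FUS_LOW = 42),
                             cna_events = data.frame(
                               specimen = c("CNA_A", "CNA_A", "CNA_A",
                                            "CNA_B", "CNA_B"),
                               target_id = c("ERBB2", "CDK6", "EGFR",
                                             "MET", "MYC"),
                               level = c(3.0, 1.45, 1.40, 2.5, 1.35),
                               stringsAsFactors = FALSE),
                             within_run_cv = c(fusion = 0.20, cna = 0.02),
                             between_run_cv = c(fusion = 0.08, cna = 0.05)) {
  stopifnot(is_count(n_fusion_specimens), n_fusion_specimens >= 1,
            is_count(n_cna_events), n_cna_events >= 1,
            is_count(repeat_replicates), repeat_replicates >= 1,
            is_count(n_runs), n_runs >= 1,
            is_count(n_operators), n_operators >= 1,
            is_count(n_instruments), n_instruments >= 1,
            length(fusion_levels) == n_fusion_specimens,
            nrow(cna_events) == n_cna_events,
            all(c("fusion", "cna") %in% names(within_run_cv)),
            all(c("fusion", "cna") %in% names(between_run_cv)))
  structure(list(n_fusion_specimens = n_fusion_specimens,
                 n_cna_events = n_cna_events,
                 repeat_replicates = repeat_replicates,
                 n_runs = n_runs, n_operators = n_operators,
                 n_instruments = n_instruments,
                 fusion_levels = fusion_levels, cna_events = cna_events,
                 within_run_cv = within_run_cv,
                 between_run_cv = between_run_cv),
            class = "precision_design")
}

#' Simulate a repeatability / intermediate-precision study
#'
#' Long-format table keyed by specimen, target, run/day, operator,
#' instrument and replicate. Run 1 is the repeatability run
#' (`repeat_replicates` replicates); subsequent runs carry one replicate
#' each. Measurements are the event level under multiplicative lognormal
#' run and replicate effects with the design's between- and within-run
#' CVs. Event-runs can be forced sub-threshold (counted downstream as
#' misses) or censored (QC-failed, excluded from the analysis).
#'
#' @param profile an [assay_profile()] (supplies the CNA p-value noise
#'   reference).
#' @param design a [precision_design()].
#' @param seed integer seed.
#' @param miss_events optional data frame (`target_id`, `run`): those
#'   event-runs draw a measurement below the call gate.
#' @param censored_events optional data frame (`target_id`, `run`): those
#'   event-runs get `qc_pass = FALSE` (failed on run and rerun).
#' @return data frame of class `precision_study` with columns
#'   `variant_kind`, `specimen_id`, `target_id`, `run`, `day`, `operator`,
#'   `instrument`, `replicate`, `measurement`, `p_value`, `qc_pass`.
#' @export
#' @examples
#' st <- make_precision_study(assay_profile(seed = 3))
#' table(st$variant_kind)  # 18 fusion rows, 30 cna rows
make_precision_study <- function(profile = assay_profile(),
                                 design = precision_design(),
                                 seed = profile$seed,
                                 miss_events = NULL,
                                 censored_events = NULL) {
  stopifnot(inherits(profile, "assay_profile"),
            inherits(design, "precision_design"))
  runs <- seq_len(design$n_runs)
  operators <- rep_len(seq_len(design$n_operators), design$n_runs)
  instruments <- rep(seq_len(design$n_instruments),
                     each = ceiling(design$n_runs / design$n_instruments),
                     length.out = design$n_runs)
  fusion_days <- 1 + runs  # fusion arm run on days 2..; CNA arm days 1,3,4,...
  cna_days <- c(1, 2 + seq_len(design$n_runs - 1))

  events <- rbind(
    data.frame(variant_kind = "fusion",
               specimen_id = names(design$fusion_levels),
               target_id = names(design$fusion_levels),
               level = unname(design$fusion_levels),
               stringsAsFactors = FALSE),
    data.frame(variant_kind = "cna",
               specimen_id = design$cna_events$specimen,
               target_id = design$cna_events$target_id,
               level = design$cna_events$level,
               stringsAsFactors = FALSE)
  )

  rows <- do.call(rbind, lapply(seq_len(nrow(events)), function(e) {
    ev <- events[e, ]
    wcv <- design$within_run_cv[[ev$variant_kind]]
    bcv <- design$between_run_cv[[ev$variant_kind]]
    sdl_w <- sqrt(log(1 + wcv^2))
    sdl_b <- sqrt(log(1 + bcv^2))
    do.call(rbind, lapply(runs, function(r) {
      nrep <- if (r == 1L) design$repeat_replicates else 1L
      m <- with_seed(derive_seed(seed, 2000 + 37L * e + r), {
        run_eff <- exp(stats::rnorm(1, 0, sdl_b))
        ev$level * run_eff * exp(stats::rnorm(nrep, 0, sdl_w))
      })
      day <- if (ev$variant_kind == "fusion") fusion_days[r] else cna_days[r]
      data.frame(variant_kind = ev$variant_kind,
                 specimen_id = ev$specimen_id, target_id = ev$target_id,
                 run = r, day = day, operator = operators[r],
                 instrument = instruments[r], replicate = seq_len(nrep),
                 measurement = m, p_value = NA_real_, qc_pass = TRUE,
                 stringsAsFactors = FALSE)
    }))
  }))

  mark <- function(spec_df, rows) {
    idx <- rep(FALSE, nrow(rows))
    if (!is.null(spec_df)) {
      stopifnot(all(c("target_id", "run") %in% names(spec_df)))
      for (i in seq_len(nrow(spec_df))) {
        idx <- idx | (rows$target_id == spec_df$target_id[i] &
                        rows$run == spec_df$run[i])
      }
    }
    idx
  }

  miss_idx <- mark(miss_events, rows)
  if (any(miss_idx)) {
    rows$measurement[miss_idx] <- with_seed(derive_seed(seed, 3001), {
      ifelse(rows$variant_kind[miss_idx] == "cna",
             stats::runif(sum(miss_idx), 1.00, 1.10),
             sample(0:2, sum(miss_idx), replace = TRUE))
    })
  }
  rows$qc_pass[mark(censored_events, rows)] <- FALSE

  is_cna <- rows$variant_kind == "cna"
  rows$p_value[is_cna] <- cna_p_value(rows$measurement[is_cna],
                                      profile$ratio_noise_sd)
  class(rows) <- c("precision_study", class(rows))
  attr(rows, "design") <- design
  rows
}
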