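#!/usr/bin/env Rscript
# Stage 5: repeatability and intermediate precision. Three single-fusion
# specimens (high/medium/low) and two CNA specimens carrying five
# amplification events are measured in triplicate within run 1 and once
# in each of runs 2-4 (different days, alternating operators and
# instruments). The study conditions include the two documented CNA
# anomalies: one event-run censored after failing QC on run and rerun,
# and one low-level CDK6 event falling below the 1.15-fold gate in one
# run — giving 18/18 fusion and 28/29 CNA detection opportunities.

library(liquidqc)

profile <- assay_profile(seed = 20220317L)
study <- make_precision_study(
  profile,
  miss_events = data.frame(target_id = "CDK6", run = 3),
  censored_events = data.frame(target_id = "MYC", run = 4))

res <- precision_analysis(study,
                          extra_groupings = c("day", "operator",
                                              "instrument"))

dir.create("results/reports", recursive = TRUE, showWarnings = FALSE)
write_json_report(res, "results/reports/precision.json")

for (kind in c("fusion", "cna")) {
  r <- res[[kind]]
  message(sprintf("%s hit rate: %d/%d = %s%%", kind, r$hit$detected,
                  r$hit$expected, format(r$hit$percent)))
  message(sprintf(
    "  repeatability CV: avg %.1f%% (range %.1f-%.1f%%); intermediate: avg %.1f%% (range %.1f-%.1f%%)",
    r$average_repeatability_cv, r$repeatability_range[1],
    r$repeatability_range[2], r$average_intermediate_cv,
    r$intermediate_range[1], r$intermediate_range[2]))
}
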