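#!/usr/bin/env Rscript
# Stage 1: generate the synthetic assay outputs every later stage consumes.
#
# One seeded profile drives everything: a processing batch (positive
# control + NTC + clinical background samples), a 12-donor negative
# cohort, five-point fusion and CNA dilution series (2,3,3,3,3 replicates)
# and a 7-run positive-control baseline for the control charts. Tables
# land under results/sim/, reports under results/reports/.

library(liquidqc)

out_dir <- "results"
profile <- assay_profile(seed = 20220317L)

status <- run_pipeline("simulate", out_dir = out_dir, profile = profile)
stopifnot(status == 0L)

calls <- read_call_table(file.path(out_dir, "sim", "cohort_calls.tsv"))
series <- read_call_table(file.path(out_dir, "sim", "batch_calls.tsv"))
message("simulated negative cohort: ", length(unique(calls$sample_id)),
        " donors, ", nrow(calls), " target rows")
message("simulated batch: ", length(unique(series$sample_id)),
        " samples (incl. positive control and NTC)")
message("dilution series + precision study + control baseline written under ",
        file.path(out_dir, "sim"))
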