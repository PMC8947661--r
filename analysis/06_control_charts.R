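#!/usr/bin/env Rscript
# Stage 6: process control charting. Levey-Jennings limits (mean +/- 3
# sample SD) are derived from the simulated 7-run positive-control
# baseline and compared with the assay's established QC ranges; every
# baseline point is classified against both sets of limits. Charts are
# rendered as PNGs under results/reports/.

library(liquidqc)

status <- run_pipeline("chart", out_dir = "results", render_png = TRUE)
stopifnot(status == 0L)

lims <- jsonlite::read_json("results/reports/control_limits.json")
ref <- reference_control_limits()
for (a in names(lims)) {
  l <- lims[[a]]
  r <- ref[ref$analyte_id == a, ]
  message(sprintf(
    "%s: derived limits %.3g-%.3g (established range %.3g-%.3g)",
    a, as.numeric(l$lower), as.numeric(l$upper), r$lower, r$upper))
  established <- control_limits_from_range(a, r$lower, r$upper)
  mid <- recover_mean_sd(established)$mean
  stopifnot(evaluate_point(mid, established) == "in_control")
}
message("charts: results/reports/chart_*.png")
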