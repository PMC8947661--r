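#!/usr/bin/env Rscript
# Stage 2: batch acceptance. The simulated batch's positive control must
# show every monitored variant as detected and the NTC must be acceptably
# empty; every sample-level gate decision is logged with its threshold in
# results/reports/pipeline.log.

library(liquidqc)

status <- run_pipeline("qc", out_dir = "results")
verdict <- jsonlite::read_json("results/reports/batch_verdict.json")

message("batch ", verdict$batch_id, ": ",
        if (isTRUE(verdict$batch_pass)) "PASS" else "FAIL")
message("  positive control pass: ", verdict$positive_control_pass)
message("  NTC pass:              ", verdict$ntc_pass)
if (length(verdict$reasons)) {
  message("  reasons: ", paste(unlist(verdict$reasons), collapse = "; "))
}
stopifnot(status == 0L)
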