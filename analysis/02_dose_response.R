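#!/usr/bin/env Rscript
# Summarize each discovery line's viability series into AUSC and IC50 and
# stratify the panel: extreme Responders (AUSC < 0.75 and IC50 below a
# quarter of the top dose), extreme Non-Responders (AUSC > 0.98, IC50 beyond
# the tested range), and the partial/limited middle.

suppressPackageStartupMessages(library(drsig))

dr <- read_dose_response("results/data/discovery_dose_response.csv")
calls <- response_calls(dr, mode = "discovery")
dir.create("results", showWarnings = FALSE)
write.csv(calls, "results/response_calls.csv", row.names = FALSE)

tab <- table(calls$response_class)
message("Response stratification of the discovery panel:")
for (cl in names(tab)) message(sprintf("  %-14s %d", cl, tab[cl]))
message(sprintf("AUSC range %.2f-%.2f; %d/%d lines IC50-censored at the top dose",
                min(calls$ausc), max(calls$ausc), sum(calls$ic50_censored),
                nrow(calls)))
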