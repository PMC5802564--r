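#!/usr/bin/env Rscript
# Validate on the 11 held-out lines: their expression arrives on a distorted
# second platform, so it is first quantile-mapped onto the training
# distribution; predictions are then scored against the binary AUSC < 0.8
# response rule measured from their viability curves.

suppressPackageStartupMessages(library(drsig))

model <- read_ra_model("results/ra_model.txt")
vexpr <- read_expression("results/data/holdout_expression.tsv",
                         platform = "synthetic-B")
vdr <- read_dose_response("results/data/holdout_dose_response.csv")

norm <- normalize_to_reference(vexpr, model)
pred <- predict(model, norm)
calls <- response_calls(vdr, mode = "validation")
truth <- data.frame(sample_id = calls$sample_id,
                    class = ifelse(calls$response_class == "RESPONDER",
                                   "Responder", "NonResponder"))
m <- evaluate_predictions(pred, truth)

write.csv(pred, "results/validation_predictions.csv", row.names = FALSE)
write.csv(data.frame(metric = names(m), value = unlist(m, use.names = FALSE)),
          "results/validation_metrics.csv", row.names = FALSE)

correct <- m$tp + m$tn
message(sprintf("Validation: %d of %d held-out lines predicted correctly", correct,
                nrow(pred)))
message(sprintf("Confusion: tp %d fp %d tn %d fn %d | sens %s spec %s",
                m$tp, m$fp, m$tn, m$fn,
                ifelse(is.na(m$sensitivity), "-", sprintf("%.1f%%", 100 * m$sensitivity)),
                ifelse(is.na(m$specificity), "-", sprintf("%.1f%%", 100 * m$specificity))))
gate_low <- sum(!pred$gate_passed)
message(sprintf("%d/%d lines were binned Non-Responder directly by the %s gate",
                gate_low, nrow(pred), model$gate_gene))
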