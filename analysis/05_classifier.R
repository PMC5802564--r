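#!/usr/bin/env Rscript
# Fit the gated Response-Average classifier from the extreme groups: the
# top-ranked signature gene becomes the gate (its sub-average expression
# forces a Non-Responder call), the next four score one point each, and a
# score below 3 is a Non-Responder.

suppressPackageStartupMessages(library(drsig))

em <- read_expression("results/data/discovery_expression.tsv",
                      platform = "synthetic-A")
calls <- read.csv("results/response_calls.csv")
sig <- read.csv("results/signature.csv")

top <- head(sig$gene_id, 5)
model <- fit_ra_model(em, calls, gate_gene = top[1], secondary_genes = top[-1],
                      score_threshold = 3)
write_ra_model(model, "results/ra_model.txt")
print(model)

# resubstitution check on the discovery panel against the binary AUSC rule
pred <- predict(model, em)
truth_calls <- response_calls(
  read_dose_response("results/data/discovery_dose_response.csv"), "validation")
truth <- data.frame(sample_id = truth_calls$sample_id,
                    class = ifelse(truth_calls$response_class == "RESPONDER",
                                   "Responder", "NonResponder"))
m <- evaluate_predictions(pred, truth)
write.csv(pred, "results/discovery_predictions.csv", row.names = FALSE)
message(sprintf("Discovery-panel fit: sens %.1f%%, spec %.1f%%, accuracy %.1f%% (tp %d fp %d tn %d fn %d)",
                100 * m$sensitivity, 100 * m$specificity, 100 * m$accuracy,
                m$tp, m$fp, m$tn, m$fn))
ext <- calls$response_class %in% c("RESPONDER", "NON_RESPONDER")
m_ext <- evaluate_predictions(pred[pred$sample_id %in% calls$sample_id[ext], ], truth)
message(sprintf("On the training extremes alone: accuracy %.1f%%",
                100 * m_ext$accuracy))
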