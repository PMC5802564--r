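#!/usr/bin/env Rscript
# Simulate the study cohort: an 82-line B-cell-like panel with a planted
# five-gene sensitivity signature, then set aside 11 lines (as if their drug
# response had not yet been assayed) for later validation. Writes the
# expression matrices, viability tables and ground truth under results/data/.

suppressPackageStartupMessages(library(drsig))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

spec <- cohort_spec(n_samples = 82, seed = seed)
cohort <- simulate_cohort(spec)
sp <- split_cohort(cohort, n_holdout = 11, seed = seed)

write_expression(sp$discovery$expression, file.path(outdir, "discovery_expression.tsv"))
write_dose_response(sp$discovery$dose_response, file.path(outdir, "discovery_dose_response.csv"))
write.csv(sp$discovery$truth, file.path(outdir, "discovery_truth.csv"), row.names = FALSE)

# the held-out lines arrive on a different expression platform
holdout_expr <- distort_platform(sp$holdout$expression, gain = 1.2, offset = -1,
                                 seed = seed)
write_expression(holdout_expr, file.path(outdir, "holdout_expression.tsv"))
write_dose_response(sp$holdout$dose_response, file.path(outdir, "holdout_dose_response.csv"))
write.csv(sp$holdout$truth, file.path(outdir, "holdout_truth.csv"), row.names = FALSE)

writeLines(paste(names(spec), vapply(spec, function(x) paste(format(x), collapse = ","), ""),
                 sep = " = "),
           file.path(outdir, "cohort_spec.txt"))

message(sprintf("Simulated %d lines (%d discovery, %d held-out), %d genes; signature: %s",
                spec$n_samples, ncol(sp$discovery$expression$values),
                ncol(sp$holdout$expression$values), spec$n_genes,
                strsplit(cohort$truth$signature_genes[1], ";")[[1]][1]))
message("Latent sensitivity strata: ",
        paste(names(table(cohort$truth$true_class)),
              table(cohort$truth$true_class), collapse = ", ", sep = "="))
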