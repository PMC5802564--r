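# Orchestration: one config drives the discovery workflow (response calls ->
# SAM -> over-representation -> signature -> Response-Average fit) and the
# validation workflow (normalize -> predict -> respond -> evaluate), writing
# every intermediate as CSV plus a manifest of files, digests and parameters.

#' Build a pipeline configuration
#'
#' Thresholds default to the workflow's canonical operating point: discovery
#' AUSC cuts 0.75 / 0.98 with the IC50 cut at max dose / 4, validation AUSC
#' cut 0.8, SAM FDR target 0.10, Mann-Whitney alpha 0.05 and a score
#' threshold of 3. All are overridable.
#'
#' @param cohort A [cohort_spec()] to simulate, an already-simulated cohort
#'   (list with `expression`, `dose_response`, `truth`, e.g. one half of
#'   [split_cohort()]), or `NULL` when file inputs are given.
#' @param expression_path,dose_response_path Input files (TSV / CSV), used
#'   when `cohort` is `NULL`.
#' @param gmt_path Gene-set catalogue; defaults to the bundled pathway file.
#' @param fdr_target,mw_alpha,score_threshold,n_permutations Stage
#'   parameters.
#' @param signature_size Number of top-ranked signature genes used for the
#'   classifier (gate = rank 1).
#' @param seed Integer seed driving every stochastic stage.
#' @param outdir Output directory (created if absent).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, expression_path = NULL,
                            dose_response_path = NULL, gmt_path = bundled_gmt(),
                            fdr_target = 0.10, mw_alpha = 0.05,
                            score_threshold = 3, n_permutations = 1000,
                            signature_size = 5, seed = 1, outdir = tempfile("drsig_run_")) {
  if (is.null(cohort) && (is.null(expression_path) || is.null(dose_response_path))) {
    stop("supply either a cohort spec or expression + dose-response paths", call. = FALSE)
  }
  structure(list(cohort = cohort, expression_path = expression_path,
                 dose_response_path = dose_response_path, gmt_path = gmt_path,
                 fdr_target = fdr_target, mw_alpha = mw_alpha,
                 score_threshold = score_threshold,
                 n_permutations = n_permutations,
                 signature_size = signature_size,
                 seed = seed, outdir = outdir), class = "pipeline_config")
}

manifest_entry <- function(stage, outputs, inputs = character(), params = list()) {
  data.frame(
    stage = stage,
    inputs = paste(inputs, collapse = ";"),
    outputs = paste(basename(outputs), collapse = ";"),
    digests = paste(unname(tools::md5sum(outputs)), collapse = ";"),
    params = paste(names(params), unlist(lapply(params, paste, collapse = ",")),
                   sep = "=", collapse = ";"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
    stringsAsFactors = FALSE
  )
}

load_discovery_inputs <- function(config) {
  if (!is.null(config$cohort)) {
    cohort <- if (inherits(config$cohort, "cohort_spec")) {
      simulate_cohort(config$cohort)
    } else {
      config$cohort  # an already-materialized cohort (e.g. a split_cohort() half)
    }
    list(expression = cohort$expression, dose_response = cohort$dose_response,
         truth = cohort$truth, source = "simulated")
  } else {
    list(expression = read_expression(config$expression_path),
         dose_response = read_dose_response(config$dose_response_path),
         truth = NULL, source = "files")
  }
}

#' Run the discovery workflow
#'
#' Stages: response calls (discovery mode) -> SAM between the extreme arms ->
#' over-representation of the called genes against the gene-set catalogue ->
#' signature selection anchored on the top-enriched set -> Response-Average
#' model fit (gate = top-ranked signature gene). Each stage writes a CSV (the
#' model as plain text) under `config$outdir` and is recorded in the returned
#' manifest. Identical config and seed reproduce digest-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list: `manifest` (data frame), `calls`, `sam`, `enrichment`,
#'   `signature`, `model`, `paths` (named file paths), plus the inputs used.
#' @export
run_discovery <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_discovery_inputs(config)
  em <- inputs$expression
  path <- function(f) file.path(config$outdir, f)
  manifest <- list()

  p_expr <- path("expression.tsv")
  p_dr <- path("dose_response.csv")
  write_expression(em, p_expr)
  write_dose_response(inputs$dose_response, p_dr)
  manifest$input <- manifest_entry("input", c(p_expr, p_dr),
                                   params = list(source = inputs$source,
                                                 seed = config$seed))

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  calls <- run_stage("respond", function() response_calls(inputs$dose_response, "discovery"))
  p_calls <- path("response_calls.csv")
  utils::write.csv(calls, p_calls, row.names = FALSE, quote = FALSE)
  manifest$respond <- manifest_entry("respond", p_calls, basename(p_dr),
                                     params = list(mode = "discovery"))

  extremes <- calls[calls$response_class %in% c("RESPONDER", "NON_RESPONDER"), ]
  sam <- run_stage("sam", function() {
    if (sum(extremes$response_class == "RESPONDER") < 2 ||
        sum(extremes$response_class == "NON_RESPONDER") < 2) {
      stop("fewer than 2 samples in an extreme arm")
    }
    sub <- subset_expression(em, samples = extremes$sample_id)
    labels <- factor(extremes$response_class,
                     levels = c("RESPONDER", "NON_RESPONDER"))
    sam_call(sub, labels, fdr_target = config$fdr_target,
             n_permutations = config$n_permutations, seed = config$seed)
  })
  p_sam <- path("sam_table.csv")
  utils::write.csv(sam$table, p_sam, row.names = FALSE, quote = FALSE)
  manifest$sam <- manifest_entry("sam", p_sam, basename(c(p_expr, p_calls)),
                                 params = list(fdr_target = config$fdr_target,
                                               n_permutations = sam$n_permutations_used,
                                               s0 = signif(sam$s0, 6),
                                               seed = config$seed))

  sets <- read_gmt(config$gmt_path)
  called_genes <- sam$table$gene_id[sam$table$called]
  enrichment <- run_stage("enrich", function() {
    if (!length(called_genes)) {
      warning("SAM called no genes; enrichment skipped")
      return(NULL)
    }
    suppressWarnings(overrepresentation(called_genes, sets, genes(em)))
  })
  p_enr <- path("enrichment.csv")
  if (is.null(enrichment)) {
    utils::write.csv(data.frame(set = character(), p = numeric()), p_enr,
                     row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(enrichment, p_enr, row.names = FALSE, quote = FALSE)
  }
  manifest$enrich <- manifest_entry("enrich", p_enr, basename(p_sam),
                                    params = list(gmt = basename(config$gmt_path)))

  signature <- run_stage("signature", function() {
    if (is.null(enrichment) || !nrow(enrichment)) {
      warning("no enrichment result; empty signature")
      return(NULL)
    }
    top_set <- sets[[enrichment$set[1]]]
    suppressWarnings(
      select_signature(sam$table, top_set, em, calls, alpha = config$mw_alpha))
  })
  p_sig <- path("signature.csv")
  if (is.null(signature) || !nrow(signature)) {
    warning("empty signature; classifier not fitted")
    utils::write.csv(data.frame(rank = integer(), gene_id = character()), p_sig,
                     row.names = FALSE, quote = FALSE)
    manifest$signature <- manifest_entry("signature", p_sig, basename(p_sam),
                                         params = list(alpha = config$mw_alpha))
    manifest$fit <- manifest_entry("fit", character(), basename(p_sig),
                                   params = list(skipped = TRUE))
    mf <- do.call(rbind, manifest)
    rownames(mf) <- NULL
    utils::write.csv(mf, path("manifest.csv"), row.names = FALSE, quote = FALSE)
    return(list(manifest = mf, calls = calls, sam = sam, enrichment = enrichment,
                signature = signature, model = NULL,
                inputs = inputs,
                paths = c(expression = p_expr, dose_response = p_dr,
                          calls = p_calls, sam = p_sam, enrichment = p_enr,
                          signature = p_sig)))
  }
  utils::write.csv(signature, p_sig, row.names = FALSE, quote = FALSE)
  manifest$signature <- manifest_entry("signature", p_sig,
                                       basename(c(p_sam, p_enr, p_expr, p_calls)),
                                       params = list(alpha = config$mw_alpha))

  model <- run_stage("fit", function() {
    top <- utils::head(signature$gene_id, config$signature_size)
    if (length(top) < 2) stop("signature too small for a gated classifier")
    fit_ra_model(em, calls, gate_gene = top[1], secondary_genes = top[-1],
                 score_threshold = min(config$score_threshold, length(top) - 1))
  })
  p_model <- path("ra_model.txt")
  write_ra_model(model, p_model)
  manifest$fit <- manifest_entry("fit", p_model, basename(c(p_sig, p_expr, p_calls)),
                                 params = list(score_threshold = model$score_threshold,
                                               gate = model$gate_gene))

  mf <- do.call(rbind, manifest)
  rownames(mf) <- NULL
  utils::write.csv(mf, path("manifest.csv"), row.names = FALSE, quote = FALSE)
  list(manifest = mf, calls = calls, sam = sam, enrichment = enrichment,
       signature = signature, model = model, inputs = inputs,
       paths = c(expression = p_expr, dose_response = p_dr, calls = p_calls,
                 sam = p_sam, enrichment = p_enr, signature = p_sig,
                 model = p_model))
}

#' Run the validation workflow
#'
#' Normalizes incoming expression onto the training platform, predicts with
#' the Response-Average model, derives truth from the validation-mode AUSC
#' rule on the new dose-response data, and writes predictions plus
#' confusion-matrix metrics.
#'
#' @param config A [pipeline_config()] (used for `outdir`).
#' @param model An `ra_model` or a path to one.
#' @param expression Incoming [expression_matrix()] (or TSV path).
#' @param dose_response Incoming dose-response data frame (or CSV path).
#' @return A list: `manifest`, `predictions`, `calls`, `metrics`, `paths`.
#' @export
run_validation <- function(config, model, expression, dose_response) {
  if (is.character(model)) model <- read_ra_model(model)
  if (is.character(expression)) expression <- read_expression(expression)
  if (is.character(dose_response)) dose_response <- read_dose_response(dose_response)
  if (ncol(expression$values) == 0) stop("empty validation set", call. = FALSE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$outdir, f)
  manifest <- list()

  skipped_norm <- identical(expression$platform, model$platform)
  normalized <- normalize_to_reference(expression, model)
  p_norm <- path("validation_expression_normalized.tsv")
  write_expression(normalized, p_norm)
  manifest$normalize <- manifest_entry("normalize", p_norm,
                                       params = list(skipped = skipped_norm,
                                                     platform = expression$platform))

  predictions <- predict(model, normalized)
  p_pred <- path("validation_predictions.csv")
  utils::write.csv(predictions, p_pred, row.names = FALSE, quote = FALSE)
  manifest$score <- manifest_entry("score", p_pred, basename(p_norm))

  calls <- response_calls(dose_response, "validation")
  p_calls <- path("validation_response_calls.csv")
  utils::write.csv(calls, p_calls, row.names = FALSE, quote = FALSE)
  manifest$respond <- manifest_entry("respond", p_calls,
                                     params = list(mode = "validation"))

  truth <- data.frame(sample_id = calls$sample_id,
                      class = ifelse(calls$response_class == "RESPONDER",
                                     "Responder", "NonResponder"),
                      stringsAsFactors = FALSE)
  metrics <- evaluate_predictions(predictions, truth)
  p_metrics <- path("validation_metrics.csv")
  utils::write.csv(data.frame(metric = names(metrics),
                              value = unlist(metrics, use.names = FALSE)),
                   p_metrics, row.names = FALSE, quote = FALSE)
  manifest$eval <- manifest_entry("eval", p_metrics, basename(c(p_pred, p_calls)))

  mf <- do.call(rbind, manifest)
  rownames(mf) <- NULL
  utils::write.csv(mf, path("validation_manifest.csv"), row.names = FALSE, quote = FALSE)
  list(manifest = mf, predictions = predictions, calls = calls, metrics = metrics,
       paths = c(normalized = p_norm, predictions = p_pred, calls = p_calls,
                 metrics = p_metrics))
}
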