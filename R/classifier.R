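# The gated Response-Average classifier: per-gene decision boundaries from
# the extreme training groups, a gate gene whose sub-boundary expression
# forces a Non-Responder call, an integer score over the secondary genes,
# cross-platform quantile renormalization, and confusion-matrix metrics.

#' Fit a Response-Average model
#'
#' For each model gene, the Response Average (RA) is the midpoint of the
#' RESPONDER and NON_RESPONDER group means (unweighted, so the boundary is
#' robust to class imbalance; `ra_method = "pooled"` gives the pooled mean
#' over all extreme samples instead). The pooled, sorted intensities of the
#' training matrix are retained as the reference distribution for
#' cross-platform normalization.
#'
#' @param em Training [expression_matrix()].
#' @param calls Response calls (`sample_id, response_class`) for the training
#'   samples.
#' @param gate_gene The gate gene (CD19 in the B-cell panel): expression at
#'   or below its RA forces a Non-Responder call.
#' @param secondary_genes The remaining signature genes, each contributing 1
#'   to the score when expressed above its RA.
#' @param score_threshold Minimum score (among gate-passing lines) for a
#'   Responder call.
#' @param ra_method `"midpoint"` (default) or `"pooled"`.
#' @return An object of class `ra_model`.
#' @export
fit_ra_model <- function(em, calls, gate_gene, secondary_genes,
                         score_threshold = 3, ra_method = c("midpoint", "pooled")) {
  ra_method <- match.arg(ra_method)
  validate_expression_matrix(em)
  if (gate_gene %in% secondary_genes) {
    stop("gate gene must not appear among the secondary genes", call. = FALSE)
  }
  model_genes <- c(gate_gene, secondary_genes)
  missing <- setdiff(model_genes, genes(em))
  if (length(missing)) {
    stop("model genes missing from the matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!(score_threshold > 0 && score_threshold <= length(secondary_genes) + 1)) {
    stop("score_threshold must be in 1..(number of secondary genes + 1)", call. = FALSE)
  }
  calls <- calls[calls$sample_id %in% samples(em), , drop = FALSE]
  resp <- calls$sample_id[calls$response_class == "RESPONDER"]
  nonr <- calls$sample_id[calls$response_class == "NON_RESPONDER"]
  if (!length(resp) || !length(nonr)) {
    stop("both extreme classes must be non-empty", call. = FALSE)
  }
  if (length(resp) < 2 || length(nonr) < 2) {
    warning("an extreme class has a single sample; Response Averages will be noisy")
  }
  v <- em$values[model_genes, , drop = FALSE]
  ra <- if (ra_method == "midpoint") {
    (rowMeans(v[, resp, drop = FALSE]) + rowMeans(v[, nonr, drop = FALSE])) / 2
  } else {
    rowMeans(v[, c(resp, nonr), drop = FALSE])
  }
  structure(list(
    gate_gene = gate_gene,
    secondary_genes = secondary_genes,
    ra = ra,
    score_threshold = as.integer(score_threshold),
    ra_method = ra_method,
    reference_distribution = sort(as.vector(em$values)),
    training_genes = genes(em),
    platform = em$platform,
    n_responders = length(resp),
    n_nonresponders = length(nonr)
  ), class = "ra_model")
}

#' @export
print.ra_model <- function(x, ...) {
  cat(sprintf("<ra_model> gate %s | %s; score threshold %d (%s RA); trained on %d+%d extremes, platform '%s'\n",
              x$gate_gene, paste(x$secondary_genes, collapse = ", "),
              x$score_threshold, x$ra_method,
              x$n_responders, x$n_nonresponders, x$platform))
  print(round(x$ra, 3))
  invisible(x)
}

#' Quantile-map incoming samples onto the training distribution
#'
#' Each incoming sample's values are replaced by the training reference
#' quantiles at the sample's own empirical probabilities (midrank plotting
#' positions, linear interpolation), which undoes any monotone cross-platform
#' distortion. Samples already on the training platform are passed through
#' unchanged.
#'
#' @param em Incoming [expression_matrix()].
#' @param model A fitted `ra_model`.
#' @return The normalized [expression_matrix()] (platform `"normalized"`), or
#'   `em` unchanged when platforms match.
#' @export
normalize_to_reference <- function(em, model) {
  validate_expression_matrix(em)
  if (identical(em$platform, model$platform)) return(em)
  if (nrow(em$values) < 2) {
    stop("cannot normalize a single-gene matrix: sample distribution undefined",
         call. = FALSE)
  }
  shared <- length(intersect(genes(em), model$training_genes)) /
    length(model$training_genes)
  if (shared < 0.10) {
    stop(sprintf("incoming genes overlap training universe by %.0f%% (< 10%%)",
                 100 * shared), call. = FALSE)
  }
  if (shared < 0.50) {
    warning(sprintf("incoming genes overlap training universe by only %.0f%%",
                    100 * shared))
  }
  ref <- model$reference_distribution
  nref <- length(ref)
  ref_probs <- (seq_len(nref) - 0.5) / nref
  v <- em$values
  ng <- nrow(v)
  probs <- (seq_len(ng) - 0.5) / ng
  for (j in seq_len(ncol(v))) {
    rk <- rank(v[, j], ties.method = "average")
    v[, j] <- stats::approx(ref_probs, ref, xout = (rk - 0.5) / ng, rule = 2)$y
  }
  expression_matrix(v, platform = "normalized")
}

#' Predict response with a Response-Average model
#'
#' Per sample: the gate passes iff the gate gene's expression strictly
#' exceeds its RA; a failed gate is immediately a Non-Responder (score
#' reported as 0). Otherwise the score counts secondary genes whose
#' expression strictly exceeds their RA, and the call is Responder iff the
#' score reaches the threshold. Equality with an RA never counts as
#' exceeding it.
#'
#' @param object A fitted `ra_model`.
#' @param newdata An [expression_matrix()] containing all model genes
#'   (normalize first with [normalize_to_reference()] if cross-platform).
#' @param ... Unused.
#' @return Data frame: `sample_id, gate_passed, score, predicted, rule_fired`
#'   with `predicted` in `{Responder, NonResponder}` and `rule_fired` in
#'   `{gate, score, pass}`.
#' @export
predict.ra_model <- function(object, newdata, ...) {
  validate_expression_matrix(newdata)
  model_genes <- c(object$gate_gene, object$secondary_genes)
  missing <- setdiff(model_genes, genes(newdata))
  if (length(missing)) {
    stop("model genes missing from the matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- newdata$values[model_genes, , drop = FALSE]
  gate_passed <- v[object$gate_gene, ] > object$ra[object$gate_gene]
  exceeds <- v[object$secondary_genes, , drop = FALSE] >
    object$ra[object$secondary_genes]
  score_raw <- colSums(exceeds)
  score <- ifelse(gate_passed, score_raw, 0L)
  predicted <- ifelse(gate_passed & score >= object$score_threshold,
                      "Responder", "NonResponder")
  rule <- ifelse(!gate_passed, "gate",
                 ifelse(predicted == "Responder", "pass", "score"))
  data.frame(sample_id = samples(newdata), gate_passed = unname(gate_passed),
             score = as.integer(unname(score)), predicted = unname(predicted),
             rule_fired = unname(rule), stringsAsFactors = FALSE)
}

#' Confusion-matrix metrics for binary response predictions
#'
#' Responder is the positive class. Ratios with zero denominators are
#' reported as `NA` (absent), never as 0.
#'
#' @param predictions Data frame from [predict.ra_model()] (`sample_id,
#'   predicted`).
#' @param truth Data frame with `sample_id` and a truth column `class` in
#'   `{Responder, NonResponder}` (e.g. derived from validation-mode
#'   [response_calls()]).
#' @return List: `tp, fp, tn, fn, sensitivity, specificity, accuracy`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  missing <- setdiff(predictions$sample_id, truth$sample_id)
  if (length(missing)) {
    stop("truth labels missing for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  t_class <- truth$class[match(predictions$sample_id, truth$sample_id)]
  p_class <- predictions$predicted
  tp <- sum(p_class == "Responder" & t_class == "Responder")
  fp <- sum(p_class == "Responder" & t_class == "NonResponder")
  tn <- sum(p_class == "NonResponder" & t_class == "NonResponder")
  fn <- sum(p_class == "NonResponder" & t_class == "Responder")
  safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = safe_ratio(tp, tp + fn),
       specificity = safe_ratio(tn, tn + fp),
       accuracy = safe_ratio(tp + tn, tp + fp + tn + fn))
}

#' Write a Response-Average model as plain text
#'
#' Key-value header followed by the sorted reference distribution; values are
#' serialized at full double precision so [read_ra_model()] round-trips
#' exactly.
#'
#' @param model An `ra_model`.
#' @param path Output path.
#' @export
write_ra_model <- function(model, path) {
  num <- function(x) formatC(x, digits = 17, format = "g")
  lines <- c(
    "# drsig ra_model v1",
    paste0("gate_gene\t", model$gate_gene),
    paste0("secondary_genes\t", paste(model$secondary_genes, collapse = ",")),
    paste0("score_threshold\t", model$score_threshold),
    paste0("ra_method\t", model$ra_method),
    paste0("platform\t", model$platform),
    paste0("n_responders\t", model$n_responders),
    paste0("n_nonresponders\t", model$n_nonresponders),
    paste0("ra\t", paste(names(model$ra), num(model$ra), sep = "=", collapse = ",")),
    paste0("training_genes\t", paste(model$training_genes, collapse = ",")),
    paste0("reference_distribution\t",
           paste(num(model$reference_distribution), collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a Response-Average model written by [write_ra_model()]
#'
#' @param path Model file path.
#' @return The `ra_model`.
#' @export
read_ra_model <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "# drsig ra_model v1") {
    stop("not a recognizable ra_model file: ", path, call. = FALSE)
  }
  kv <- strsplit(lines[-1], "\t", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  ra_pairs <- strsplit(strsplit(vals[["ra"]], ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  ra <- stats::setNames(as.numeric(vapply(ra_pairs, `[`, character(1), 2)),
                        vapply(ra_pairs, `[`, character(1), 1))
  structure(list(
    gate_gene = vals[["gate_gene"]],
    secondary_genes = strsplit(vals[["secondary_genes"]], ",", fixed = TRUE)[[1]],
    ra = ra,
    score_threshold = as.integer(vals[["score_threshold"]]),
    ra_method = vals[["ra_method"]],
    reference_distribution = as.numeric(
      strsplit(vals[["reference_distribution"]], ",", fixed = TRUE)[[1]]),
    training_genes = strsplit(vals[["training_genes"]], ",", fixed = TRUE)[[1]],
    platform = vals[["platform"]],
    n_responders = as.integer(vals[["n_responders"]]),
    n_nonresponders = as.integer(vals[["n_nonresponders"]])
  ), class = "ra_model")
}
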