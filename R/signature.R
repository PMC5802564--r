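# Signature selection: hypergeometric over-representation against gene-set
# catalogues, Mann-Whitney filtering between the extreme response groups,
# and four-group ANOVA with a monotone-trend annotation.

RESPONSE_LEVELS <- c("RESPONDER", "PARTIAL", "LIMITED", "NON_RESPONDER")

#' Hypergeometric over-representation of a gene list in gene sets
#'
#' For each set (intersected with the universe first), the upper-tail
#' hypergeometric probability of observing at least the seen overlap between
#' the set and the differential list, with Benjamini-Hochberg adjustment
#' across sets. Sets with no member in the universe are skipped with a
#' warning.
#'
#' @param diff_genes Character vector, the differential list (must lie within
#'   `universe`).
#' @param sets Named list of gene-symbol vectors (see [read_gmt()]).
#' @param universe Character vector, the tested gene universe.
#' @return Data frame sorted by p: `set, overlap, set_size, list_size,
#'   universe_size, p, p_adjusted`.
#' @export
overrepresentation <- function(diff_genes, sets, universe) {
  universe <- unique(universe)
  diff_genes <- unique(diff_genes)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(diff_genes)) stop("empty differential gene list", call. = FALSE)
  stray <- setdiff(diff_genes, universe)
  if (length(stray)) {
    stop("differential genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(diff_genes)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    if (!length(set)) {
      warning("gene set '", nm, "' has no member in the universe; skipped")
      return(NULL)
    }
    K <- length(set)
    x <- length(intersect(set, diff_genes))
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = x, set_size = K, list_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no gene set overlaps the universe", call. = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from rank sums with midranks for ties (U for the first
#' group). The p-value is exact — by enumeration of all group-membership
#' assignments of the pooled values — when both groups have at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie-corrected variance and a continuity correction is used. The
#' two-sided exact p counts assignments whose U is at least as far from the
#' null mean `n_a n_b / 2` as observed.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return List: `u` (first group), `p`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (length(unique(pooled)) == 1) {
    warning("all values identical across both groups")
    return(list(u = u, p = 1, method = "degenerate"))
  }
  ties <- any(duplicated(pooled))
  if (na <= 8 && nb <= 8 && !ties) {
    combos <- utils::combn(na + nb, na)
    srt <- sort(rk)  # = 1..N, no ties
    us <- colSums(matrix(srt[combos], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    return(list(u = u, p = p, method = "exact"))
  }
  N <- na + nb
  tab <- table(pooled)
  tie_term <- sum(tab^3 - tab) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  z <- (max(0, abs(u - mu) - 0.5)) / sqrt(sigma2)
  list(u = u, p = min(1, 2 * stats::pnorm(-z)), method = "normal")
}

#' One-way ANOVA across response groups with a monotone-trend annotation
#'
#' Fixed-effects one-way ANOVA (via `anova(lm(...))`) over the supplied
#' groups, plus a check that group means are non-increasing along the
#' resistance ordering RESPONDER >= PARTIAL >= LIMITED >= NON_RESPONDER
#' (weak inequality: ties are consistent with the trend). The trend is only
#' defined (`NA` otherwise) when all four groups are present.
#'
#' @param values Numeric vector of expression values.
#' @param groups Character/factor of response classes, same length.
#' @return List: `f`, `p`, `means` (named, in resistance order; `NA` for
#'   absent groups), `monotone_trend`.
#' @export
four_group_anova <- function(values, groups) {
  groups <- as.character(groups)
  keep <- groups %in% RESPONSE_LEVELS
  values <- values[keep]
  groups <- groups[keep]
  counts <- table(factor(groups, levels = RESPONSE_LEVELS))
  usable <- sum(counts >= 2)
  if (usable < 2) {
    stop("need at least 2 groups with at least 2 samples each", call. = FALSE)
  }
  g <- factor(groups, levels = RESPONSE_LEVELS[counts > 0])
  means_all <- tapply(values, factor(groups, levels = RESPONSE_LEVELS), mean)
  if (stats::var(values) == 0) {
    f <- 0
    p <- 1
  } else {
    tab <- stats::anova(stats::lm(values ~ g))
    f <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
  }
  trend <- if (all(counts > 0)) {
    all(diff(unname(means_all)) <= 1e-12)
  } else {
    NA
  }
  list(f = f, p = p, means = means_all, monotone_trend = trend)
}

#' Select a pathway-anchored response signature
#'
#' Candidates are the SAM-called genes that belong to the pathway set. Each
#' candidate is tested by [mann_whitney()] between the extreme groups
#' (RESPONDER vs NON_RESPONDER samples only); genes with `p < alpha` survive
#' and are ranked by ascending p, ties broken toward larger absolute log
#' fold. Each survivor is annotated with the four-group ANOVA and the
#' monotone-trend flag across all classified lines.
#'
#' @param sam_table SAM result table (`gene_id, d, log_fold, called`).
#' @param pathway_genes Character vector, the anchoring gene set.
#' @param em The [expression_matrix()] used for SAM.
#' @param calls Response-call data frame from [response_calls()]
#'   (`sample_id, response_class`).
#' @param alpha Mann-Whitney significance cutoff.
#' @return Data frame ordered by rank: `rank, gene_id, mw_u, mw_p, log_fold,
#'   mean_RESPONDER, mean_PARTIAL, mean_LIMITED, mean_NON_RESPONDER, anova_f,
#'   anova_p, monotone_trend`. Empty (with a warning) when no called gene
#'   lies in the pathway.
#' @export
select_signature <- function(sam_table, pathway_genes, em, calls, alpha = 0.05) {
  validate_expression_matrix(em)
  candidates <- intersect(sam_table$gene_id[sam_table$called], pathway_genes)
  empty <- data.frame(rank = integer(), gene_id = character(), mw_u = numeric(),
                      mw_p = numeric(), log_fold = numeric(),
                      mean_RESPONDER = numeric(), mean_PARTIAL = numeric(),
                      mean_LIMITED = numeric(), mean_NON_RESPONDER = numeric(),
                      anova_f = numeric(), anova_p = numeric(),
                      monotone_trend = logical(), stringsAsFactors = FALSE)
  if (!length(candidates)) {
    warning("no SAM-called gene lies in the pathway set; empty signature")
    return(empty)
  }
  calls <- calls[calls$sample_id %in% samples(em), , drop = FALSE]
  resp <- calls$sample_id[calls$response_class == "RESPONDER"]
  nonr <- calls$sample_id[calls$response_class == "NON_RESPONDER"]
  if (!length(resp) || !length(nonr)) {
    stop("need at least one RESPONDER and one NON_RESPONDER sample", call. = FALSE)
  }
  graded <- calls[calls$response_class %in% RESPONSE_LEVELS, , drop = FALSE]

  lf <- stats::setNames(sam_table$log_fold, sam_table$gene_id)
  rows <- lapply(candidates, function(gid) {
    x <- em$values[gid, ]
    mw <- mann_whitney(x[resp], x[nonr])
    av <- four_group_anova(x[graded$sample_id], graded$response_class)
    data.frame(gene_id = gid, mw_u = mw$u, mw_p = mw$p, log_fold = unname(lf[gid]),
               mean_RESPONDER = unname(av$means["RESPONDER"]),
               mean_PARTIAL = unname(av$means["PARTIAL"]),
               mean_LIMITED = unname(av$means["LIMITED"]),
               mean_NON_RESPONDER = unname(av$means["NON_RESPONDER"]),
               anova_f = av$f, anova_p = av$p, monotone_trend = av$monotone_trend,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$mw_p < alpha, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(out$mw_p, -abs(out$log_fold), out$gene_id), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
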