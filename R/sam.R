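# Two-class unpaired Significance Analysis of Microarrays: relative
# difference d = r / (s + s0), fudge-factor selection, permutation null via
# expected order statistics, delta thresholding and FDR estimation.

# Per-gene numerator r (difference of class means, class 1 minus class 2)
# and pooled standard error s. labels: logical/2-level factor; TRUE / first
# level = class 1. Returns list(r, s, m1, m2).
sam_rs <- function(values, in1) {
  n1 <- sum(in1)
  n2 <- sum(!in1)
  x1 <- values[, in1, drop = FALSE]
  x2 <- values[, !in1, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(r = m1 - m2, s = s, m1 = m1, m2 = m2)
}

as_class1_indicator <- function(labels, n) {
  if (is.logical(labels)) {
    if (length(labels) != n) stop("labels length mismatch", call. = FALSE)
    return(labels)
  }
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two classes", call. = FALSE)
  if (length(f) != n) stop("labels length mismatch", call. = FALSE)
  f == levels(f)[1]
}

#' Per-gene SAM relative-difference statistics
#'
#' For gene `i` with class means `m1, m2` and pooled standard error
#' `s_i = sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))`, the statistic is
#' `d_i = (m1 - m2) / (s_i + s0)`. Class 1 is the first factor level (or
#' `TRUE`); by convention callers put the responder arm first so positive `d`
#' means higher expression in responders.
#'
#' @param em An [expression_matrix()] (log2 scale).
#' @param labels Two-class assignment over samples: a 2-level factor or a
#'   logical vector (`TRUE` = class 1).
#' @param s0 Fudge factor; when `NULL`, chosen by [choose_s0()].
#' @return Data frame: `gene_id, r, s, d, log_fold` (with `log_fold = r`, the
#'   log2 mean difference), plus attribute `s0`.
#' @export
sam_statistics <- function(em, labels, s0 = NULL) {
  validate_expression_matrix(em)
  in1 <- as_class1_indicator(labels, ncol(em$values))
  if (sum(in1) < 2 || sum(!in1) < 2) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  rs <- sam_rs(em$values, in1)
  if (is.null(s0)) s0 <- choose_s0(rs$r, rs$s)
  if (any(rs$s + s0 == 0)) {
    stop("zero-variance gene with s0 = 0: d is undefined; supply s0 > 0",
         call. = FALSE)
  }
  out <- data.frame(gene_id = genes(em), r = rs$r, s = rs$s,
                    d = rs$r / (rs$s + s0), log_fold = rs$r,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "s0") <- s0
  out
}

#' Choose the SAM fudge factor
#'
#' Standard rule: candidate values are the percentiles 0, 5, ..., 100 of the
#' per-gene standard errors; for each candidate, genes are binned into 100
#' quantile windows of `s`, the median absolute deviation of `d` is taken in
#' each window, and the candidate minimizing the coefficient of variation of
#' those window MADs is chosen (ties toward the smaller value).
#'
#' @param r Per-gene numerators.
#' @param s Per-gene pooled standard errors.
#' @param n_windows Number of quantile windows (capped by the gene count).
#' @return The chosen `s0`.
#' @export
choose_s0 <- function(r, s, n_windows = 100) {
  n <- length(s)
  if (n < 100) warning("fewer than 100 genes; fudge-factor selection is unstable")
  if (max(s) - min(s) < .Machine$double.eps * max(1, max(s))) {
    warning("all standard errors identical; s0 = 0 (any s0 gives the same ordering)")
    return(0)
  }
  cand <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE))
  nw <- max(2L, min(n_windows, floor(n / 2)))
  breaks <- unique(stats::quantile(s, probs = seq(0, 1, length.out = nw + 1),
                                   names = FALSE))
  win <- cut(s, breaks = breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(a) {
    d <- r / (s + a)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[is.finite(mads)]
    if (length(mads) < 2 || mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  cand[which.min(cv)]  # which.min takes the first (= smallest candidate) on ties
}

# All distinct assignments of n1 class-1 slots among n samples, as a logical
# matrix (n x n_assignments), or a seeded uniform sample of `size` of them.
permutation_indicators <- function(n, n1, size, seed) {
  total <- choose(n, n1)
  if (total <= size) {
    sets <- utils::combn(n, n1)
    ind <- matrix(FALSE, n, ncol(sets))
    for (j in seq_len(ncol(sets))) ind[sets[, j], j] <- TRUE
    ind
  } else {
    with_stream(seed, "sam", {
      ind <- matrix(FALSE, n, size)
      for (j in seq_len(size)) ind[sample.int(n, n1), j] <- TRUE
      ind
    })
  }
}

#' Run SAM: permutation null, delta selection, calling and q-values
#'
#' Builds the permutation null of the sorted statistics (all distinct label
#' shuffles when their count is within `n_permutations`, otherwise a seeded
#' uniform sample), forms expected order statistics `dbar_(i)`, and scans a
#' delta grid. At each delta, the cut-up (cut-down) threshold is the observed
#' `d_(i)` at the first point above (below) the origin where
#' `|d_(i) - dbar_(i)|` exceeds delta; all genes beyond the cuts are called.
#' The estimated FDR at delta is the median permutation count of statistics
#' beyond the cuts divided by the number called (pi0 fixed at 1,
#' conservative). The run's delta is the smallest grid value achieving
#' `fdr_target`; per-gene q-values are the smallest estimated FDR among grid
#' thresholds calling the gene.
#'
#' @param em An [expression_matrix()].
#' @param labels Two-class assignment (class 1 = responder arm by convention).
#' @param fdr_target Target false discovery rate, in (0, 1).
#' @param n_permutations Permutation budget (exhaustive when the distinct
#'   shuffle count is within it).
#' @param seed Integer seed for permutation sampling.
#' @param s0 Optional fudge factor; default chosen from the observed data and
#'   held fixed across permutations.
#' @param grid_size Delta-grid resolution.
#' @return A list of class `sam_run`: `table` (data frame `gene_id, d,
#'   log_fold, q_value, called`), `s0`, `delta`, `fdr_at_delta`, `cut_up`,
#'   `cut_down`, `n_called`, `n_permutations_used`, `exhaustive`,
#'   `d_sorted`, `dbar`, `fdr_target`, `seed`, `min_achievable_fdr`.
#' @export
sam_call <- function(em, labels, fdr_target = 0.10, n_permutations = 1000,
                     seed = 1, s0 = NULL, grid_size = 200) {
  if (!(fdr_target > 0 && fdr_target < 1)) stop("fdr_target must be in (0,1)", call. = FALSE)
  obs <- sam_statistics(em, labels, s0 = s0)
  s0 <- attr(obs, "s0")
  in1 <- as_class1_indicator(labels, ncol(em$values))
  n <- length(in1)
  n1 <- sum(in1)

  ind <- permutation_indicators(n, n1, n_permutations, seed)
  B <- ncol(ind)
  ng <- nrow(em$values)
  perm_sorted <- matrix(NA_real_, ng, B)
  for (b in seq_len(B)) {
    rs <- sam_rs(em$values, ind[, b])
    perm_sorted[, b] <- sort(rs$r / (rs$s + s0))
  }
  dbar <- rowMeans(perm_sorted)

  ord <- order(obs$d)
  d_sorted <- obs$d[ord]
  diff <- d_sorted - dbar
  origin <- which(dbar >= 0)[1]
  if (is.na(origin)) origin <- ng  # all-negative null mean: degenerate but safe

  grid <- seq(0, max(abs(diff)), length.out = grid_size)
  # For each delta: first crossing above / below the origin.
  eval_delta <- function(delta) {
    up_idx <- which(seq_len(ng) >= origin & diff > delta)
    cut_up <- if (length(up_idx)) d_sorted[min(up_idx)] else Inf
    dn_idx <- which(seq_len(ng) < origin & -diff > delta)
    cut_dn <- if (length(dn_idx)) d_sorted[max(dn_idx)] else -Inf
    called <- obs$d >= cut_up | obs$d <= cut_dn
    n_called <- sum(called)
    false_counts <- colSums(perm_sorted >= cut_up) + colSums(perm_sorted <= cut_dn)
    fdr <- stats::median(false_counts) / max(1, n_called)
    list(cut_up = cut_up, cut_dn = cut_dn, called = called,
         n_called = n_called, fdr = min(1, fdr))
  }
  scans <- lapply(grid, eval_delta)
  fdrs <- vapply(scans, `[[`, numeric(1), "fdr")
  ncalls <- vapply(scans, `[[`, numeric(1), "n_called")

  ok <- which(fdrs <= fdr_target & ncalls > 0)
  if (length(ok)) {
    pick <- min(ok)
  } else {
    # no delta achieves the target with any calls: empty call set, report the
    # grid's minimum achieved FDR
    pick <- NA_integer_
  }

  q <- rep(NA_real_, ng)
  for (j in seq_along(grid)) {
    cj <- scans[[j]]$called
    q[cj] <- pmin(q[cj], fdrs[j], na.rm = TRUE)
  }
  q[is.na(q)] <- 1

  if (is.na(pick)) {
    called <- rep(FALSE, ng)
    delta <- NA_real_
    fdr_at <- NA_real_
    cut_up <- Inf
    cut_dn <- -Inf
  } else {
    sel <- scans[[pick]]
    called <- sel$called
    delta <- grid[pick]
    fdr_at <- sel$fdr
    cut_up <- sel$cut_up
    cut_dn <- sel$cut_dn
  }

  table <- data.frame(gene_id = obs$gene_id, d = obs$d, log_fold = obs$log_fold,
                      q_value = q, called = called, stringsAsFactors = FALSE)
  structure(list(
    table = table, s0 = s0, delta = delta, fdr_at_delta = fdr_at,
    cut_up = cut_up, cut_down = cut_dn, n_called = sum(called),
    n_permutations_used = B, exhaustive = B == choose(n, n1),
    d_sorted = d_sorted, dbar = dbar, fdr_target = fdr_target, seed = seed,
    min_achievable_fdr = min(fdrs[ncalls > 0], Inf)
  ), class = "sam_run")
}

#' @export
print.sam_run <- function(x, ...) {
  cat(sprintf(
    "<sam_run> %d genes, s0 = %.4g, delta = %s, %d called (est. FDR %s), %d permutations%s\n",
    nrow(x$table), x$s0,
    if (is.na(x$delta)) "none" else sprintf("%.4g", x$delta),
    x$n_called,
    if (is.na(x$fdr_at_delta)) "-" else sprintf("%.3f", x$fdr_at_delta),
    x$n_permutations_used, if (x$exhaustive) " (exhaustive)" else ""))
  invisible(x)
}

#' SAM diagnostic plot
#'
#' Observed versus expected (permutation-mean) order statistics with the
#' identity line and the delta band; called genes are highlighted.
#'
#' @param run A `sam_run`.
#' @param path Output image path (PNG).
#' @return `path`, invisibly.
#' @export
sam_plot <- function(run, path) {
  grDevices::png(path, width = 700, height = 700)
  on.exit(grDevices::dev.off())
  called_sorted <- sort(run$table$d) %in% run$table$d[run$table$called]
  graphics::plot(run$dbar, run$d_sorted,
                 xlab = "expected order statistic", ylab = "observed d",
                 pch = 20, col = ifelse(called_sorted, "firebrick", "grey40"),
                 main = sprintf("SAM: %d called at est. FDR %s", run$n_called,
                                if (is.na(run$fdr_at_delta)) "-"
                                else sprintf("%.2f", run$fdr_at_delta)))
  graphics::abline(0, 1)
  if (!is.na(run$delta)) {
    graphics::abline(run$delta, 1, lty = 2)
    graphics::abline(-run$delta, 1, lty = 2)
  }
  invisible(path)
}
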