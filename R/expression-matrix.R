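#' Construct an expression matrix
#'
#' The substrate of every statistic in the package: a dense genes x samples
#' matrix of log2 fluorescence intensities with a platform tag. Gene and
#' sample identifiers must be unique and all values finite.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must carry
#'   rownames (gene symbols) and colnames (cell-line names).
#' @param platform Free-text platform label, e.g. `"synthetic-A"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `platform`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("CD19", "BTK", "PAX5"), c("s1", "s2")))
#' em <- expression_matrix(m, platform = "demo")
#' dim(em)
#' @export
expression_matrix <- function(values, platform = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (genes) and colnames (samples)", call. = FALSE)
  }
  em <- structure(
    list(values = values, platform = as.character(platform)[1]),
    class = "expr_matrix"
  )
  validate_expression_matrix(em)
  em
}

#' Validate an expression matrix
#'
#' Enforces the type invariants: unique gene and sample ids, finite values,
#' dimensions consistent with the id lists.
#'
#' @param em An `expr_matrix`.
#' @return `em`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  v <- em$values
  g <- rownames(v)
  s <- colnames(v)
  if (anyDuplicated(g)) {
    stop("duplicate gene ids: ", paste(unique(g[duplicated(g)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(s)) {
    stop("duplicate sample ids: ", paste(unique(s[duplicated(s)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 g[bad[1]], s[bad[2]]), call. = FALSE)
  }
  invisible(em)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param em An `expr_matrix`.
#' @return Character vector of ids.
#' @export
genes <- function(em) rownames(em$values)

#' @rdname genes
#' @export
samples <- function(em) colnames(em$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, platform '%s'\n",
              nrow(x$values), ncol(x$values), x$platform))
  invisible(x)
}

#' Subset an expression matrix
#'
#' Row/column subsetting by gene and sample id (or index), preserving the
#' platform tag.
#'
#' @param em An `expr_matrix`.
#' @param genes,samples Ids or indices; `NULL` keeps all.
#' @return The subset `expr_matrix`.
#' @export
subset_expression <- function(em, genes = NULL, samples = NULL) {
  v <- em$values
  if (!is.null(genes)) {
    if (is.character(genes)) {
      missing <- setdiff(genes, rownames(v))
      if (length(missing)) {
        stop("genes not present: ", paste(missing, collapse = ", "), call. = FALSE)
      }
    }
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) {
      missing <- setdiff(samples, colnames(v))
      if (length(missing)) {
        stop("samples not present: ", paste(missing, collapse = ", "), call. = FALSE)
      }
    }
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, em$platform)
}
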