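# Readers and writers for the three tabular interchange formats:
# expression (TSV / GCT 1.2), dose-response CSV, gene sets (GMT).

#' Read a gene x sample expression matrix
#'
#' TSV dialect: a header row of sample ids, first column gene symbols.
#' GCT dialect: the standard 1.2 layout (`#1.2` line, a dimension line, then a
#' header with `Name`/`Description` columns). Duplicate gene rows are
#' collapsed by the per-sample maximum, the usual probe-to-gene convention
#' when probe identity has been discarded.
#'
#' @param path File path.
#' @param fmt `"tsv"` or `"gct"`.
#' @param platform Platform label to attach.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, fmt = c("tsv", "gct"), platform = "unspecified") {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (fmt == "gct") {
    if (length(lines) < 3 || !startsWith(lines[1], "#1.2")) {
      stop("malformed GCT header: expected '#1.2' on line 1, got '",
           if (length(lines)) lines[1] else "", "'", call. = FALSE)
    }
    dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]]))
    if (length(dims) < 2 || anyNA(dims[1:2])) {
      stop("malformed GCT dimension line (line 2): '", lines[2], "'", call. = FALSE)
    }
    body <- lines[-(1:2)]
    tab <- parse_delim_matrix(body, sep = "\t", drop_cols = 2, what = path)
    if (nrow(tab$values) != dims[1]) {
      stop(sprintf("GCT dimension line declares %d rows but %d data rows found",
                   dims[1], nrow(tab$values)), call. = FALSE)
    }
  } else {
    tab <- parse_delim_matrix(lines, sep = "\t", drop_cols = 1, what = path)
  }
  values <- collapse_duplicate_genes(tab$values)
  expression_matrix(values, platform)
}

# Parse header + data lines into a named numeric matrix. drop_cols is the
# number of leading label columns (1 for TSV, 2 for GCT Name/Description).
parse_delim_matrix <- function(lines, sep, drop_cols, what) {
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("no data rows in ", what, call. = FALSE)
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  sample_ids <- header[-seq_len(drop_cols)]
  if (length(sample_ids) < 1) {
    stop("malformed header (no sample columns): '", lines[1], "'", call. = FALSE)
  }
  rows <- strsplit(lines[-1], sep, fixed = TRUE)
  n_fields <- drop_cols + length(sample_ids)
  values <- matrix(NA_real_, length(rows), length(sample_ids))
  gene_ids <- character(length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != n_fields) {
      stop(sprintf("line %d has %d fields, expected %d", i + 1L, length(f), n_fields),
           call. = FALSE)
    }
    gene_ids[i] <- f[1]
    x <- suppressWarnings(as.numeric(f[-seq_len(drop_cols)]))
    if (anyNA(x)) {
      j <- which(is.na(x))[1]
      stop(sprintf("non-numeric value '%s' at data row %d, sample column %d",
                   f[drop_cols + j], i, j), call. = FALSE)
    }
    values[i, ] <- x
  }
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  list(values = values)
}

# Collapse duplicate gene symbols by the per-sample maximum. Idempotent and
# independent of row order.
collapse_duplicate_genes <- function(values) {
  g <- rownames(values)
  if (!anyDuplicated(g)) return(values)
  keep <- unique(g)
  out <- matrix(NA_real_, length(keep), ncol(values),
                dimnames = list(keep, colnames(values)))
  for (gene in keep) {
    rows <- values[g == gene, , drop = FALSE]
    out[gene, ] <- apply(rows, 2, max)
  }
  out
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: `read_expression(write_expression(m))`
#' reproduces `m` to full double precision (values serialized with 17
#' significant digits).
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @param fmt `"tsv"` or `"gct"`.
#' @export
write_expression <- function(em, path, fmt = c("tsv", "gct")) {
  fmt <- match.arg(fmt)
  validate_expression_matrix(em)
  if (ncol(em$values) == 0) stop("refusing to write a matrix with no samples", call. = FALSE)
  if (nrow(em$values) == 0) stop("refusing to write a matrix with no genes", call. = FALSE)
  v <- em$values
  num <- apply(v, 2, function(col) formatC(col, digits = 17, format = "g"))
  num <- matrix(num, nrow = nrow(v))
  body <- apply(cbind(rownames(v), if (fmt == "gct") "na" else NULL, num), 1,
                paste, collapse = "\t")
  if (fmt == "gct") {
    lines <- c("#1.2",
               paste(nrow(v), ncol(v), sep = "\t"),
               paste(c("Name", "Description", colnames(v)), collapse = "\t"),
               body)
  } else {
    lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"), body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-well dose-response table
#'
#' CSV with columns `sample_id, drug_id, dose_uM, viability`. Viability is a
#' fraction of untreated control; values somewhat above 1 are measurement
#' noise and are kept. A column whose values run above 2 is interpreted as
#' percent and divided by 100 with a warning (exports vary; genuine fractional
#' noise stays below ~1.3, so 2 is unambiguous).
#'
#' @param path CSV path.
#' @return A `data.frame` with the four columns plus `max_conc`, the largest
#'   dose within each (sample, drug) series.
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "drug_id", "dose_uM", "viability")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("dose-response table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  if (any(df$viability > 2)) {
    warning("viability column looks like percent (values > 2); dividing by 100")
    df$viability <- df$viability / 100
  }
  validate_dose_response(df)
  key <- paste(df$sample_id, df$drug_id, sep = "\r")
  df$max_conc <- stats::ave(df$dose_uM, key, FUN = max)
  df
}

#' Validate a dose-response table
#'
#' Doses strictly positive and distinct within each (sample, drug) series;
#' viability non-negative.
#'
#' @param df Data frame with `sample_id, drug_id, dose_uM, viability`.
#' @return `df`, invisibly.
#' @export
validate_dose_response <- function(df) {
  bad_dose <- which(!is.finite(df$dose_uM) | df$dose_uM <= 0)
  if (length(bad_dose)) {
    stop("non-positive or non-finite dose at rows: ",
         paste(utils::head(bad_dose, 10), collapse = ", "), call. = FALSE)
  }
  bad_v <- which(!is.finite(df$viability) | df$viability < 0)
  if (length(bad_v)) {
    stop("negative or non-finite viability at rows: ",
         paste(utils::head(bad_v, 10), collapse = ", "), call. = FALSE)
  }
  key <- paste(df$sample_id, df$drug_id, df$dose_uM, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate (sample, drug, dose) row: %s / %s / %g",
                 d$sample_id, d$drug_id, d$dose_uM), call. = FALSE)
  }
  invisible(df)
}

#' Write a dose-response table
#'
#' @param df Data frame as returned by [read_dose_response()] or the
#'   simulator; only the four canonical columns are written.
#' @param path Output CSV path.
#' @export
write_dose_response <- function(df, path) {
  utils::write.csv(df[c("sample_id", "drug_id", "dose_uM", "viability")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB gene...`.
#'
#' @param path GMT path.
#' @return A named list of character vectors of gene symbols, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT line %d has %d fields; need name, description and >= 1 gene",
                   i, length(f)), call. = FALSE)
    }
    name <- f[1]
    if (name %in% names(sets)) {
      stop("duplicate gene-set name '", name, "' at line ", i, call. = FALSE)
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set '", name, "' at line ", i, call. = FALSE)
    sets[[name]] <- members
    descs[name] <- f[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Path to the bundled B-cell-receptor pathway gene sets
#'
#' A small GMT shipping with the package: a BCR-pathway member list (including
#' CD19, EBF1, PAX5, BTK and BLNK) plus a T-cell-receptor decoy set, used as
#' the over-representation catalogue for synthetic cohorts.
#'
#' @return File path.
#' @export
bundled_gmt <- function() {
  system.file("extdata", "bcr_pathway.gmt", package = "drsig", mustWork = TRUE)
}
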