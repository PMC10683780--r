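#' Read a genes-by-samples expression matrix
#'
#' Expects delimited text (tab or comma, sniffed from the header) with gene
#' symbols in the first column and one column per sample, on a
#' log2(TPM + 1)-like scale. An optional annotation sidecar supplies a
#' cancer-type label per sample.
#'
#' @param path Path to the expression table.
#' @param annotation_path Optional path to a two-column delimited file with
#'   header `sample_id`, `cancer_type`.
#' @return Numeric matrix (genes x samples) with a named `cancer_type`
#'   attribute when annotations are supplied.
#' @export
read_expression <- function(path, annotation_path = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path,
    header = TRUE, sep = sep, quote = "\"",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicated gene symbols in expression table: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (!is.null(annotation_path)) {
    ah <- readLines(annotation_path, n = 1L)
    asep <- if (grepl("\t", ah)) "\t" else ","
    ann <- utils::read.table(annotation_path,
      header = TRUE, sep = asep,
      stringsAsFactors = FALSE
    )
    ct <- stats::setNames(as.character(ann$cancer_type), ann$sample_id)
    attr(m, "cancer_type") <- ct[colnames(m)]
    names(attr(m, "cancer_type")) <- colnames(m)
  }
  m
}

#' Read a DepMap-layout gene-effect CSV
#'
#' DepMap CRISPR gene-effect files have cell lines as rows and gene columns
#' headed `"SYMBOL (EntrezID)"`. This parses the headers down to bare
#' symbols and transposes to the package's genes-by-cell-lines layout
#' (CHRONOS-like scores; more negative = more sensitive).
#'
#' @param path Path to the CSV.
#' @param plain_symbols If `TRUE`, columns that are already bare symbols
#'   (no Entrez suffix) are accepted as-is instead of raising an error.
#' @return Numeric matrix (genes x cell lines).
#' @export
read_depmap_gene_effect <- function(path, plain_symbols = FALSE) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lines <- as.character(tab[[1]])
  cols <- names(tab)[-1]
  m <- regmatches(cols, regexec("^(\\S+) \\((\\d+)\\)$", cols))
  symbols <- vapply(seq_along(cols), function(i) {
    if (length(m[[i]]) == 3) {
      m[[i]][2]
    } else if (plain_symbols && !grepl("[ ()]", cols[i])) {
      cols[i]
    } else {
      NA_character_
    }
  }, character(1))
  if (anyNA(symbols)) {
    stop("gene-effect header(s) not matching 'SYMBOL (EntrezID)' at column index ",
         paste(which(is.na(symbols)) + 1L, collapse = ", "))
  }
  if (anyDuplicated(symbols)) {
    stop("gene-effect columns parse to duplicated symbol(s): ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  out <- t(vals)
  rownames(out) <- symbols
  colnames(out) <- lines
  out
}

#' Drop zero-inflated genes
#'
#' Removes genes whose fraction of zero entries strictly exceeds
#' `max_zero_fraction` (default 0.20, i.e. genes with > 20% zeros across
#' samples are dropped).
#'
#' @param expr Genes-by-samples numeric matrix.
#' @param max_zero_fraction Threshold in \[0, 1\].
#' @return The filtered matrix; errors if no gene survives.
#' @export
filter_zero_genes <- function(expr, max_zero_fraction = 0.20) {
  stopifnot(is.matrix(expr), max_zero_fraction >= 0, max_zero_fraction <= 1)
  zf <- rowMeans(expr == 0)
  drop <- zf > max_zero_fraction
  if (all(drop)) {
    stop("all genes exceed the zero-fraction threshold")
  }
  if (any(drop)) {
    message(sum(drop), " gene(s) dropped with zero fraction > ", max_zero_fraction)
  }
  keep_attrs(expr[!drop, , drop = FALSE], expr)
}

#' Half-zero filter and k-nearest-neighbour imputation
#'
#' The preprocessing used for bulk tumour cohorts before sign inference:
#' genes with zeros in more than half of the samples are removed; the
#' remaining zero entries are treated as missing and replaced by the mean
#' of the k nearest genes (rows) under Euclidean distance computed over
#' mutually observed samples (per-coordinate scaled, so rows with
#' different overlap are comparable). Observed entries are never altered.
#'
#' @param expr Genes-by-samples numeric matrix; zeros are treated as
#'   missing for retained genes.
#' @param k Neighbour count (default 10). If fewer than `k` candidate rows
#'   are observed at a missing cell, the gene's own row mean is used with a
#'   warning.
#' @return The filtered, fully imputed matrix.
#' @export
half_zero_filter_and_knn_impute <- function(expr, k = 10) {
  stopifnot(is.matrix(expr), k >= 1)
  zf <- rowMeans(expr == 0)
  drop <- zf > 0.5
  if (any(drop)) {
    message(sum(drop), " gene(s) dropped with zeros in more than half the samples")
  }
  x <- expr[!drop, , drop = FALSE]
  miss <- x == 0
  if (!any(miss)) {
    return(keep_attrs(x, expr))
  }
  xm <- x
  xm[miss] <- NA_real_
  fell_back <- FALSE
  for (i in which(rowSums(miss) > 0)) {
    mi <- which(miss[i, ])
    shared_ok <- !is.na(xm[i, ])
    for (j in mi) {
      candidates <- which(!miss[, j] & seq_len(nrow(x)) != i)
      if (length(candidates) < k) {
        x[i, j] <- mean(xm[i, ], na.rm = TRUE)
        fell_back <- TRUE
        next
      }
      d <- vapply(candidates, function(cc) {
        both <- shared_ok & !miss[cc, ]
        if (!any(both)) {
          return(Inf)
        }
        sqrt(mean((xm[i, both] - x[cc, both])^2))
      }, numeric(1))
      nn <- candidates[order(d)[seq_len(k)]]
      x[i, j] <- mean(x[nn, j])
    }
  }
  if (fell_back) {
    warning("fewer than k observed candidate rows for some cells; row-mean imputation used")
  }
  keep_attrs(x, expr)
}

#' Align expression and sensitivity matrices
#'
#' Restricts both matrices to the intersection of their sample/cell-line
#' identifiers and gene symbols, in identical (lexicographic) order. The
#' operation is idempotent.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param sens Genes-by-cell-lines sensitivity matrix.
#' @return A list with elements `expression` and `sensitivity`.
#' @export
align_datasets <- function(expr, sens) {
  stopifnot(is.matrix(expr), is.matrix(sens), nrow(expr) > 0, nrow(sens) > 0)
  genes <- sort(intersect(rownames(expr), rownames(sens)))
  samples <- sort(intersect(colnames(expr), colnames(sens)))
  if (length(genes) == 0) {
    stop(sprintf(
      "no shared genes between expression (%d) and sensitivity (%d)",
      nrow(expr), nrow(sens)
    ))
  }
  if (length(samples) == 0) {
    stop(sprintf(
      "no shared samples between expression (%d) and sensitivity (%d)",
      ncol(expr), ncol(sens)
    ))
  }
  e <- expr[genes, samples, drop = FALSE]
  ct <- attr(expr, "cancer_type")
  if (!is.null(ct)) {
    attr(e, "cancer_type") <- ct[samples]
  }
  list(
    expression = e,
    sensitivity = sens[genes, samples, drop = FALSE]
  )
}

# carry the sample annotation attribute across row-subsetting operations
keep_attrs <- function(new, old) {
  ct <- attr(old, "cancer_type")
  if (!is.null(ct)) {
    attr(new, "cancer_type") <- ct
  }
  new
}
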