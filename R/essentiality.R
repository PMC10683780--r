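#' Binarize gene-effect scores into essentiality calls
#'
#' A gene is called essential in a cell line when its CHRONOS-like
#' gene-effect score is strictly below the threshold (default -0.6, the
#' conventional cutoff for a substantial growth defect on knockout).
#' Missing scores propagate to missing calls.
#'
#' @param sens Genes-by-cell-lines numeric matrix of gene-effect scores
#'   (more negative = more sensitive).
#' @param threshold Finite score cutoff; default -0.6.
#' @return An `essentiality_calls` object: logical genes x cell-lines
#'   matrix with per-gene essential / non-essential counts and the
#'   threshold as attributes.
#' @export
binarize_essentiality <- function(sens, threshold = -0.6) {
  stopifnot(is.matrix(sens), is.finite(threshold))
  calls <- sens < threshold
  structure(calls,
    class = c("essentiality_calls", "matrix"),
    threshold = threshold,
    n_essential = rowSums(calls, na.rm = TRUE),
    n_nonessential = rowSums(!calls, na.rm = TRUE)
  )
}

#' @export
print.essentiality_calls <- function(x, ...) {
  cat(sprintf(
    "<essentiality_calls> %d genes x %d cell lines | threshold: %s\n",
    nrow(x), ncol(x), format(attr(x, "threshold"))
  ))
  invisible(x)
}

#' Select sometimes-essential genes
#'
#' Genes that are essential in every cell line, or in none, carry no
#' information about variation in sensitivity and are removed. In
#' `"per-cancer"` mode a gene is kept when it has at least one essential
#' and one non-essential call among the supplied lines (apply it per
#' cancer type's columns). In `"pan-cancer"` mode a gene must be essential
#' in at least `max(1, floor(min_fraction * N / 100))` of the N lines and
#' non-essential in at least as many.
#'
#' @param calls A [binarize_essentiality()] result (or logical matrix).
#' @param mode `"per-cancer"` or `"pan-cancer"`.
#' @param min_fraction Percentage (e.g. 1, 5, 10) for pan-cancer mode;
#'   ignored in per-cancer mode.
#' @return Character vector of retained gene symbols.
#' @export
sometimes_essential <- function(calls, mode = c("per-cancer", "pan-cancer"),
                                min_fraction = 1) {
  mode <- match.arg(mode)
  if (ncol(calls) == 0) {
    stop("no cell lines in essentiality calls")
  }
  ne <- rowSums(unclass(calls), na.rm = TRUE)
  nn <- rowSums(!unclass(calls), na.rm = TRUE)
  if (mode == "per-cancer") {
    req <- 1L
  } else {
    stopifnot(min_fraction > 0)
    n_obs <- ne + nn
    req <- pmax(1L, floor(min_fraction * n_obs / 100))
  }
  rownames(calls)[ne >= req & nn >= req]
}

#' Genes eligible for binary (CLES) analysis
#'
#' For the common-language effect size to be meaningful both groups need a
#' minimum size: a gene is eligible when it is essential in at least
#' `min_per_group` cell lines and non-essential in at least as many
#' (default 3 each).
#'
#' @param calls A [binarize_essentiality()] result.
#' @param min_per_group Minimum calls in each group (default 3).
#' @return Character vector of eligible gene symbols.
#' @export
binary_eligible <- function(calls, min_per_group = 3) {
  stopifnot(min_per_group >= 1)
  ne <- rowSums(unclass(calls), na.rm = TRUE)
  nn <- rowSums(!unclass(calls), na.rm = TRUE)
  rownames(calls)[ne >= min_per_group & nn >= min_per_group]
}
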