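#' Pearson correlation with a t-based p-value
#'
#' Product-moment correlation R between two sample vectors and the
#' two-sided p-value from t = R * sqrt(n - 2) / sqrt(1 - R^2) on n - 2
#' degrees of freedom, after pairwise-complete filtering. Constant vectors
#' or n < 3 yield a missing record with a reason.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `r`, `p`, `n`, and `reason` (NA unless degenerate).
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) {
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "fewer than 3 complete pairs"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "constant vector"))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    return(list(r = sign(r), p = 0, n = n, reason = NA_character_))
  }
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(tval), n - 2), n = n, reason = NA_character_)
}

#' Bin an absolute correlation
#'
#' Bins used to stratify significant correlations: `(0.2,0.4]`,
#' `(0.4,0.6]`, `(0.6,0.8]`, `(0.8,1]`, with `<=0.2` for values at or
#' below the lowest edge.
#'
#' @param r Numeric vector of correlations.
#' @return Character vector of bin labels.
#' @export
abs_r_bin <- function(r) {
  a <- abs(r)
  cut(a,
    breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, 1),
    labels = c("<=0.2", "(0.2,0.4]", "(0.4,0.6]", "(0.6,0.8]", "(0.8,1]")
  ) |> as.character()
}

#' Correlate a predictor matrix with gene sensitivity, per gene
#'
#' For each gene in `genes`, correlates its row of the predictor matrix
#' (an activity matrix, where the row is the regulator's inferred
#' activity, or an expression matrix, where the row is the regulator's
#' own mRNA) with its row of the sensitivity matrix across the shared
#' samples. Records the Pearson R, p, significance at `alpha`, the
#' absolute-R bin and the sign. Per-gene failures are recorded with their
#' reason rather than raised.
#'
#' @param pred Predictor matrix (rows = genes/regulators, columns =
#'   samples matching `sens`).
#' @param sens Genes-by-cell-lines sensitivity matrix.
#' @param genes Genes to evaluate (must be rows of both matrices).
#' @param predictor Label stored in the `predictor` column.
#' @param alpha Significance gate (default 0.05, no multiplicity
#'   correction; set `adjust = "BH"` to gate on Benjamini-Hochberg
#'   adjusted p-values instead).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with one row per gene: `gene`, `predictor`, `n`, `r`,
#'   `p`, `significant`, `bin`, `sign`, `reason`.
#' @export
correlate_all <- function(pred, sens, genes, predictor = "activity",
                          alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  samples <- intersect(colnames(pred), colnames(sens))
  genes <- as.character(genes)
  n_g <- length(genes)
  r <- rep(NA_real_, n_g)
  p <- rep(NA_real_, n_g)
  n <- integer(n_g)
  reason <- rep(NA_character_, n_g)
  present <- genes %in% rownames(pred) & genes %in% rownames(sens)
  reason[!present] <- "gene absent from predictor or sensitivity matrix"
  if (any(present)) {
    X <- pred[genes[present], samples, drop = FALSE]
    Y <- sens[genes[present], samples, drop = FALSE]
    complete <- rowSums(!is.finite(X)) == 0 & rowSums(!is.finite(Y)) == 0
    if (length(samples) < 3) {
      complete[] <- FALSE
    }
    idx <- which(present)
    # fast path: complete rows, fully vectorized
    ic <- idx[complete]
    if (length(ic) > 0 && length(samples) >= 3) {
      rc <- rowwise_pearson(X[complete, , drop = FALSE], Y[complete, , drop = FALSE])
      nc <- length(samples)
      tv <- rc * sqrt(nc - 2) / sqrt(pmax(1 - rc^2, 0))
      pc <- 2 * stats::pt(-abs(tv), nc - 2)
      pc[!is.na(rc) & abs(rc) >= 1] <- 0
      r[ic] <- rc
      p[ic] <- pc
      n[ic] <- nc
      reason[ic][is.na(rc)] <- "constant vector"
    }
    # slow path: rows with missing values (pairwise-complete per gene)
    for (j in which(!complete)) {
      res <- pearson_with_p(X[j, ], Y[j, ])
      i <- idx[j]
      r[i] <- res$r
      p[i] <- res$p
      n[i] <- as.integer(res$n)
      reason[i] <- res$reason
    }
  }
  out <- tibble::tibble(
    gene = genes, predictor = predictor, n = n, r = r, p = p, reason = reason
  )
  p_gate <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- !is.na(p_gate) & p_gate < alpha
  out$bin <- abs_r_bin(out$r)
  out$sign <- ifelse(is.na(out$r), NA_character_,
    ifelse(out$r >= 0, "positive", "negative")
  )
  out
}

#' Common-language effect size
#'
#' The probability that a randomly drawn member of the essential group
#' scores higher than a randomly drawn member of the non-essential group,
#' ties counted one half:
#' CLES = (#(e > n) + 0.5 #(e = n)) / (|E| |N|). Numerically identical to
#' the area under the ROC curve with essential as the positive class.
#' Computed via midranks, so it is O((m+n) log(m+n)).
#'
#' @param essential_scores,nonessential_scores Numeric vectors (both
#'   non-empty).
#' @return CLES in \[0, 1\].
#' @export
cles <- function(essential_scores, nonessential_scores) {
  e <- essential_scores[is.finite(essential_scores)]
  n <- nonessential_scores[is.finite(nonessential_scores)]
  stopifnot(length(e) > 0, length(n) > 0)
  r <- rank(c(e, n))
  (sum(r[seq_along(e)]) - length(e) * (length(e) + 1) / 2) / (length(e) * length(n))
}

#' Wilcoxon rank-sum test
#'
#' Unpaired two-sample rank-sum test: exact enumeration when the combined
#' sample size is at most 12 and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger
#'   than b) or `"less"`.
#' @return The p-value.
#' @export
rank_sum_test <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  stopifnot(length(a) > 0, length(b) > 0)
  no_ties <- !anyDuplicated(c(a, b))
  exact <- (length(a) + length(b)) <= 12 && no_ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b,
      alternative = alternative, exact = exact, correct = TRUE
    )$p.value
  )
  # all observations tied across both groups: no evidence either way
  if (is.nan(p)) p <- 1
  p
}

#' Per-gene CLES table with threshold counts
#'
#' For each eligible gene, computes the CLES of the predictor values in
#' essential versus non-essential cell lines together with the rank-sum
#' p-value, then counts genes passing `p < alpha` with CLES above each
#' threshold.
#'
#' @param pred Predictor matrix (rows = genes, columns = cell lines).
#' @param calls A [binarize_essentiality()] result over the same cell
#'   lines.
#' @param eligible Genes to evaluate (from [binary_eligible()]).
#' @param thresholds CLES thresholds to count (default 0.7, 0.8, 0.9).
#' @param alpha Significance gate for the rank-sum p (default 0.05).
#' @param predictor Label stored in the records.
#' @return A list with `records` (tibble: gene, predictor, cles, p,
#'   n_essential, n_nonessential) and `counts` (named integer vector, one
#'   entry per threshold).
#' @export
cles_table <- function(pred, calls, eligible, thresholds = c(0.7, 0.8, 0.9),
                       alpha = 0.05, predictor = "activity") {
  lines <- intersect(colnames(pred), colnames(calls))
  rows <- lapply(eligible, function(g) {
    cl <- unclass(calls)[g, lines]
    v <- pred[g, lines]
    ok <- !is.na(cl) & is.finite(v)
    e <- v[ok & cl]
    n <- v[ok & !cl]
    if (length(e) == 0 || length(n) == 0) {
      return(tibble::tibble(
        gene = g, predictor = predictor, cles = NA_real_, p = NA_real_,
        n_essential = length(e), n_nonessential = length(n)
      ))
    }
    tibble::tibble(
      gene = g, predictor = predictor,
      cles = cles(e, n), p = rank_sum_test(e, n),
      n_essential = length(e), n_nonessential = length(n)
    )
  })
  records <- dplyr::bind_rows(rows)
  counts <- vapply(thresholds, function(th) {
    sum(!is.na(records$cles) & !is.na(records$p) &
          records$p < alpha & records$cles > th)
  }, integer(1))
  names(counts) <- paste0("cles_gt_", thresholds)
  list(records = records, counts = counts)
}

#' Matched- versus mismatched-regulon ranking test
#'
#' Given a cancer-type by regulon-source table of mean absolute
#' correlations, ranks the regulons within each cancer type (rank 1 = the
#' largest mean |R|, midranks on ties), collects the ranks of the matched
#' cells (row label == column label) against all mismatched cells, and
#' tests the two rank samples with the rank-sum test. Because it uses only
#' within-row ranks, the test is invariant to monotone transforms applied
#' per row.
#'
#' @param mean_abs_r Numeric matrix, rows = evaluated cancer types,
#'   columns = regulon cancer types; matched cells are on the diagonal of
#'   the shared labels. `NA` rows/cells are excluded.
#' @param alternative Passed to [rank_sum_test()]; `"less"` asks whether
#'   matched ranks are smaller (i.e. matched regulons perform better).
#' @return A list with `ranks` (tibble: cancer_type, regulon, rank,
#'   matched), `p`, and `alternative`.
#' @export
matched_vs_mismatched <- function(mean_abs_r, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(mean_abs_r), !is.null(rownames(mean_abs_r)), !is.null(colnames(mean_abs_r)))
  rows <- lapply(rownames(mean_abs_r), function(ct) {
    v <- mean_abs_r[ct, ]
    ok <- !is.na(v)
    if (!any(ok)) {
      return(NULL)
    }
    rk <- rank(-v[ok], ties.method = "average")
    tibble::tibble(
      cancer_type = ct, regulon = names(rk), rank = as.numeric(rk),
      matched = names(rk) == ct
    )
  })
  ranks <- dplyr::bind_rows(rows)
  matched <- ranks$rank[ranks$matched]
  mismatched <- ranks$rank[!ranks$matched]
  if (length(matched) == 0 || length(mismatched) == 0) {
    stop("need both matched and mismatched cells to compare")
  }
  p <- rank_sum_test(matched, mismatched, alternative = alternative)
  list(ranks = ranks, p = p, alternative = alternative)
}

#' Sequential adjusted R-squared variance decomposition
#'
#' Fits the nested sequence of ordinary least squares models implied by
#' the term order and attributes to each term the increase in adjusted
#' R-squared when it is added. Categorical terms are dummy-encoded with
#' the first level as reference; numeric terms are standardized. Shares
#' are order-dependent by construction; the order used is returned.
#'
#' @param data Data frame with the response and term columns.
#' @param response Name of the numeric response column (e.g. the mean
#'   absolute correlation of a cancer-type/regulon/method combination).
#' @param terms Character vector of term names, in the order they enter
#'   the model.
#' @return A tibble with `term`, `adj_r_squared` (cumulative) and `share`
#'   (increment), plus attributes `full_adj_r_squared` and `order`.
#' @export
variance_decomposition <- function(data, response, terms) {
  stopifnot(all(c(response, terms) %in% names(data)))
  df <- data
  for (t in terms) {
    if (is.character(df[[t]])) {
      df[[t]] <- factor(df[[t]])
    } else if (is.numeric(df[[t]])) {
      s <- stats::sd(df[[t]])
      df[[t]] <- if (s > 0) (df[[t]] - mean(df[[t]])) / s else df[[t]] * 0
    }
  }
  n_par <- 1 + sum(vapply(terms, function(t) {
    if (is.factor(df[[t]])) nlevels(df[[t]]) - 1L else 1L
  }, integer(1)))
  if (nrow(df) <= n_par) {
    stop("fewer rows than model parameters")
  }
  prev <- 0
  out <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    fml <- stats::reformulate(terms[seq_len(i)], response = response)
    fit <- stats::lm(fml, data = df)
    ar2 <- summary(fit)$adj.r.squared
    out[[i]] <- tibble::tibble(
      term = terms[i], adj_r_squared = ar2, share = ar2 - prev
    )
    prev <- ar2
  }
  res <- dplyr::bind_rows(out)
  attr(res, "full_adj_r_squared") <- prev
  attr(res, "order") <- terms
  res
}

#' Per-gene variance across samples
#'
#' Unbiased (n - 1 denominator) variance of each row of a predictor
#' matrix, used to compare the spread of activity scores across methods
#' with the spread of expression.
#'
#' @param pred Matrix with >= 2 columns.
#' @param method Optional method label column.
#' @return A tibble with `gene`, `variance` and (if given) `method`.
#' @export
per_gene_variance <- function(pred, method = NULL) {
  stopifnot(is.matrix(pred), ncol(pred) >= 2)
  v <- apply(pred, 1, stats::var, na.rm = TRUE)
  out <- tibble::tibble(gene = rownames(pred), variance = unname(v))
  if (!is.null(method)) {
    out$method <- method
  }
  out
}

#' Gene-set enrichment by Fisher's exact test
#'
#' One-sided (enrichment) Fisher's exact test of the overlap between a hit
#' set and an annotation set within a universe, via the hypergeometric
#' tail; the odds ratio is the sample odds ratio of the 2x2 table (ad/bc).
#'
#' @param hits Character vector, subset of `universe`.
#' @param universe Character vector of all evaluated genes.
#' @param annotation Character vector (intersected with `universe`), e.g.
#'   an oncogene or master-regulator list.
#' @return A list with `odds_ratio`, `p`, and the 2x2 `table`.
#' @export
gene_set_enrichment <- function(hits, universe, annotation) {
  universe <- unique(universe)
  if (length(universe) == 0) {
    stop("empty universe")
  }
  hits <- intersect(unique(hits), universe)
  annotation <- intersect(unique(annotation), universe)
  a <- length(intersect(hits, annotation))
  b <- length(setdiff(hits, annotation))
  cc <- length(setdiff(annotation, hits))
  d <- length(universe) - a - b - cc
  p <- stats::phyper(a - 1, length(annotation),
    length(universe) - length(annotation), length(hits),
    lower.tail = FALSE
  )
  or <- if (b * cc == 0) {
    if (a * d == 0) 0 else Inf
  } else {
    (a * d) / (b * cc)
  }
  tab <- matrix(c(a, cc, b, d), 2, 2,
    dimnames = list(hit = c("yes", "no"), annotated = c("yes", "no"))
  )
  list(odds_ratio = or, p = p, table = tab)
}
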