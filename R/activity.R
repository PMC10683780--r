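#' Build dense weight vectors for regulators paired with an expression matrix
#'
#' Every activity method consumes, per regulator, a dense vector over the
#' genes of the expression matrix whose entries are the effective signed
#' weights (`weight * mor`) of the regulator's targets and zero elsewhere.
#' Regulators with fewer than `min_targets` targets present in the
#' expression matrix, or with no nonzero signed entry, are dropped with a
#' logged count.
#'
#' @param reg A [regulon_set()].
#' @param expr Genes-by-samples expression matrix (only rownames are used).
#' @param min_targets Minimum targets present in `expr` for a regulator to
#'   be retained (default 5).
#' @return A `weight_matrix` object: list with `signed` (genes x regulators
#'   matrix of `weight * mor`), `weight` and `mor` (same layout, needed by
#'   the rank-based enrichment method), and `regulators`.
#' @export
build_weight_matrix <- function(reg, expr, min_targets = 5) {
  stopifnot(inherits(reg, "regulon_set"), min_targets >= 1)
  genes <- rownames(expr)
  e <- reg[reg$target %in% genes, , drop = FALSE]
  n_t <- table(e$regulator)
  keep <- names(n_t)[n_t >= min_targets]
  dropped <- setdiff(unique(reg$regulator), keep)
  e <- e[e$regulator %in% keep, , drop = FALSE]
  if (length(keep) == 0) {
    stop("no regulator has >= ", min_targets, " targets in the expression matrix")
  }
  keep <- sort(keep)
  W <- matrix(0, nrow = length(genes), ncol = length(keep),
              dimnames = list(genes, keep))
  M <- W
  gi <- match(e$target, genes)
  ri <- match(e$regulator, keep)
  idx <- cbind(gi, ri)
  W[idx] <- e$weight
  M[idx] <- e$mor
  signed <- W * M
  nonzero <- colSums(signed != 0) > 0
  if (any(!nonzero)) {
    dropped <- c(dropped, keep[!nonzero])
    W <- W[, nonzero, drop = FALSE]
    M <- M[, nonzero, drop = FALSE]
    signed <- signed[, nonzero, drop = FALSE]
    keep <- keep[nonzero]
  }
  if (ncol(signed) == 0) {
    stop("no regulator retains a nonzero signed weight vector")
  }
  if (length(dropped) > 0) {
    message(length(dropped), " regulator(s) dropped at pairing time")
  }
  structure(
    list(signed = signed, weight = W, mor = M, regulators = keep),
    class = "weight_matrix"
  )
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf(
    "<weight_matrix> %d regulators x %d genes\n",
    length(x$regulators), nrow(x$signed)
  ))
  invisible(x)
}

# cap applied to t-values from (near-)perfect fits so downstream
# correlations stay finite
.t_cap <- 1e6

new_activity <- function(values, method, source = NA_character_,
                         cancer_type = NA_character_) {
  structure(values,
    class = c("activity_matrix", "matrix"),
    method = method, source = source, cancer_type = cancer_type
  )
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf(
    "<activity_matrix> %d regulators x %d samples | method: %s\n",
    nrow(x), ncol(x), attr(x, "method")
  ))
  invisible(x)
}

#' Univariate linear model (ULM) activity
#'
#' For each sample and regulator, regresses the sample's expression across
#' genes on the regulator's signed weight vector (intercept included) and
#' reports the t-statistic of the slope (slope / standard error, G - 2
#' degrees of freedom) as the activity score: a positive score means the
#' regulator's activating targets are high and its repressed targets low.
#' Computed via the correlation identity t = r * sqrt(G - 2) / sqrt(1 - r^2).
#' Zero-variance weight vectors yield missing scores; perfect fits are
#' capped at +/- 1e6 and flagged via the `capped` attribute.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param weights A [build_weight_matrix()] result.
#' @return `activity_matrix` (regulators x samples) of t-values.
#' @export
ulm_activity <- function(expr, weights) {
  stopifnot(is.matrix(expr), inherits(weights, "weight_matrix"))
  G <- nrow(expr)
  if (G < 3) {
    stop("ULM requires at least 3 genes")
  }
  M <- weights$signed[rownames(expr), , drop = FALSE]
  sds <- apply(M, 2, stats::sd)
  r <- suppressWarnings(stats::cor(M, expr))
  r[sds == 0, ] <- NA_real_
  tval <- r * sqrt(G - 2) / sqrt(pmax(1 - r^2, 0))
  capped <- !is.na(r) & (1 - r^2 <= 0 | abs(tval) > .t_cap)
  tval[capped] <- sign(r[capped]) * .t_cap
  out <- new_activity(tval, "ulm")
  attr(out, "capped") <- capped
  out
}

#' Multivariate linear model (MLM) activity
#'
#' Per sample, fits one multiple regression of expression across genes on
#' all regulators' signed weight vectors jointly (plus intercept); the
#' activity of regulator r in sample s is the t-value of its coefficient
#' (G - p - 1 degrees of freedom). Requires more genes than regulators and
#' a full-rank design; on rank deficiency the most collinear regulator
#' pair is named.
#'
#' @inheritParams ulm_activity
#' @return `activity_matrix` (regulators x samples) of t-values.
#' @export
mlm_activity <- function(expr, weights) {
  stopifnot(is.matrix(expr), inherits(weights, "weight_matrix"))
  M <- weights$signed[rownames(expr), , drop = FALSE]
  G <- nrow(expr)
  p <- ncol(M)
  if (G <= p + 1) {
    stop("MLM requires more genes than regulators plus one")
  }
  X <- cbind(`(intercept)` = 1, M)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    cm <- suppressWarnings(stats::cor(M))
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm), na.rm = TRUE), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "rank-deficient weight matrix; most collinear regulators: %s and %s (|r| = %.3f)",
      colnames(M)[worst[1]], colnames(M)[worst[2]],
      max(abs(cm), na.rm = TRUE)
    ))
  }
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, expr)
  resid <- expr - X %*% B
  df <- G - p - 1
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(XtXinv), sigma2))
  tval <- B / se
  tval <- tval[-1, , drop = FALSE]
  rownames(tval) <- colnames(M)
  capped <- abs(tval) > .t_cap
  tval[capped] <- sign(tval[capped]) * .t_cap
  out <- new_activity(tval, "mlm")
  attr(out, "capped") <- capped
  out
}

#' Single-layer analytic rank-based enrichment (VIPER-style) activity
#'
#' Implements the analytic rank-based enrichment score that underlies
#' VIPER, without pleiotropy or shadow corrections. Per sample, genes are
#' midranked (r_i over G genes) and mapped to normal quantiles: two-tail
#' q2_i = qnorm(r_i / (G + 1)) and one-tail
#' q1_i = qnorm(0.5 + |r_i / (G + 1) - 0.5|). For a regulator with edge
#' weights w_i and modes mor_i:
#' ES = \[sum w_i mor_i q2_i + sum w_i (1 - |mor_i|) q1_i\] / sum w_i, and
#' the reported activity is the normalized score
#' NES = ES * sqrt(sum(w_i / max_j w_j)). A sample with all-tied
#' expression yields activity 0 for every regulator.
#'
#' @inheritParams ulm_activity
#' @return `activity_matrix` (regulators x samples) of normalized
#'   enrichment scores.
#' @export
viper_activity <- function(expr, weights) {
  stopifnot(is.matrix(expr), inherits(weights, "weight_matrix"))
  G <- nrow(expr)
  if (G < 5) {
    stop("rank-based enrichment requires at least 5 genes")
  }
  W <- weights$weight[rownames(expr), , drop = FALSE]
  Mor <- weights$mor[rownames(expr), , drop = FALSE]
  R <- apply(expr, 2, rank) / (G + 1)
  Q2 <- stats::qnorm(R)
  Q1 <- stats::qnorm(0.5 + abs(R - 0.5))
  Wm <- W * Mor
  W1 <- W * (1 - abs(Mor))
  denom <- colSums(W)
  ES <- (crossprod(Wm, Q2) + crossprod(W1, Q1)) / denom
  wmax <- apply(W, 2, max)
  nes_factor <- sqrt(colSums(sweep(W, 2, wmax, "/")))
  new_activity(ES * nes_factor, "viper")
}

#' Weighted sum and weighted mean activity
#'
#' `wsum_activity` scores regulator r in sample s as the sum over its
#' targets of signed weight times expression; `wmean_activity` divides
#' that sum by the total absolute signed weight. The two differ by a
#' positive per-regulator constant, so all sample-wise correlations based
#' on them coincide.
#'
#' @inheritParams ulm_activity
#' @return `activity_matrix` (regulators x samples).
#' @export
wsum_activity <- function(expr, weights) {
  stopifnot(is.matrix(expr), inherits(weights, "weight_matrix"))
  M <- weights$signed[rownames(expr), , drop = FALSE]
  new_activity(crossprod(M, expr), "wsum")
}

#' @rdname wsum_activity
#' @export
wmean_activity <- function(expr, weights) {
  stopifnot(is.matrix(expr), inherits(weights, "weight_matrix"))
  M <- weights$signed[rownames(expr), , drop = FALSE]
  s <- crossprod(M, expr)
  new_activity(s / colSums(abs(M)), "wmean")
}

#' Consensus activity across methods
#'
#' Per method and sample, scores are standardized across regulators
#' (mean 0, sd 1; an all-equal column maps to zeros); the consensus is the
#' unweighted mean of the standardized scores across methods, skipping
#' missing per-cell scores (the effective number of methods per cell is
#' retained in the `n_methods` attribute).
#'
#' @param per_method List of >= 2 `activity_matrix` objects over identical
#'   regulator x sample grids.
#' @return `activity_matrix` with method tag `"consensus"`.
#' @export
consensus_activity <- function(per_method) {
  stopifnot(is.list(per_method), length(per_method) >= 2)
  dims <- lapply(per_method, dimnames)
  for (i in seq_along(per_method)[-1]) {
    if (!identical(dims[[1]], dims[[i]])) {
      stop("activity matrices disagree in their regulator x sample grids")
    }
  }
  zs <- lapply(per_method, function(a) {
    apply(unclass(a), 2, function(col) {
      s <- stats::sd(col, na.rm = TRUE)
      if (is.na(s) || s == 0) {
        rep(0, length(col))
      } else {
        (col - mean(col, na.rm = TRUE)) / s
      }
    })
  })
  arr <- simplify2array(zs)
  cons <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  n_eff <- apply(arr, c(1, 2), function(v) sum(!is.na(v)))
  dimnames(cons) <- dims[[1]]
  out <- new_activity(cons, "consensus")
  attr(out, "n_methods") <- n_eff
  out
}

#' Infer activity with one or more methods
#'
#' Convenience wrapper pairing a regulon set with an expression matrix and
#' running the requested scoring methods. `"consensus"` requires (and will
#' automatically compute) the five base methods.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param reg A [regulon_set()].
#' @param methods Subset of `c("ulm", "mlm", "viper", "wsum", "wmean",
#'   "consensus")` or `"all"`.
#' @param min_targets Passed to [build_weight_matrix()].
#' @return Named list of `activity_matrix` objects.
#' @export
infer_activity <- function(expr, reg,
                           methods = c("ulm", "mlm", "viper", "wsum", "wmean", "consensus"),
                           min_targets = 5) {
  if (identical(methods, "all")) {
    methods <- c("ulm", "mlm", "viper", "wsum", "wmean", "consensus")
  }
  methods <- match.arg(methods,
    c("ulm", "mlm", "viper", "wsum", "wmean", "consensus"),
    several.ok = TRUE
  )
  wts <- build_weight_matrix(reg, expr, min_targets = min_targets)
  base_needed <- setdiff(methods, "consensus")
  if ("consensus" %in% methods) {
    base_needed <- c("ulm", "mlm", "viper", "wsum", "wmean")
  }
  runners <- list(
    ulm = ulm_activity, mlm = mlm_activity, viper = viper_activity,
    wsum = wsum_activity, wmean = wmean_activity
  )
  out <- lapply(runners[base_needed], function(f) f(expr, wts))
  if ("consensus" %in% methods) {
    out$consensus <- consensus_activity(out)
  }
  out[intersect(c("ulm", "mlm", "viper", "wsum", "wmean", "consensus"), methods)]
}
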