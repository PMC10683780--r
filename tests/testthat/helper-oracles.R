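# Independent oracles used to check the package's own implementations.
# These are deliberately naive (explicit normal equations, literal loops,
# trapezoidal integration) so that they share no code path with R/.

# OLS t-values via explicit normal equations on design [1, X]
oracle_ols_t <- function(X, y) {
  X <- cbind(1, X)
  XtX <- t(X) %*% X
  inv <- solve(XtX)
  beta <- inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  unname((beta / sqrt(sigma2 * diag(inv)))[-1])
}

# literal loop-summation weighted sum / mean
oracle_wsum <- function(signed, y) {
  s <- 0
  for (i in seq_along(y)) s <- s + signed[[i]] * y[[i]]
  s
}
oracle_wmean <- function(signed, y) {
  oracle_wsum(signed, y) / sum(abs(signed))
}

# trapezoidal AUROC over scores with binary labels (1 = positive class)
oracle_auroc <- function(scores, labels) {
  thr <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  tpr <- fpr <- numeric(length(thr))
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  for (i in seq_along(thr)) {
    tpr[i] <- sum(scores >= thr[i] & labels == 1) / P
    fpr[i] <- sum(scores >= thr[i] & labels == 0) / N
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# exhaustive pairwise CLES
oracle_cles <- function(e, n) {
  tot <- 0
  for (ei in e) {
    for (ni in n) {
      tot <- tot + (ei > ni) + 0.5 * (ei == ni)
    }
  }
  tot / (length(e) * length(n))
}

# write a small delimited regulon fixture, returning its path
write_regulon_fixture <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# tiny paired expression/weights fixture used across activity tests
tiny_weights <- function(expr, targets, weights, mors, regulator = "R1") {
  reg <- regulon_set(
    regulator = rep(regulator, length(targets)),
    target = targets, weight = weights, mor = mors
  )
  build_weight_matrix(reg, expr, min_targets = 1)
}
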