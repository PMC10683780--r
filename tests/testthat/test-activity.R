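make_expr <- function(G, S, seed = 1) {
  set.seed(seed)
  matrix(rnorm(G * S), G, S,
    dimnames = list(sprintf("g%03d", seq_len(G)), sprintf("s%02d", seq_len(S)))
  )
}

test_that("weight matrix building enforces min_targets and drops regulators", {
  expr <- make_expr(6, 2)
  reg <- regulon_set(
    c(rep("R1", 5), rep("R2", 2)),
    c(rownames(expr)[1:3], "ZZ1", "ZZ2", rownames(expr)[4:5]),
    weight = 1, mor = 1
  )
  # R1 has only 3 of 5 targets present (R2 just 2) -> nobody survives
  expect_error(build_weight_matrix(reg, expr, min_targets = 5), "no regulator")
  wts <- suppressMessages(build_weight_matrix(reg, expr, min_targets = 2))
  expect_setequal(wts$regulators, c("R1", "R2"))
  # single-target regulator retained at min_targets = 1
  reg1 <- regulon_set("R9", rownames(expr)[1])
  w1 <- build_weight_matrix(reg1, expr, min_targets = 1)
  expect_equal(w1$regulators, "R9")
})

test_that("dense weight vectors match a hand-written expectation", {
  expr <- make_expr(6, 2)
  g <- rownames(expr)
  reg <- regulon_set(
    c("R1", "R1", "R2", "R2"),
    c(g[1], g[3], g[2], g[6]),
    weight = c(0.5, 1, 0.25, 0.75), mor = c(1, -1, 1, 1)
  )
  wts <- build_weight_matrix(reg, expr, min_targets = 1)
  expect_equal(unname(wts$signed[, "R1"]), c(0.5, 0, -1, 0, 0, 0))
  expect_equal(unname(wts$signed[, "R2"]), c(0, 0.25, 0, 0, 0, 0.75))
})

test_that("ULM t-values match the normal-equation oracle", {
  for (seed in 1:5) {
    expr <- make_expr(50, 4, seed)
    set.seed(seed + 100)
    reg <- regulon_set(
      rep(c("R1", "R2"), each = 10),
      sample(rownames(expr), 20),
      weight = runif(20, 0.5, 1), mor = sample(c(-1, 1), 20, TRUE)
    )
    wts <- build_weight_matrix(reg, expr, min_targets = 5)
    act <- ulm_activity(expr, wts)
    for (r in wts$regulators) {
      for (s in seq_len(ncol(expr))) {
        expect_equal(
          act[r, s],
          oracle_ols_t(wts$signed[, r, drop = FALSE], expr[, s])[[1]],
          tolerance = 1e-8
        )
      }
    }
  }
})

test_that("ULM boundary behaviour: orthogonal weights, degenerate inputs", {
  expr <- matrix(c(3, 3, 5, 7), 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
  reg <- regulon_set(rep("R1", 2), c("g1", "g2"), weight = 1, mor = c(1, -1))
  wts <- build_weight_matrix(reg, expr, min_targets = 1)
  # weight vector [1,-1,0,0] orthogonal to expression -> slope 0 -> t = 0
  expect_equal(unname(ulm_activity(expr, wts)["R1", 1]), 0)

  # expression proportional to weights -> perfect fit, capped and flagged
  expr2 <- matrix(c(1, -1, 0, 0) * 2 + 5, 4, 1, dimnames = dimnames(expr))
  act2 <- ulm_activity(expr2, wts)
  expect_equal(unname(act2["R1", 1]), 1e6)
  expect_true(attr(act2, "capped")["R1", 1])
})

test_that("MLM matches the multi-column normal-equation oracle", {
  for (seed in 1:5) {
    expr <- make_expr(60, 3, seed)
    set.seed(seed + 200)
    reg <- regulon_set(
      rep(c("R1", "R2", "R3"), each = 12),
      sample(rownames(expr), 36),
      weight = runif(36, 0.5, 1), mor = sample(c(-1, 1), 36, TRUE)
    )
    wts <- build_weight_matrix(reg, expr, min_targets = 5)
    act <- mlm_activity(expr, wts)
    for (s in seq_len(ncol(expr))) {
      expect_equal(
        unname(act[, s]),
        unname(oracle_ols_t(wts$signed, expr[, s])),
        tolerance = 1e-8
      )
    }
  }
})

test_that("MLM equals ULM on orthogonal weight vectors", {
  expr <- make_expr(10, 4, 3)
  g <- rownames(expr)
  # disjoint target sets with disjoint support are orthogonal... but also
  # must be orthogonal after centering; construct balanced +1/-1 pairs
  reg <- regulon_set(
    c("R1", "R1", "R2", "R2"),
    c(g[1], g[2], g[3], g[4]),
    weight = 1, mor = c(1, -1, 1, -1)
  )
  wts <- build_weight_matrix(reg, expr, min_targets = 1)
  expect_equal(unname(crossprod(wts$signed)[1, 2]), 0)
  expect_lt(abs(sum(wts$signed[, 1])), 1e-12)
  u <- ulm_activity(expr, wts)
  m <- mlm_activity(expr, wts)
  # same point estimate direction; t-values agree up to the df ratio
  # (G-2 vs G-p-1) through the residual variance; on orthogonal designs the
  # coefficients agree exactly, so compare slopes via t * se reconstruction
  expect_equal(sign(unclass(u)), sign(unclass(m)), ignore_attr = TRUE)
  expect_gt(min(cor(as.vector(u), as.vector(m)), 1), 0.99)
})

test_that("MLM rejects duplicate (collinear) regulator columns", {
  expr <- make_expr(20, 2, 5)
  g <- rownames(expr)
  reg <- regulon_set(
    rep(c("R1", "R2"), each = 5),
    c(g[1:5], g[1:5]),
    weight = 1, mor = 1
  )
  wts <- build_weight_matrix(reg, expr, min_targets = 1)
  expect_error(mlm_activity(expr, wts), "collinear.*R[12].*R[12]")
})

test_that("MLM is calibrated under the null", {
  set.seed(7)
  G <- 200
  genes <- sprintf("g%03d", 1:G)
  reg <- regulon_set(
    rep(c("R1", "R2", "R3"), each = 15),
    c(sample(genes, 15), sample(genes, 15), sample(genes, 15)),
    weight = 1, mor = sample(c(-1, 1), 45, TRUE)
  )
  n_samp <- 100
  expr <- matrix(rnorm(G * n_samp), G, n_samp,
    dimnames = list(genes, sprintf("s%03d", 1:n_samp))
  )
  wts <- build_weight_matrix(reg, expr, min_targets = 5)
  tvals <- mlm_activity(expr, wts)
  # mean |t| close to E|t| ~ sqrt(2/pi) for large df
  expect_lt(abs(mean(abs(tvals)) - sqrt(2 / pi)), 0.1)
  # Bonferroni-level exceedances are rare
  bonf <- qt(1 - 0.025 / nrow(tvals), df = G - 4)
  frac_samples_hit <- mean(apply(abs(unclass(tvals)) > bonf, 2, any))
  expect_lt(frac_samples_hit, 0.05 + 2 * sqrt(0.05 * 0.95 / n_samp) + 0.02)
})

test_that("rank-based enrichment matches the normal-quantile oracle", {
  # single-target regulator, target top-ranked among G = 9 genes
  genes <- paste0("g", 1:9)
  expr <- matrix(c(9, 1:8), 9, 1, dimnames = list(genes, "s1"))
  reg <- regulon_set("R1", "g1", weight = 1, mor = 1)
  wts <- build_weight_matrix(reg, expr, min_targets = 1)
  act <- viper_activity(expr, wts)
  expect_equal(unname(act["R1", 1]), qnorm(0.9), tolerance = 1e-12)
})

test_that("rank-based enrichment: ties floor, antisymmetry, mor-0 one-tail term", {
  genes <- paste0("g", 1:8)
  const <- matrix(5, 8, 1, dimnames = list(genes, "s1"))
  reg <- regulon_set(rep("R1", 3), genes[1:3], weight = c(1, 0.5, 0.8), mor = c(1, -1, 1))
  wts <- build_weight_matrix(reg, const, min_targets = 1)
  expect_equal(unname(viper_activity(const, wts)["R1", 1]), 0)

  set.seed(11)
  expr <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(genes, paste0("s", 1:5)))
  pos <- build_weight_matrix(reg, expr, min_targets = 1)
  neg_reg <- regulon_set(rep("R1", 3), genes[1:3],
    weight = c(1, 0.5, 0.8), mor = c(-1, 1, -1)
  )
  neg <- build_weight_matrix(neg_reg, expr, min_targets = 1)
  expect_equal(
    unclass(viper_activity(expr, pos)),
    -unclass(viper_activity(expr, neg))
  )

  # an edge with mor = 0 (weight in the one-tail term only) changes the
  # score but contributes no signed part: compare against direct formula
  reg0 <- regulon_set(rep("R1", 2), genes[1:2], weight = c(1, 1), mor = c(1, 0))
  # build manually since build_weight_matrix drops all-zero signed columns
  # only when *all* entries are zero; here g1 keeps it alive
  w0 <- build_weight_matrix(reg0, expr, min_targets = 1)
  a0 <- viper_activity(expr, w0)
  G <- nrow(expr)
  r <- apply(expr, 2, rank) / (G + 1)
  es <- (qnorm(r[1, ]) + qnorm(0.5 + abs(r[2, ] - 0.5))) / 2
  expect_equal(unname(a0["R1", ]), unname(es * sqrt(2)), tolerance = 1e-12)
})

test_that("weighted sum and mean match literal loop oracles", {
  # two-term arithmetic case
  expr <- matrix(c(2, 1, 0), 3, 1, dimnames = list(c("g1", "g2", "g3"), "s1"))
  reg <- regulon_set(rep("R1", 2), c("g1", "g2"), weight = 1, mor = c(1, -1))
  wts <- build_weight_matrix(reg, expr, min_targets = 1)
  expect_equal(unname(wsum_activity(expr, wts)["R1", 1]), 1)
  expect_equal(unname(wmean_activity(expr, wts)["R1", 1]), 0.5)

  # constant weights reduce wmean to the plain mean over targets
  reg2 <- regulon_set(rep("R2", 3), c("g1", "g2", "g3"), weight = 0.5, mor = 1)
  wts2 <- build_weight_matrix(reg2, expr, min_targets = 1)
  expect_equal(unname(wmean_activity(expr, wts2)["R2", 1]), mean(expr[, 1]))

  # random fixture against the loop oracle
  expr3 <- make_expr(20, 3, 13)
  set.seed(14)
  reg3 <- regulon_set(
    rep(c("R1", "R2"), each = 8), sample(rownames(expr3), 16),
    weight = runif(16), mor = sample(c(-1, 1), 16, TRUE)
  )
  wts3 <- build_weight_matrix(reg3, expr3, min_targets = 1)
  ws <- wsum_activity(expr3, wts3)
  wm <- wmean_activity(expr3, wts3)
  for (r in wts3$regulators) {
    for (s in 1:3) {
      expect_equal(ws[r, s], oracle_wsum(wts3$signed[, r], expr3[, s]), tolerance = 1e-12)
      expect_equal(wm[r, s], oracle_wmean(wts3$signed[, r], expr3[, s]), tolerance = 1e-12)
    }
  }
})

test_that("scale equivariance: scaling one regulator's weights", {
  expr <- make_expr(30, 6, 21)
  set.seed(22)
  targets <- sample(rownames(expr), 10)
  w <- runif(10, 0.5, 1)
  m <- sample(c(-1, 1), 10, TRUE)
  reg_a <- regulon_set(rep("R1", 10), targets, weight = w, mor = m)
  reg_b <- regulon_set(rep("R1", 10), targets, weight = 3 * w, mor = m)
  wa <- build_weight_matrix(reg_a, expr, min_targets = 1)
  wb <- build_weight_matrix(reg_b, expr, min_targets = 1)
  expect_equal(
    unclass(wsum_activity(expr, wb)), 3 * unclass(wsum_activity(expr, wa)),
    tolerance = 1e-12
  )
  expect_equal(
    unclass(wmean_activity(expr, wb)), unclass(wmean_activity(expr, wa)),
    tolerance = 1e-12
  )
  expect_equal(
    unclass(ulm_activity(expr, wb)), unclass(ulm_activity(expr, wa)),
    tolerance = 1e-10
  )
  # NES ranking of samples unchanged
  expect_equal(
    rank(viper_activity(expr, wb)["R1", ]),
    rank(viper_activity(expr, wa)["R1", ])
  )
})

test_that("consensus is the per-sample z-score mean", {
  dn <- list(paste0("R", 1:4), paste0("s", 1:2))
  m1 <- matrix(c(1, 2, 3, 4, 4, 3, 2, 1), 4, 2, dimnames = dn)
  m2 <- matrix(c(2, 4, 6, 8, 1, 1, 2, 2), 4, 2, dimnames = dn)
  m3 <- matrix(c(0, 0, 1, 1, 5, 6, 7, 8), 4, 2, dimnames = dn)
  mats <- lapply(list(m1, m2, m3), regulonbench:::new_activity, method = "x")
  cons <- consensus_activity(mats)
  z <- function(v) (v - mean(v)) / sd(v)
  hand <- (apply(m1, 2, z) + apply(m2, 2, z) + apply(m3, 2, z)) / 3
  expect_equal(unclass(cons), hand, ignore_attr = TRUE)

  # identical inputs -> consensus equals the standardized matrix
  cons2 <- consensus_activity(list(mats[[1]], mats[[1]]))
  expect_equal(unclass(cons2), apply(m1, 2, z), ignore_attr = TRUE)

  # z-negations cancel
  m_neg <- regulonbench:::new_activity(-m1, method = "y")
  cons3 <- consensus_activity(list(mats[[1]], m_neg))
  expect_true(all(abs(cons3) < 1e-12))

  # grid mismatch errors
  bad <- regulonbench:::new_activity(m1[1:3, ], method = "z")
  expect_error(consensus_activity(list(mats[[1]], bad)), "grids")
})

test_that("all method scores are mean-zero under regulon-independent noise", {
  set.seed(31)
  G <- 100
  genes <- sprintf("g%03d", 1:G)
  reg <- regulon_set(
    rep(c("R1", "R2"), each = 10),
    c(sample(genes, 10), sample(genes, 10)),
    weight = runif(20, 0.5, 1), mor = sample(c(-1, 1), 20, TRUE)
  )
  reps <- 500
  expr <- matrix(rnorm(G * reps), G, reps, dimnames = list(genes, NULL))
  colnames(expr) <- sprintf("s%03d", seq_len(reps))
  wts <- build_weight_matrix(reg, expr, min_targets = 5)
  for (f in list(ulm_activity, mlm_activity, viper_activity, wsum_activity, wmean_activity)) {
    a <- f(expr, wts)
    mc_se <- apply(unclass(a), 1, sd) / sqrt(reps)
    expect_true(all(abs(rowMeans(unclass(a))) < 4 * mc_se + 1e-3))
  }
})

test_that("infer_activity wires methods together", {
  expr <- make_expr(40, 5, 17)
  set.seed(18)
  reg <- regulon_set(
    rep(c("R1", "R2"), each = 8), sample(rownames(expr), 16),
    weight = runif(16, 0.5, 1), mor = sample(c(-1, 1), 16, TRUE)
  )
  out <- infer_activity(expr, reg, methods = "all", min_targets = 5)
  expect_named(out, c("ulm", "mlm", "viper", "wsum", "wmean", "consensus"))
  expect_equal(dim(out$consensus), c(2, 5))
  two <- infer_activity(expr, reg, methods = c("wsum", "wmean"), min_targets = 5)
  expect_named(two, c("wsum", "wmean"))
})
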