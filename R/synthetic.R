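#' Configuration for a synthetic benchmark cohort
#'
#' Defines the generative model used to test the pipeline with planted
#' ground truth. Per cancer type, latent regulator activities A(r, s) are
#' standard normal; target genes respond linearly to the signed weighted
#' activity of their regulators; each regulator's own mRNA is coupled to
#' its latent activity with correlation `alpha`; gene-effect scores are
#' driven by either the latent activity or the regulator's mRNA (the two
#' poles of the benchmark's headline question) plus Gaussian noise.
#'
#' Defaults describe the cohorts used throughout the package's own
#' evaluation: 10 cancer types of 30 samples, 2000 genes, 50 regulators
#' with 30 targets each, sensitivity effect size 1 against noise sd 0.5.
#'
#' @param n_cancer_types Number of cancer types (default 10).
#' @param n_samples Samples (cell lines) per cancer type (default 30).
#' @param n_genes Total genes G (default 2000).
#' @param n_regulators Number of regulatory genes (default 50).
#' @param targets_min,targets_max Per-regulator target count range
#'   (default 30, 30).
#' @param inhib_prob Probability an edge is inhibitory, mor = -1
#'   (default 0.3).
#' @param rewire_fraction Fraction of each regulator's targets rewired to
#'   new random genes in each non-reference cancer type, in \[0, 1\]
#'   (default 0 = identical networks across types).
#' @param beta_t Activity-to-target signal strength (default 1).
#' @param alpha Regulator mRNA / latent activity coupling in \[0, 1\]:
#'   mRNA = alpha * A + sqrt(1 - alpha^2) * noise (default 0).
#' @param driver What drives sensitivity: `"activity"` (latent activity),
#'   `"expression"` (the regulator's own mRNA), `"none"`, or a number in
#'   (0, 1) giving the weight of activity in a convex activity/expression
#'   mix.
#' @param beta_s Sensitivity effect size (default 1).
#' @param sigma_e Expression noise sd (default 1).
#' @param sigma_s Sensitivity noise sd (default 0.5).
#' @param essential_fraction Fraction of lines per gene centred below the
#'   -0.6 essentiality cutoff (default 0.3).
#' @param seed Integer random seed; the whole cohort is reproduced
#'   bit-for-bit from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_cancer_types = 10, n_samples = 30, n_genes = 2000,
                             n_regulators = 50, targets_min = 30, targets_max = 30,
                             inhib_prob = 0.3, rewire_fraction = 0,
                             beta_t = 1, alpha = 0, driver = "activity",
                             beta_s = 1, sigma_e = 1, sigma_s = 0.5,
                             essential_fraction = 0.3, seed = 1) {
  stopifnot(
    n_cancer_types >= 1, n_samples >= 2, n_genes > n_regulators + targets_max,
    n_regulators >= 1, targets_min >= 1, targets_max >= targets_min,
    inhib_prob >= 0, inhib_prob <= 1,
    rewire_fraction >= 0, rewire_fraction <= 1,
    alpha >= 0, alpha <= 1, sigma_e >= 0, sigma_s >= 0,
    essential_fraction > 0, essential_fraction < 1
  )
  if (is.character(driver)) {
    driver <- match.arg(driver, c("activity", "expression", "none"))
  } else {
    stopifnot(is.numeric(driver), driver >= 0, driver <= 1)
  }
  structure(
    list(
      n_cancer_types = n_cancer_types, n_samples = n_samples,
      n_genes = n_genes, n_regulators = n_regulators,
      targets_min = targets_min, targets_max = targets_max,
      inhib_prob = inhib_prob, rewire_fraction = rewire_fraction,
      beta_t = beta_t, alpha = alpha, driver = driver, beta_s = beta_s,
      sigma_e = sigma_e, sigma_s = sigma_s,
      essential_fraction = essential_fraction, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

.type_labels <- function(cfg) sprintf("CT%02d", seq_len(cfg$n_cancer_types))
.gene_labels <- function(cfg) {
  c(
    sprintf("REG%03d", seq_len(cfg$n_regulators)),
    sprintf("G%05d", seq_len(cfg$n_genes - cfg$n_regulators))
  )
}

#' Simulate cancer-type-specific regulons
#'
#' Each regulator draws a target count uniformly from the configured
#' range; targets are sampled without replacement from the non-regulator
#' genes; edges are inhibitory (mor = -1) with probability `inhib_prob`
#' and carry weights uniform on (0.5, 1). Each non-reference cancer type
#' rewires the configured fraction of every regulator's targets to new
#' random genes, so `rewire_fraction = 0` yields identical sets.
#'
#' @param cfg A [synthetic_config()].
#' @return Named list of [regulon_set()] objects, one per cancer type.
#' @export
simulate_grn <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  genes <- .gene_labels(cfg)
  regs <- genes[seq_len(cfg$n_regulators)]
  pool <- setdiff(genes, regs)
  base <- lapply(regs, function(r) {
    k <- if (cfg$targets_max > cfg$targets_min) {
      sample(cfg$targets_min:cfg$targets_max, 1)
    } else {
      cfg$targets_min
    }
    data.frame(
      regulator = r,
      target = sample(pool, k),
      weight = stats::runif(k, 0.5, 1),
      mor = ifelse(stats::runif(k) < cfg$inhib_prob, -1, 1),
      stringsAsFactors = FALSE
    )
  })
  types <- .type_labels(cfg)
  out <- stats::setNames(vector("list", length(types)), types)
  for (ti in seq_along(types)) {
    edges <- base
    if (ti > 1 && cfg$rewire_fraction > 0) {
      edges <- lapply(base, function(df) {
        k <- nrow(df)
        n_rw <- round(cfg$rewire_fraction * k)
        if (n_rw > 0) {
          swap <- sample(k, n_rw)
          new_targets <- sample(setdiff(pool, df$target), n_rw)
          df$target[swap] <- new_targets
        }
        df
      })
    }
    df <- do.call(rbind, edges)
    out[[ti]] <- regulon_set(df$regulator, df$target, df$weight, df$mor,
      source = "synthetic", cancer_type = types[ti]
    )
  }
  out
}

#' Simulate expression driven by latent regulator activity
#'
#' Per cancer type: latent activities A(r, s) ~ N(0, 1); target gene t has
#' x(t, s) = beta_t * sum_r mor * weight * A(r, s) + N(0, sigma_e);
#' regulator mRNA is x(r, s) = alpha * A(r, s) + sqrt(1 - alpha^2) * eta;
#' background genes are pure standard normal noise. The pooled matrix is
#' affine-rescaled (a single global shift/scale, which preserves all
#' correlation structure) onto a non-negative log2(TPM + 1)-like range.
#'
#' @param grn Output of [simulate_grn()].
#' @param cfg The same [synthetic_config()].
#' @return A list with `expression` (genes x samples matrix, cancer-type
#'   annotation attribute) and `truth` (per-type latent activities, the
#'   regulon sets, and the config).
#' @export
simulate_expression <- function(grn, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  genes <- .gene_labels(cfg)
  regs <- genes[seq_len(cfg$n_regulators)]
  types <- .type_labels(cfg)
  n_s <- cfg$n_samples
  expr_blocks <- list()
  A_list <- stats::setNames(vector("list", length(types)), types)
  for (ti in seq_along(types)) {
    t <- types[ti]
    A <- matrix(stats::rnorm(length(regs) * n_s), length(regs), n_s,
      dimnames = list(regs, sprintf("%s_S%02d", t, seq_len(n_s)))
    )
    wm <- matrix(0, length(genes), length(regs), dimnames = list(genes, regs))
    e <- grn[[t]]
    wm[cbind(match(e$target, genes), match(e$regulator, regs))] <- e$weight * e$mor
    X <- cfg$beta_t * (wm %*% A) +
      matrix(stats::rnorm(length(genes) * n_s, sd = cfg$sigma_e), length(genes), n_s)
    X[regs, ] <- cfg$alpha * A + sqrt(1 - cfg$alpha^2) *
      matrix(stats::rnorm(length(regs) * n_s), length(regs), n_s)
    bg <- setdiff(genes, c(regs, unique(e$target)))
    X[bg, ] <- matrix(stats::rnorm(length(bg) * n_s), length(bg), n_s)
    colnames(X) <- colnames(A)
    expr_blocks[[ti]] <- X
    A_list[[t]] <- A
  }
  expr <- do.call(cbind, expr_blocks)
  rng <- range(expr)
  expr <- (expr - rng[1]) / (rng[2] - rng[1]) * 12
  attr(expr, "cancer_type") <- stats::setNames(
    rep(types, each = n_s), colnames(expr)
  )
  truth <- structure(
    list(activity = A_list, regulons = grn, config = cfg),
    class = "ground_truth"
  )
  list(expression = expr, truth = truth)
}

#' Simulate CHRONOS-like gene-effect scores
#'
#' For each regulator gene, score(r, s) = -beta_s * D(r, s) + N(0,
#' sigma_s), where the standardized driver D is the latent activity
#' (`driver = "activity"`), the regulator's own mRNA
#' (`driver = "expression"`), zero (`"none"`), or a standardized convex
#' mix (numeric driver = weight of activity). Non-regulator genes receive
#' pure noise. Each gene's scores are then shifted so that its
#' `essential_fraction` quantile sits at the -0.6 binarization point —
#' a per-gene monotone shift, so correlations are untouched while the
#' sometimes-essential structure is guaranteed.
#'
#' @param truth Ground truth from [simulate_expression()].
#' @param expr The matching expression matrix.
#' @param cfg The same [synthetic_config()].
#' @return Genes x cell-lines sensitivity matrix (regulators plus an equal
#'   number of background genes).
#' @export
simulate_sensitivity <- function(truth, expr, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 2L)
  genes <- .gene_labels(cfg)
  regs <- genes[seq_len(cfg$n_regulators)]
  samples <- colnames(expr)
  std <- function(v) {
    s <- stats::sd(v)
    if (s == 0) v * 0 else (v - mean(v)) / s
  }
  A_all <- do.call(cbind, truth$activity)[, samples, drop = FALSE]
  n_bg <- cfg$n_regulators
  bg <- setdiff(genes, regs)[seq_len(min(n_bg, length(genes) - length(regs)))]
  score_genes <- c(regs, bg)
  S <- matrix(stats::rnorm(length(score_genes) * length(samples), sd = cfg$sigma_s),
    length(score_genes), length(samples),
    dimnames = list(score_genes, samples)
  )
  if (!identical(cfg$driver, "none")) {
    for (r in regs) {
      D <- if (identical(cfg$driver, "activity")) {
        std(A_all[r, ])
      } else if (identical(cfg$driver, "expression")) {
        std(expr[r, samples])
      } else {
        std(cfg$driver * std(A_all[r, ]) + (1 - cfg$driver) * std(expr[r, samples]))
      }
      S[r, ] <- S[r, ] - cfg$beta_s * D
    }
  }
  shift <- apply(S, 1, stats::quantile, probs = cfg$essential_fraction)
  S <- S - shift - 0.6 + 1e-9
  S
}

#' Simulate a full cohort
#'
#' Runs [simulate_grn()], [simulate_expression()] and
#' [simulate_sensitivity()] from one config; the result is reproduced
#' bit-for-bit from the same config.
#'
#' @param cfg A [synthetic_config()] (or arguments forwarded to it).
#' @return A list with `regulons`, `expression`, `sensitivity`, `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(cfg = synthetic_config()) {
  if (!inherits(cfg, "synthetic_config")) {
    stop("cfg must be a synthetic_config")
  }
  grn <- simulate_grn(cfg)
  se <- simulate_expression(grn, cfg)
  sens <- simulate_sensitivity(se$truth, se$expression, cfg)
  list(
    regulons = grn, expression = se$expression, sensitivity = sens,
    truth = se$truth, config = cfg
  )
}

#' Write a cohort to the package's standard text formats
#'
#' Emits the expression TSV, the sample-annotation sidecar, a DepMap-style
#' gene-effect CSV, one canonical regulon TSV per cancer type, and a JSON
#' ground-truth sidecar echoing the config (requires the jsonlite
#' package).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- cohort$expression
  utils::write.table(
    data.frame(gene = rownames(expr), expr, check.names = FALSE),
    file.path(dir, "expression.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  ct <- attr(expr, "cancer_type")
  utils::write.table(
    data.frame(sample_id = names(ct), cancer_type = unname(ct)),
    file.path(dir, "sample_annotation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  sens <- cohort$sensitivity
  depmap <- data.frame(
    DepMap_ID = colnames(sens),
    t(sens), check.names = FALSE
  )
  names(depmap)[-1] <- sprintf("%s (%d)", rownames(sens), seq_len(nrow(sens)))
  utils::write.csv(depmap, file.path(dir, "gene_effect.csv"), row.names = FALSE, quote = FALSE)
  for (t in names(cohort$regulons)) {
    write_regulons(cohort$regulons[[t]], file.path(dir, paste0("regulons_", t, ".tsv")))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      cohort$config[setdiff(names(cohort$config), character(0))],
      file.path(dir, "ground_truth_config.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
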