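#' Run the full activity-versus-expression benchmark
#'
#' For every cancer type, pairs its expression and sensitivity columns
#' with its (matched) regulon set, infers activity with the requested
#' methods, and evaluates each activity matrix and the expression
#' baseline against gene sensitivity with both approaches: quantitative
#' per-gene Pearson correlations (summarized as the mean absolute R over
#' the shared gene universe, with significance/bin/sign counts) and
#' binary essentiality via the common-language effect size with threshold
#' counts. Every predictor for a given cancer type is evaluated over the
#' identical gene set — the regulators retained at pairing time that are
#' sometimes-essential within the type — so expression and activity are
#' directly comparable.
#'
#' @param expression Genes-by-samples matrix with a named `cancer_type`
#'   attribute (or pass `cancer_types`).
#' @param sensitivity Genes-by-cell-lines matrix sharing sample
#'   identifiers with `expression`.
#' @param regulons A [regulon_set()] (used for every type) or a named
#'   list with one set per cancer type.
#' @param cancer_types Named character vector of per-sample labels;
#'   defaults to the expression attribute.
#' @param methods Activity methods to evaluate (default all six).
#' @param min_targets Passed to [build_weight_matrix()].
#' @param essential_threshold Binarization cutoff (default -0.6).
#' @param alpha Significance gate for correlations and CLES (default
#'   0.05).
#' @param cles_thresholds CLES count thresholds (default 0.7, 0.8, 0.9).
#' @param min_per_group Minimum essential and non-essential lines for
#'   CLES eligibility (default 3).
#' @param run_cles If `FALSE`, skip the binary (CLES) evaluation and
#'   report only the quantitative correlation approach.
#' @return A `benchmark_summary` list: `summary` (tibble, one row per
#'   cancer type x predictor with mean_abs_r, gene counts, significant
#'   bins, CLES counts), `records` (per-gene correlation tibble),
#'   `cles_records`, and `verdicts` (per cancer type, the winning
#'   predictor by mean |R| and by CLES > 0.7 count).
#' @export
run_benchmark <- function(expression, sensitivity, regulons,
                          cancer_types = attr(expression, "cancer_type"),
                          methods = c("ulm", "mlm", "viper", "wsum", "wmean", "consensus"),
                          min_targets = 5, essential_threshold = -0.6,
                          alpha = 0.05, cles_thresholds = c(0.7, 0.8, 0.9),
                          min_per_group = 3, run_cles = TRUE) {
  stopifnot(is.matrix(expression), is.matrix(sensitivity))
  if (is.null(cancer_types)) {
    cancer_types <- stats::setNames(
      rep("pan", ncol(expression)), colnames(expression)
    )
  }
  types <- unique(unname(cancer_types))
  summary_rows <- list()
  record_rows <- list()
  cles_rows <- list()
  verdict_rows <- list()
  for (t in types) {
    samples <- intersect(names(cancer_types)[cancer_types == t], colnames(sensitivity))
    if (length(samples) < 3) {
      next
    }
    E <- expression[, samples, drop = FALSE]
    S <- sensitivity[, samples, drop = FALSE]
    reg <- if (inherits(regulons, "regulon_set")) regulons else regulons[[t]]
    if (is.null(reg)) {
      next
    }
    res <- evaluate_combination(
      E, S, reg, t,
      methods = methods, min_targets = min_targets,
      essential_threshold = essential_threshold, alpha = alpha,
      cles_thresholds = cles_thresholds, min_per_group = min_per_group,
      run_cles = run_cles
    )
    if (is.null(res)) {
      next
    }
    summary_rows[[t]] <- res$summary
    record_rows[[t]] <- res$records
    cles_rows[[t]] <- res$cles_records
    verdict_rows[[t]] <- res$verdict
  }
  if (length(summary_rows) == 0) {
    stop("no cancer type could be evaluated")
  }
  structure(
    list(
      summary = dplyr::bind_rows(summary_rows),
      records = dplyr::bind_rows(record_rows),
      cles_records = dplyr::bind_rows(cles_rows),
      verdicts = dplyr::bind_rows(verdict_rows)
    ),
    class = "benchmark_summary"
  )
}

# one (cancer type, regulon) evaluation shared by run_benchmark and
# cross_regulon_matrix
evaluate_combination <- function(E, S, reg, type, methods, min_targets,
                                 essential_threshold, alpha,
                                 cles_thresholds, min_per_group,
                                 run_cles = TRUE) {
  wts <- tryCatch(
    suppressMessages(build_weight_matrix(reg, E, min_targets = min_targets)),
    error = function(e) NULL
  )
  if (is.null(wts)) {
    return(NULL)
  }
  calls <- binarize_essentiality(S, essential_threshold)
  se_genes <- sometimes_essential(calls, mode = "per-cancer")
  universe <- intersect(intersect(wts$regulators, se_genes), rownames(E))
  if (length(universe) == 0) {
    return(NULL)
  }
  eligible <- intersect(binary_eligible(calls, min_per_group), universe)

  base_methods <- setdiff(methods, "consensus")
  if ("consensus" %in% methods) {
    base_methods <- c("ulm", "mlm", "viper", "wsum", "wmean")
  }
  runners <- list(
    ulm = ulm_activity, mlm = mlm_activity, viper = viper_activity,
    wsum = wsum_activity, wmean = wmean_activity
  )
  acts <- lapply(runners[base_methods], function(f) f(E, wts))
  if ("consensus" %in% methods) {
    acts$consensus <- consensus_activity(acts)
  }
  acts <- acts[intersect(c("ulm", "mlm", "viper", "wsum", "wmean", "consensus"), methods)]
  predictors <- c(
    list(expression = E),
    stats::setNames(lapply(acts, unclass), paste0("activity:", names(acts)))
  )

  summary_rows <- list()
  record_rows <- list()
  cles_rows <- list()
  for (pn in names(predictors)) {
    recs <- correlate_all(predictors[[pn]], S, universe,
      predictor = pn, alpha = alpha
    )
    recs$cancer_type <- type
    ct <- if (run_cles && length(eligible) > 0) {
      cles_table(predictors[[pn]], calls, eligible,
        thresholds = cles_thresholds, alpha = alpha, predictor = pn
      )
    } else {
      list(
        records = tibble::tibble(),
        counts = stats::setNames(
          rep(0L, length(cles_thresholds)),
          paste0("cles_gt_", cles_thresholds)
        )
      )
    }
    if (nrow(ct$records) > 0) {
      ct$records$cancer_type <- type
    }
    summary_rows[[pn]] <- tibble::tibble(
      cancer_type = type, predictor = pn,
      n_genes = length(universe), n_eligible = length(eligible),
      n_samples = ncol(E),
      mean_abs_r = mean(abs(recs$r), na.rm = TRUE),
      n_significant = sum(recs$significant, na.rm = TRUE),
      n_sig_gt_0.2 = sum(recs$significant & abs(recs$r) > 0.2, na.rm = TRUE),
      n_sig_positive = sum(recs$significant & recs$sign == "positive", na.rm = TRUE),
      n_sig_negative = sum(recs$significant & recs$sign == "negative", na.rm = TRUE),
      !!!as.list(ct$counts)
    )
    record_rows[[pn]] <- recs
    cles_rows[[pn]] <- ct$records
  }
  summary <- dplyr::bind_rows(summary_rows)
  act_rows <- summary[summary$predictor != "expression", ]
  best_act <- act_rows[which.max(act_rows$mean_abs_r), ]
  verdict <- tibble::tibble(
    cancer_type = type,
    winner_mean_abs_r = if (summary$mean_abs_r[summary$predictor == "expression"] >=
      max(act_rows$mean_abs_r)) "expression" else best_act$predictor,
    best_activity = best_act$predictor,
    expression_mean_abs_r = summary$mean_abs_r[summary$predictor == "expression"],
    best_activity_mean_abs_r = best_act$mean_abs_r,
    winner_cles = if (!run_cles) {
      NA_character_
    } else if (summary$cles_gt_0.7[summary$predictor == "expression"] >=
      max(act_rows$cles_gt_0.7)) {
      "expression"
    } else {
      act_rows$predictor[which.max(act_rows$cles_gt_0.7)]
    }
  )
  list(
    summary = summary, records = dplyr::bind_rows(record_rows),
    cles_records = dplyr::bind_rows(cles_rows), verdict = verdict
  )
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf(
    "<benchmark_summary> %d cancer type(s) x %d predictor(s)\n",
    length(unique(x$summary$cancer_type)),
    length(unique(x$summary$predictor))
  ))
  print(x$verdicts)
  invisible(x)
}

# Pearson correlation of matched rows of two matrices (complete data),
# NA where either row is constant
rowwise_pearson <- function(X, Y) {
  xc <- X - rowMeans(X)
  yc <- Y - rowMeans(Y)
  den <- sqrt(rowSums(xc^2) * rowSums(yc^2))
  r <- rowSums(xc * yc) / den
  r[den == 0] <- NA_real_
  r
}

#' Cross-regulon evaluation matrix
#'
#' Evaluates every cancer type's cell lines with every cancer type's
#' regulon, returning the cancer-type by regulon matrix of mean absolute
#' Pearson correlations between activity (one method) and sensitivity.
#' Matched cells sit on the diagonal; feed the result to
#' [matched_vs_mismatched()] to test whether matched networks outperform
#' mismatched ones. For comparability across regulon columns, each row's
#' gene universe is the intersection of the type's sometimes-essential
#' regulators across all regulon columns.
#'
#' @inheritParams run_benchmark
#' @param method Single activity method to use (default `"ulm"`).
#' @return Numeric matrix (cancer types x regulon sources) of mean |R|;
#'   cells that could not be evaluated are `NA`.
#' @export
cross_regulon_matrix <- function(expression, sensitivity, regulons,
                                 cancer_types = attr(expression, "cancer_type"),
                                 method = "ulm", min_targets = 5,
                                 essential_threshold = -0.6) {
  stopifnot(is.list(regulons), length(regulons) >= 2, !is.null(names(regulons)))
  types <- unique(unname(cancer_types))
  reg_names <- names(regulons)
  out <- matrix(NA_real_,
    nrow = length(types), ncol = length(reg_names),
    dimnames = list(types, reg_names)
  )
  runners <- list(
    ulm = ulm_activity, mlm = mlm_activity, viper = viper_activity,
    wsum = wsum_activity, wmean = wmean_activity
  )
  if (!method %in% names(runners)) {
    stop("method must be one of: ", paste(names(runners), collapse = ", "))
  }
  for (t in types) {
    samples <- intersect(names(cancer_types)[cancer_types == t], colnames(sensitivity))
    if (length(samples) < 3) {
      next
    }
    E <- expression[, samples, drop = FALSE]
    S <- sensitivity[, samples, drop = FALSE]
    calls <- binarize_essentiality(S, essential_threshold)
    se_genes <- sometimes_essential(calls, mode = "per-cancer")
    for (g in reg_names) {
      wts <- tryCatch(
        suppressMessages(build_weight_matrix(regulons[[g]], E, min_targets = min_targets)),
        error = function(e) NULL
      )
      if (is.null(wts)) {
        next
      }
      universe <- intersect(wts$regulators, se_genes)
      if (length(universe) == 0) {
        next
      }
      A <- runners[[method]](E, wts)
      r <- rowwise_pearson(
        unclass(A)[universe, , drop = FALSE],
        S[universe, colnames(A), drop = FALSE]
      )
      out[t, g] <- mean(abs(r), na.rm = TRUE)
    }
  }
  out
}
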