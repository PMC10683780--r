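#' Construct a regulon set
#'
#' A regulon set is a weighted, signed collection of regulator-to-target
#' edges from one network source. It is stored as a data frame with columns
#' `regulator`, `target`, `weight` (non-negative magnitude) and `mor`
#' (signed mode of regulation in \[-1, 1\]; -1 = inhibition, +1 = activation),
#' carrying the source dialect and cancer-type label as attributes.
#'
#' Duplicate (regulator, target) pairs are resolved by keeping the edge with
#' the largest absolute weight. Self-edges (regulator == target) are allowed
#' but counted and reported.
#'
#' @param regulator,target Character vectors of gene symbols.
#' @param weight Non-negative edge magnitudes (recycled).
#' @param mor Signed mode of regulation in \[-1, 1\] (recycled).
#' @param source Source dialect tag, e.g. `"aracne"`, `"grndb"`,
#'   `"dorothea"`, `"synthetic"`, `"canonical"`.
#' @param cancer_type Cancer-type label, or `"pan"` for type-agnostic sets.
#' @param needs_sign Logical; `TRUE` when `mor` is a +1 placeholder awaiting
#'   [infer_mor_sign()] (the unsigned GENIE3-weight dialect).
#' @return An object of class `regulon_set`.
#' @export
regulon_set <- function(regulator, target, weight = 1, mor = 1,
                        source = "synthetic", cancer_type = "pan",
                        needs_sign = FALSE) {
  stopifnot(length(regulator) == length(target))
  df <- data.frame(
    regulator = as.character(regulator),
    target = as.character(target),
    weight = rep_len(as.numeric(weight), length(regulator)),
    mor = rep_len(as.numeric(mor), length(regulator)),
    stringsAsFactors = FALSE
  )
  if (any(df$weight < 0, na.rm = TRUE)) {
    stop("edge weights must be non-negative")
  }
  if (any(abs(df$mor) > 1 + 1e-12, na.rm = TRUE)) {
    stop("mode of regulation must lie in [-1, 1]")
  }
  df <- dedup_edges(df)
  n_self <- sum(df$regulator == df$target)
  if (n_self > 0) {
    message(n_self, " self-edge(s) present (kept, flagged)")
  }
  structure(df,
    class = c("regulon_set", "data.frame"),
    source = source, cancer_type = cancer_type, needs_sign = needs_sign
  )
}

# keep the max-|weight| edge among duplicated (regulator, target) pairs
dedup_edges <- function(df) {
  key <- paste(df$regulator, df$target, sep = "\r")
  if (!anyDuplicated(key)) {
    return(df)
  }
  ord <- order(key, -abs(df$weight))
  df <- df[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  message(sum(!keep), " duplicate (regulator, target) pair(s) collapsed, keeping max |weight|")
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.regulon_set <- function(x, ...) {
  cat(sprintf(
    "<regulon_set> %d edges, %d regulators | source: %s | cancer type: %s\n",
    nrow(x), length(unique(x$regulator)),
    attr(x, "source"), attr(x, "cancer_type")
  ))
  invisible(x)
}

.dialect_columns <- list(
  aracne = c(regulator = "regulator", target = "target",
             mor = "mor", likelihood = "likelihood"),
  grndb = c(regulator = "TF", target = "gene", weight = "weight"),
  dorothea = c(regulator = "tf", target = "target", confidence = "confidence"),
  canonical = c(regulator = "regulator", target = "target",
                weight = "weight", mor = "mor")
)

#' Parse a regulon table from delimited text
#'
#' Reads a regulator-to-target edge table in one of four dialects and
#' normalizes it to the internal weighted-signed representation:
#'
#' * `"aracne"`: columns `regulator`, `target`, `mor`, `likelihood`. The
#'   likelihood becomes the weight; `mor` keeps its raw (possibly
#'   fractional) value until [update_mor_aracne()] is applied.
#' * `"grndb"`: columns `TF`, `gene`, `weight` (a GENIE3-style importance
#'   with no direction). Edges receive `mor = +1` as a placeholder and the
#'   set is flagged `needs_sign`; use [infer_mor_sign()] to resolve signs.
#' * `"dorothea"`: columns `tf`, `target`, `confidence` and optionally
#'   `mor`. Curated edges carry weight 1; when no `mor` column is present
#'   the sign defaults to +1. `confidence_levels` restricts to a subset of
#'   the A-E grades (e.g. `c("A","B","C")` for high-confidence regulons).
#' * `"canonical"`: the package's own output format, columns `regulator`,
#'   `target`, `weight`, `mor`.
#'
#' The field separator (tab or comma) is sniffed from the header. Rows with
#' a missing regulator or target are dropped and counted.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect One of `"aracne"`, `"grndb"`, `"dorothea"`, `"canonical"`.
#' @param confidence_levels Optional subset of `c("A","B","C","D","E")`;
#'   only valid for the dorothea dialect.
#' @param cancer_type Cancer-type label attached to the returned set.
#' @return A [regulon_set()].
#' @export
parse_regulons <- function(path, dialect = c("aracne", "grndb", "dorothea", "canonical"),
                           confidence_levels = NULL, cancer_type = "pan") {
  dialect <- tryCatch(match.arg(dialect), error = function(e) {
    stop("unknown regulon dialect: ", paste(dialect, collapse = ", "), call. = FALSE)
  })
  if (!is.null(confidence_levels) && dialect != "dorothea") {
    stop("confidence_levels is only applicable to the dorothea dialect")
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path,
    header = TRUE, sep = sep, quote = "\"",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  cols <- .dialect_columns[[dialect]]
  missing_cols <- setdiff(unname(cols), names(tab))
  if (dialect == "dorothea") {
    missing_cols <- setdiff(missing_cols, character(0))
  }
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "regulon table '%s' lacks required column(s) for dialect '%s': %s",
      path, dialect, paste(missing_cols, collapse = ", ")
    ))
  }

  reg <- tab[[cols[["regulator"]]]]
  tgt <- tab[[cols[["target"]]]]
  bad <- is.na(reg) | reg == "" | is.na(tgt) | tgt == ""
  if (any(bad)) {
    message(sum(bad), " row(s) with missing regulator or target dropped")
    tab <- tab[!bad, , drop = FALSE]
    reg <- reg[!bad]
    tgt <- tgt[!bad]
  }

  needs_sign <- FALSE
  if (dialect == "aracne") {
    weight <- as.numeric(tab$likelihood)
    mor <- as.numeric(tab$mor)
  } else if (dialect == "grndb") {
    weight <- as.numeric(tab$weight)
    mor <- rep(1, length(reg))
    needs_sign <- TRUE
  } else if (dialect == "dorothea") {
    if (!is.null(confidence_levels)) {
      keep <- tab$confidence %in% confidence_levels
      tab <- tab[keep, , drop = FALSE]
      reg <- reg[keep]
      tgt <- tgt[keep]
    }
    weight <- rep(1, length(reg))
    mor <- if ("mor" %in% names(tab)) sign(as.numeric(tab$mor)) else rep(1, length(reg))
  } else {
    weight <- as.numeric(tab$weight)
    mor <- as.numeric(tab$mor)
  }

  if (length(reg) == 0) {
    warning("regulon table '", path, "' yielded zero edges")
    out <- structure(
      data.frame(regulator = character(), target = character(),
                 weight = numeric(), mor = numeric(), stringsAsFactors = FALSE),
      class = c("regulon_set", "data.frame"),
      source = dialect, cancer_type = cancer_type, needs_sign = needs_sign
    )
    return(out)
  }
  regulon_set(reg, tgt, weight, mor,
    source = dialect, cancer_type = cancer_type, needs_sign = needs_sign
  )
}

#' Fold the ARACNe mode of regulation into a sign
#'
#' ARACNe-style tables report a likelihood and a fractional mode of
#' regulation per edge. The effective signed weight used downstream is
#' `likelihood * sign(mor)`: the likelihood stays as the weight and the
#' mode of regulation is collapsed to its sign. Edges whose raw mode of
#' regulation is exactly zero keep `mor = 0` (they contribute nothing to
#' signed scores) and are flagged in the `zero_mor` column rather than
#' dropped, so regulon sizes are unchanged.
#'
#' @param reg A [regulon_set()] parsed with the aracne dialect.
#' @return The regulon set with `mor` in \{-1, 0, +1\} and a `zero_mor`
#'   flag column.
#' @export
update_mor_aracne <- function(reg) {
  stopifnot(inherits(reg, "regulon_set"))
  if (any(reg$weight < 0)) {
    stop("negative likelihood encountered")
  }
  zero <- reg$mor == 0
  if (any(zero)) {
    message(sum(zero), " edge(s) with zero mode of regulation flagged")
  }
  reg$mor <- sign(reg$mor)
  reg$zero_mor <- zero
  reg
}

#' Infer edge signs from a reference expression matrix
#'
#' Unsigned regulon dialects (GENIE3-style weights) carry no direction of
#' regulation. For each edge this computes the Spearman rank correlation
#' (midranks for ties) between the regulator's and the target's expression
#' across the reference samples and sets `mor = sign(rho)`. Edges whose
#' regulator or target is absent from the matrix, or whose expression is
#' constant (rho undefined), are dropped and counted.
#'
#' @param reg A [regulon_set()] flagged as needing signs.
#' @param reference_expression Genes-by-samples numeric matrix with at
#'   least 3 samples; conventionally the same cohort the network was
#'   inferred from.
#' @return The regulon set with resolved `mor` signs and `needs_sign`
#'   cleared.
#' @export
infer_mor_sign <- function(reg, reference_expression) {
  stopifnot(inherits(reg, "regulon_set"), is.matrix(reference_expression))
  if (ncol(reference_expression) < 3) {
    stop("reference expression matrix must have at least 3 samples")
  }
  genes <- rownames(reference_expression)
  present <- reg$regulator %in% genes & reg$target %in% genes
  if (any(!present)) {
    message(sum(!present), " edge(s) dropped: regulator or target absent from expression matrix")
    reg <- reg[present, , drop = FALSE]
  }
  if (nrow(reg) == 0) {
    attr(reg, "needs_sign") <- FALSE
    return(reg)
  }
  rho <- vapply(seq_len(nrow(reg)), function(i) {
    x <- reference_expression[reg$regulator[i], ]
    y <- reference_expression[reg$target[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y, method = "spearman")
  }, numeric(1))
  degenerate <- is.na(rho)
  if (any(degenerate)) {
    message(sum(degenerate), " edge(s) dropped: zero variance (Spearman undefined)")
  }
  reg <- reg[!degenerate, , drop = FALSE]
  reg$mor <- sign(rho[!degenerate])
  rownames(reg) <- NULL
  attr(reg, "needs_sign") <- FALSE
  reg
}

#' Stratify regulators by regulon size and target uniqueness
#'
#' Assigns each regulator (pooled over the supplied sets) a size class —
#' small (<= 20 targets), medium (21-100), large (> 100) — and a
#' unique-target class based on the fraction of its targets regulated by no
#' other tested regulator: `none` (fraction 0), `low` (0 < fraction <=
#' 0.10), `high` (> 0.10). Uniqueness is computed against the union of all
#' regulators' target lists across the supplied sets.
#'
#' @param sets A [regulon_set()] or list of them.
#' @return A tibble with one row per regulator: `regulator`, `n_targets`,
#'   `size_class`, `unique_fraction`, `unique_class`.
#' @export
stratify_regulons <- function(sets) {
  if (inherits(sets, "regulon_set")) {
    sets <- list(sets)
  }
  edges <- do.call(rbind, lapply(sets, function(s) {
    data.frame(regulator = s$regulator, target = s$target, stringsAsFactors = FALSE)
  }))
  edges <- unique(edges)
  targets_by_reg <- split(edges$target, edges$regulator)
  regs <- names(targets_by_reg)
  out <- lapply(regs, function(r) {
    tg <- unique(targets_by_reg[[r]])
    others <- unique(edges$target[edges$regulator != r])
    uf <- sum(!(tg %in% others)) / length(tg)
    tibble::tibble(
      regulator = r,
      n_targets = length(tg),
      size_class = if (length(tg) <= 20) "small" else if (length(tg) <= 100) "medium" else "large",
      unique_fraction = uf,
      unique_class = if (uf == 0) "none" else if (uf <= 0.10) "low" else "high"
    )
  })
  dplyr::bind_rows(out)
}

#' Write a regulon set as a canonical TSV
#'
#' @param reg A [regulon_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regulons <- function(reg, path) {
  stopifnot(inherits(reg, "regulon_set"))
  out <- data.frame(
    regulator = reg$regulator, target = reg$target,
    weight = reg$weight, mor = reg$mor,
    source = attr(reg, "source"), cancer_type = attr(reg, "cancer_type"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
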