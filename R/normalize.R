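expr_matrix <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$probe_id %||% expr$gene
  m
}

matrix_expr <- function(m, id_col, ids) {
  out <- tibble::as_tibble(m)
  out[[id_col]] <- ids
  out[, c(id_col, setdiff(names(out), id_col))]
}

#' Bring an expression table onto the linear scale
#'
#' Samples declared `log2` are transformed value -> 2^value; `linear`
#' samples pass through unchanged. Every sample column must have a declared
#' scale: studies whose encoding is not stated cannot be integrated and are
#' rejected, mirroring the usual meta-analysis exclusion rule.
#'
#' @param expr Expression tibble from [read_expression()] (first column
#'   `probe_id`, one column per sample).
#' @param scales Named character vector mapping sample id to `"linear"` or
#'   `"log2"`, or a `tx_manifest` (its `sample_id`/`scale` columns are used).
#' @return The expression tibble on the linear scale.
#' @export
linearize_expression <- function(expr, scales) {
  if (inherits(scales, "tx_manifest") || is.data.frame(scales)) {
    scales <- setNames(scales$scale, scales$sample_id)
  }
  samples <- names(expr)[-1]
  missing <- samples[!samples %in% names(scales) | is.na(scales[samples])]
  if (length(missing) > 0) {
    abort(paste0("No declared scale for sample(s): ", paste(missing, collapse = ", ")),
          class = "txmap_validation_error")
  }
  for (s in samples) {
    if (scales[[s]] == "log2") {
      expr[[s]] <- 2^expr[[s]]
    } else if (any(expr[[s]] < 0, na.rm = TRUE)) {
      abort(paste0("Negative linear expression values in sample ", s),
            class = "txmap_validation_error")
    }
  }
  expr
}

#' Quantile-normalize samples within one dataset
#'
#' Forces every sample of a dataset onto a common intensity distribution:
#' the reference is the mean of the samples' sorted value vectors, so after
#' normalization each complete sample's sorted values equal the reference
#' while within-sample rank order is preserved. Ties receive the mean of the
#' reference values at the tied ranks, and missing data points are ignored
#' (samples of unequal depth are matched through interpolation on a common
#' quantile grid) and remain missing. Delegates to
#' [limma::normalizeQuantiles()], which implements exactly this rule.
#'
#' A sample with fewer than two present values carries no distribution to
#' normalize and is passed through unchanged with a warning.
#'
#' @param expr Linear-scale expression tibble (first column `probe_id`).
#' @return The normalized expression tibble.
#' @export
normalize_quantiles_within <- function(expr) {
  m <- expr_matrix(expr)
  if (ncol(m) == 0) return(expr)
  n_present <- colSums(!is.na(m))
  thin <- n_present < 2
  if (any(thin)) {
    warn(paste0("Sample(s) with < 2 present values passed through unnormalized: ",
                paste(colnames(m)[thin], collapse = ", ")))
  }
  use <- !thin
  if (sum(use) >= 1) {
    m[, use] <- limma::normalizeQuantiles(m[, use, drop = FALSE], ties = TRUE)
  }
  matrix_expr(m, names(expr)[1], expr[[1]])
}

#' Scale gene-level dataset tables to a common median
#'
#' Each dataset is multiplied by the single positive factor that brings the
#' median of all its present values to `target_median`, so relative values
#' within a dataset are untouched while datasets from different platforms
#' become directly comparable.
#'
#' @param tables Named list of gene-by-sample tibbles (first column `gene`),
#'   one per dataset, or a single such tibble.
#' @param target_median The common median (default 1).
#' @return The scaled table(s), in the same shape as the input.
#' @export
scale_to_median <- function(tables, target_median = 1) {
  one <- is.data.frame(tables)
  if (one) tables <- list(tables)
  out <- lapply(tables, function(tbl) {
    m <- as.matrix(tbl[, -1, drop = FALSE])
    med <- median(m, na.rm = TRUE)
    if (!is.finite(med) || med == 0) {
      abort("Cannot scale a dataset whose median expression is zero.",
            class = "txmap_validation_error")
    }
    tbl[, -1] <- tbl[, -1] * (target_median / med)
    tbl
  })
  if (one) out[[1]] else out
}
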