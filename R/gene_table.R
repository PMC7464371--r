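#' Collapse probe-level expression to gene symbols
#'
#' Per sample, a gene's value is the arithmetic mean of the present values of
#' the probes annotated to it; a gene none of whose probes has a value in a
#' sample gets no value there (missing, not zero). Probes with no gene
#' symbol in the annotation are dropped.
#'
#' @param expr Normalized linear expression tibble (first column `probe_id`).
#' @param annotation Platform annotation tibble from
#'   [read_platform_annotation()].
#' @param platform_id Optional platform label; when given, the annotation is
#'   restricted to it and an empty restriction is an error (platform
#'   mismatch).
#' @return A gene-by-sample tibble (first column `gene`), genes sorted by
#'   symbol.
#' @export
collapse_probes <- function(expr, annotation, platform_id = NULL) {
  if (!is.null(platform_id) && "platform_id" %in% names(annotation)) {
    annotation <- annotation[annotation$platform_id == platform_id, , drop = FALSE]
    if (nrow(annotation) == 0) {
      abort(paste0("Annotation has no probes for platform ", platform_id),
            class = "txmap_validation_error")
    }
  }
  sym <- setNames(annotation$gene_symbol, annotation$probe_id)
  keep <- expr$probe_id %in% names(sym)
  m <- expr_matrix(expr[keep, , drop = FALSE])
  genes <- sym[expr$probe_id[keep]]
  if (nrow(m) == 0) {
    return(matrix_expr(m, "gene", character()))
  }
  present <- !is.na(m)
  vals <- ifelse(present, m, 0)
  sums <- rowsum(vals, genes)
  counts <- rowsum(present + 0, genes)
  means <- sums / counts
  means[counts == 0] <- NA_real_
  ord <- order(rownames(sums))
  matrix_expr(means[ord, , drop = FALSE], "gene", rownames(sums)[ord])
}

#' Pool samples into a per-gene expression profile
#'
#' A pool's value for a gene is the mean of every sample-level gene value
#' available for that gene across all datasets in the pool, each data point
#' weighted equally; `data_points` counts the contributing values. Genes
#' observed fewer than `sample_number` times are removed — the "sample
#' number" filter that keeps single-measurement genes out of cross-dataset
#' comparisons.
#'
#' @param gene_tables Named list of gene-by-sample tibbles (scaled to a
#'   common median), one per dataset, or a single tibble.
#' @param manifest A `tx_manifest` naming the samples.
#' @param pool Pool label (see [pool_samples()]).
#' @param sample_number Minimum data points per gene (default 2).
#' @return A tibble `(gene, value, data_points)` of class `tx_pool` with
#'   attributes `pool` and `n_samples`.
#' @export
pool_expression <- function(gene_tables, manifest, pool, sample_number = 2L) {
  if (is.data.frame(gene_tables)) gene_tables <- list(gene_tables)
  ids <- pool_samples(manifest, pool)
  if (length(ids) == 0) {
    abort(paste0("Pool ", pool, " contains no samples."),
          class = "txmap_validation_error")
  }
  pieces <- purrr::map(gene_tables, function(tbl) {
    cols <- intersect(names(tbl)[-1], ids)
    if (length(cols) == 0) return(NULL)
    m <- as.matrix(tbl[, cols, drop = FALSE])
    tibble::tibble(
      gene = tbl$gene,
      sum = rowSums(m, na.rm = TRUE),
      n = rowSums(!is.na(m))
    )
  })
  long <- dplyr::bind_rows(pieces)
  if (nrow(long) == 0) {
    abort(paste0("No expression data found for samples of pool ", pool),
          class = "txmap_validation_error")
  }
  out <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(sum = sum(.data$sum), data_points = sum(.data$n), .groups = "drop") |>
    dplyr::filter(.data$data_points >= sample_number) |>
    dplyr::mutate(value = .data$sum / .data$data_points) |>
    dplyr::select("gene", "value", "data_points") |>
    dplyr::arrange(.data$gene)
  structure(out, pool = pool, n_samples = length(ids),
            class = c("tx_pool", class(out)))
}

#' Per-gene expression ratios between two pools
#'
#' Restricted to genes present in both pooled profiles; `ratio` is the pool-A
#' value over the pool-B value. Genes with a zero denominator carry no
#' defined ratio and are excluded with a warning giving the count.
#'
#' @param pool_a,pool_b Pooled profiles from [pool_expression()].
#' @return A tibble `(gene, value_a, value_b, ratio, tail)` with `tail`
#'   initialized to `"none"`.
#' @export
gene_ratios <- function(pool_a, pool_b) {
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(pool_a), "gene", value_a = "value"),
    dplyr::select(tibble::as_tibble(pool_b), "gene", value_b = "value"),
    by = "gene"
  )
  zero <- joined$value_b == 0
  if (any(zero)) {
    warn(sprintf("%d gene(s) with zero denominator excluded from the ratio table.",
                 sum(zero)))
    joined <- joined[!zero, , drop = FALSE]
  }
  dplyr::mutate(joined, ratio = .data$value_a / .data$value_b, tail = "none")
}

#' Flag over- and underexpressed tail genes
#'
#' Flags the `ceiling(tail_fraction * N)` genes with the largest ratios as
#' `"over"` and the same number with the smallest ratios as `"under"`; these
#' tails define the gene universe the segment enrichment test draws from.
#' Ties at a tail boundary are broken by gene symbol order, deterministically,
#' with a warning.
#'
#' @param ratios Ratio table from [gene_ratios()].
#' @param tail_fraction Fraction per tail (default 0.025).
#' @return The ratio table with `tail` set to `"over"`, `"under"` or
#'   `"none"`.
#' @export
call_tails <- function(ratios, tail_fraction = 0.025) {
  n <- nrow(ratios)
  if (n == 0) abort("Empty ratio table.", class = "txmap_validation_error")
  if (tail_fraction <= 0 || tail_fraction >= 0.5) {
    abort("`tail_fraction` must lie strictly between 0 and 0.5.")
  }
  m <- ceiling(tail_fraction * n)
  if (n < 1 / tail_fraction) {
    warn(sprintf("Only %d genes in the ratio table; flagging one gene per tail.", n))
  }
  # over tail: largest ratios, ties -> lexicographically first symbols;
  # under tail: smallest ratios, ties -> lexicographically last (the mirror)
  over_ord <- order(-ratios$ratio, ratios$gene)
  under_ord <- order(ratios$ratio, -xtfrm(ratios$gene))
  tie <- function(ord, r) {
    n > m && r[ord[m]] == r[ord[m + 1]]
  }
  if (tie(over_ord, ratios$ratio) || tie(under_ord, ratios$ratio)) {
    warn("Tied ratios at a tail boundary; ties broken by gene symbol order.")
  }
  tail <- rep("none", n)
  over_idx <- over_ord[seq_len(m)]
  under_idx <- setdiff(under_ord[seq_len(m)], over_idx)
  tail[over_idx] <- "over"
  tail[under_idx] <- "under"
  ratios$tail <- tail
  ratios
}
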