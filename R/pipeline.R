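#' Validate that the parts of a run fit together
#'
#' Checks that expression data are present, every sample column is in the
#' manifest, every manifest platform has an annotation, and loci exist.
#'
#' @param manifest A `tx_manifest`.
#' @param expression Named list of probe expression tibbles, one per dataset.
#' @param annotation Combined platform annotation tibble.
#' @param loci Gene locus tibble.
#' @return Invisibly `TRUE`; aborts on inconsistency.
#' @export
validate_inputs <- function(manifest, expression, annotation, loci) {
  if (length(expression) == 0) {
    abort("No expression datasets supplied.", class = "txmap_validation_error")
  }
  if (nrow(loci) == 0) {
    abort("Empty gene locus table.", class = "txmap_validation_error")
  }
  samples <- unlist(lapply(expression, function(e) names(e)[-1]))
  unknown <- setdiff(samples, manifest$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("Expression sample(s) absent from the manifest: ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "txmap_validation_error")
  }
  missing_pf <- setdiff(unique(manifest$platform_id), unique(annotation$platform_id))
  if (length(missing_pf) > 0) {
    abort(paste0("Manifest platform(s) without annotation: ",
                 paste(missing_pf, collapse = ", ")),
          class = "txmap_validation_error")
  }
  invisible(TRUE)
}

# dataset_id -> platform_id lookup from a manifest
dataset_platforms <- function(manifest) {
  pf <- unique(manifest[, c("dataset_id", "platform_id")])
  setNames(pf$platform_id, pf$dataset_id)
}

#' Normalize datasets and collapse them to gene level
#'
#' Per dataset: linearize declared log2 samples, quantile-normalize the
#' samples against each other, collapse probes to gene symbols; then scale
#' every dataset's gene table to a common median so values are comparable
#' across platforms.
#'
#' @param expression Named list of probe expression tibbles per dataset.
#' @param manifest A `tx_manifest` (provides per-sample scale and platform).
#' @param annotation Combined platform annotation tibble.
#' @param target_median Common median after inter-dataset scaling.
#' @return Named list of gene-by-sample tibbles, one per dataset.
#' @export
normalize_study <- function(expression, manifest, annotation, target_median = 1) {
  platforms <- dataset_platforms(manifest)
  tables <- lapply(names(expression), function(ds) {
    expr <- linearize_expression(expression[[ds]], manifest)
    expr <- normalize_quantiles_within(expr)
    collapse_probes(expr, annotation, platform_id = platforms[[ds]])
  })
  names(tables) <- names(expression)
  scale_to_median(tables, target_median)
}

#' Run a complete two-pool map analysis
#'
#' Orchestrates validate, normalize, pool, map. Both resolutions are always
#' produced: the default 500 kb / 250 kb segment map and the single-gene
#' 12.5 kb / 6.25 kb map whose significant windows are merged into gene
#' spans. If `out_dir` is given, writes `segments_default.tsv`,
#' `segments_single_gene.tsv`, `significant.bed`, `summary.json` and
#' `run.log` there; a failure removes any partial output.
#'
#' @param manifest A `tx_manifest`.
#' @param expression Named list of probe expression tibbles per dataset.
#' @param annotation Combined platform annotation tibble.
#' @param loci Gene locus tibble.
#' @param chrom_lengths Optional tibble `(chrom, length)`; defaults to the
#'   lengths implied by `loci`.
#' @param pool_a,pool_b Pool labels compared as A vs B (numerator /
#'   denominator).
#' @param config A [tx_config()]; its window geometry is used for the
#'   default-resolution map.
#' @param out_dir Optional output directory.
#' @return A list of class `tx_report`: `map_default`, `map_single_gene`,
#'   `spans`, `summary` (named list of counts), `log` (character lines).
#' @export
run_map_analysis <- function(manifest, expression, annotation, loci,
                             chrom_lengths = NULL, pool_a = "A", pool_b = "B",
                             config = tx_config(), out_dir = NULL) {
  if (identical(pool_a, pool_b)) {
    abort("The two pools must be distinct.", class = "txmap_validation_error")
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)),
            class = "txmap_stage_error", parent = e)
    })
  }
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  stage("validate", validate_inputs(manifest, expression, annotation, loci))
  note("validate: %d datasets, %d manifest samples, %d loci",
       length(expression), nrow(manifest), nrow(loci))

  tables <- stage("normalize", normalize_study(expression, manifest, annotation,
                                               config$target_median))
  for (ds in names(tables)) {
    note("normalize: dataset %s -> %d genes x %d samples",
         ds, nrow(tables[[ds]]), ncol(tables[[ds]]) - 1)
  }

  pools <- stage("pool", list(
    a = pool_expression(tables, manifest, pool_a, config$sample_number),
    b = pool_expression(tables, manifest, pool_b, config$sample_number)
  ))
  note("pool: %s = %d samples, %d data points over %d genes",
       pool_a, attr(pools$a, "n_samples"), sum(pools$a$data_points), nrow(pools$a))
  note("pool: %s = %d samples, %d data points over %d genes",
       pool_b, attr(pools$b, "n_samples"), sum(pools$b$data_points), nrow(pools$b))

  map_default <- stage("map_default",
                       transcriptome_map(pools$a, pools$b, loci, chrom_lengths, config))
  cfg_sg <- tx_config(tail_fraction = config$tail_fraction,
                      min_tail_genes = config$min_tail_genes,
                      q_threshold = config$q_threshold,
                      sample_number = config$sample_number,
                      target_median = config$target_median,
                      mode = "single_gene")
  map_single <- stage("map_single_gene",
                      transcriptome_map(pools$a, pools$b, loci, chrom_lengths, cfg_sg))
  note("map: %d mapped loci in the ratio table", map_default$n_genes)
  note("map default: %d segments, %d significant (%d over, %d under)",
       nrow(map_default$segments), sum(map_default$segments$significant),
       sum(map_default$segments$significant & map_default$segments$direction == "over"),
       sum(map_default$segments$significant & map_default$segments$direction == "under"))
  note("map single-gene: %d segments, %d significant, %d merged spans",
       nrow(map_single$segments), sum(map_single$segments$significant),
       nrow(map_single$spans))

  summary <- list(
    pool_a = pool_a, pool_b = pool_b,
    n_samples_a = attr(pools$a, "n_samples"),
    n_samples_b = attr(pools$b, "n_samples"),
    data_points_a = sum(pools$a$data_points),
    data_points_b = sum(pools$b$data_points),
    mapped_loci = map_default$n_genes,
    n_segments_default = nrow(map_default$segments),
    n_significant_default = sum(map_default$segments$significant),
    n_significant_over = sum(map_default$segments$significant &
                               map_default$segments$direction == "over"),
    n_significant_under = sum(map_default$segments$significant &
                                map_default$segments$direction == "under"),
    n_regions_default = nrow(map_default$spans),
    n_regions_over = sum(map_default$spans$direction == "over"),
    n_regions_under = sum(map_default$spans$direction == "under"),
    n_spans_single_gene = nrow(map_single$spans),
    n_spans_over = sum(map_single$spans$direction == "over"),
    n_spans_under = sum(map_single$spans$direction == "under")
  )

  report <- structure(
    list(map_default = map_default, map_single_gene = map_single,
         spans = map_single$spans, summary = summary, log = log),
    class = "tx_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

format_gene_marks <- function(genes, ratios) {
  tail_of <- setNames(ratios$tail, ratios$gene)
  med <- median(ratios$ratio)
  r_of <- setNames(ratios$ratio, ratios$gene)
  vapply(genes, function(gs) {
    marks <- vapply(gs, function(g) {
      tl <- tail_of[[g]] %||% "none"
      sign <- if (!g %in% names(r_of)) "" else if (r_of[[g]] >= med) "+" else "-"
      paste0(if (tl != "none") "*" else "", g, sign)
    }, character(1))
    paste(marks, collapse = " ")
  }, character(1))
}

#' Write the segment table of a map
#'
#' Tab-delimited segment records: coordinates, per-pool values, ratio,
#' tail-gene counts, p and q, direction and significance, plus the gene
#' list. In the gene list a leading `*` flags a tail gene and a trailing
#' `+`/`-` marks a gene ratio above/below the genome median ratio.
#'
#' @param map A `tx_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(map, path) {
  seg <- map$segments
  out <- dplyr::mutate(
    dplyr::select(seg, -"genes"),
    genes = format_gene_marks(seg$genes, map$ratios)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read back a segment table written by [write_segments_tsv()]
#'
#' @param path Path to the TSV.
#' @return A tibble with the serialized segment columns.
#' @export
read_segments_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    genes = readr::col_character(),
    direction = readr::col_character(),
    significant = readr::col_logical(),
    n_genes = readr::col_integer(),
    n_over = readr::col_integer(),
    n_under = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
}

#' Write significant segments as BED6
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention (`start - 1`, `end`). The name field is the
#' direction, the score is `-10 log10(q)` capped at 1000.
#'
#' @param map A `tx_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(map, path) {
  sig <- map$segments[map$segments$significant, , drop = FALSE]
  bed <- tibble::tibble(
    chrom = sig$chrom,
    start = format(sig$start - 1, scientific = FALSE, trim = TRUE),
    end = format(sig$end, scientific = FALSE, trim = TRUE),
    name = sig$direction,
    score = pmin(1000, round(-10 * log10(pmax(sig$q, 1e-100)))),
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write the gene-level span table of a map
#'
#' @param map A `tx_map` (typically single-gene mode).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spans_tsv <- function(map, path) {
  spans <- map$spans
  out <- dplyr::mutate(dplyr::select(spans, -"genes"),
                       genes = vapply(spans$genes, paste, character(1), collapse = " "))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write the full report bundle of a run
#'
#' @param report A `tx_report` from [run_map_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("segments_default.tsv", "segments_single_gene.tsv",
                            "significant.bed", "summary.json", "run.log"))
  tryCatch({
    write_segments_tsv(report$map_default, paths[1])
    write_segments_tsv(report$map_single_gene, paths[2])
    write_segments_bed(report$map_default, paths[3])
    jsonlite::write_json(report$summary, paths[4], auto_unbox = TRUE, pretty = TRUE)
    writeLines(report$log, paths[5])
    write_spans_tsv(report$map_single_gene, file.path(dir, "spans_single_gene.tsv"))
  }, error = function(e) {
    unlink(c(paths, file.path(dir, "spans_single_gene.tsv")))
    abort(paste0("Writing the report failed: ", conditionMessage(e)),
          class = "txmap_io_error", parent = e)
  })
  invisible(dir)
}
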