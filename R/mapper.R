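#' Build a sliding-window genome grid
#'
#' Windows on each chromosome start at `1 + k * shift_bp` for
#' `k = 0, 1, ...` while the start lies on the chromosome, and span
#' `window_bp` bases (1-based, inclusive ends). The last window may extend
#' past the chromosome end; gene assignment is by gene start, so no clipping
#' is needed.
#'
#' @param chrom_lengths Tibble `(chrom, length)` or a named numeric vector.
#' @param window_bp Window width in bp (default 500,000).
#' @param shift_bp Step between window starts in bp (default 250,000).
#' @return A tibble `(chrom, start, end)`, windows ordered by chromosome
#'   (as given) then start.
#' @examples
#' build_windows(c(chr1 = 600000))
#' @export
build_windows <- function(chrom_lengths, window_bp = 500000, shift_bp = 250000) {
  if (is.numeric(chrom_lengths) && !is.null(names(chrom_lengths))) {
    chrom_lengths <- tibble::tibble(chrom = names(chrom_lengths),
                                    length = unname(chrom_lengths))
  }
  if (window_bp < 1 || shift_bp < 1) {
    abort("Window and shift sizes must be positive.", class = "txmap_validation_error")
  }
  if (any(chrom_lengths$length < 1)) {
    abort("Chromosome lengths must be positive.", class = "txmap_validation_error")
  }
  purrr::map2(chrom_lengths$chrom, chrom_lengths$length, function(ch, len) {
    starts <- seq(1, len, by = shift_bp)
    tibble::tibble(chrom = ch, start = starts, end = starts + window_bp - 1)
  }) |>
    dplyr::bind_rows()
}

#' Assign gene loci to windows
#'
#' A gene belongs to every window of its chromosome whose span contains the
#' gene's start coordinate (both window boundaries inclusive). With a full
#' grid this places each gene in `window_bp / shift_bp` windows, fewer near
#' the chromosome start. Genes are ordered by start within each window.
#'
#' @param windows Window grid from [build_windows()].
#' @param loci Gene locus tibble from [read_gene_loci()].
#' @return A tibble `(chrom, start, end, gene, gene_start)`, one row per
#'   (window, gene) pair.
#' @export
assign_genes <- function(windows, loci) {
  missing_chrom <- setdiff(unique(loci$chrom), unique(windows$chrom))
  if (length(missing_chrom) > 0) {
    abort(paste0("Loci on chromosome(s) absent from the window grid: ",
                 paste(missing_chrom, collapse = ", ")),
          class = "txmap_validation_error")
  }
  if (nrow(windows) == 0 || nrow(loci) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          gene = character(), gene_start = numeric()))
  }
  window_bp <- windows$end[1] - windows$start[1] + 1
  shifts <- diff(windows$start[windows$chrom == windows$chrom[1]])
  shift_bp <- if (length(shifts) > 0) shifts[1] else window_bp
  grid_max <- setNames(
    vapply(split(windows$start, windows$chrom), max, numeric(1)),
    NULL
  )
  max_start <- vapply(split(windows$start, windows$chrom), max, numeric(1))
  # windows containing a gene start g: starts 1 + k*shift with
  # start <= g <= start + window - 1  =>  k in [ (g - window)/shift , (g - 1)/shift ]
  k_max <- pmin(floor((loci$start - 1) / shift_bp),
                (max_start[loci$chrom] - 1) / shift_bp)
  k_min <- pmax(ceiling((loci$start - window_bp) / shift_bp), 0)
  n_win <- pmax(k_max - k_min + 1, 0)
  idx <- rep(seq_len(nrow(loci)), n_win)
  ks <- unlist(purrr::map2(k_min, k_max, function(a, b) if (b >= a) seq(a, b) else numeric(0)))
  out <- tibble::tibble(
    chrom = loci$chrom[idx],
    start = 1 + ks * shift_bp,
    end = 1 + ks * shift_bp + window_bp - 1,
    gene = loci$gene[idx],
    gene_start = loci$start[idx]
  )
  chrom_order <- unique(windows$chrom)
  dplyr::arrange(out, match(.data$chrom, chrom_order), .data$start, .data$gene_start)
}

#' Segment-level expression statistics
#'
#' For every window containing at least one gene with a pooled value in both
#' pools, the segment value per pool is the mean of the pooled gene values of
#' those genes, and the segment ratio is the ratio of those two means (not
#' the mean of per-gene ratios). Windows without such genes yield no record.
#'
#' @param assignment Window-gene assignment from [assign_genes()].
#' @param pool_a,pool_b Pooled profiles from [pool_expression()].
#' @return A tibble of segment records `(chrom, start, end, n_genes, genes,
#'   value_a, value_b, ratio)`; `genes` is a list-column of gene symbols
#'   ordered by start.
#' @export
segment_stats <- function(assignment, pool_a, pool_b) {
  val_a <- setNames(pool_a$value, pool_a$gene)
  val_b <- setNames(pool_b$value, pool_b$gene)
  shared <- assignment$gene %in% names(val_a) & assignment$gene %in% names(val_b)
  hit <- assignment[shared, , drop = FALSE]
  if (nrow(hit) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          n_genes = integer(), genes = list(),
                          value_a = numeric(), value_b = numeric(), ratio = numeric()))
  }
  hit |>
    dplyr::mutate(a = val_a[.data$gene], b = val_b[.data$gene]) |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      genes = list(.data$gene[order(.data$gene_start)]),
      value_a = mean(.data$a),
      value_b = mean(.data$b),
      .groups = "drop"
    ) |>
    dplyr::mutate(ratio = .data$value_a / .data$value_b) |>
    dplyr::arrange(match(.data$chrom, unique(assignment$chrom)), .data$start)
}

#' Hypergeometric tail-gene enrichment of segments
#'
#' Tests every segment for enrichment of over- and under-tail genes against
#' the genome-wide background: drawing `n_genes` genes from a universe of
#' `N` genes of which `K` are in the given tail, `p_over` is the upper-tail
#' hypergeometric probability of observing at least the segment's over-tail
#' count (and `p_under` analogously). The segment p-value is the smaller of
#' the two, with the direction recorded; q-values are Benjamini-Hochberg
#' adjusted across all segments of the map. A segment is significant when
#' `q < q_threshold`, the winning direction contains at least
#' `min_tail_genes` tail genes, and the segment ratio agrees with the
#' direction (> 1 for over, < 1 for under).
#'
#' @param segments Segment records from [segment_stats()].
#' @param ratios Tail-called ratio table from [call_tails()].
#' @param config A [tx_config()].
#' @return The segment tibble with `n_over`, `n_under`, `p_over`, `p_under`,
#'   `p`, `q`, `direction` and `significant` columns.
#' @export
segment_significance <- function(segments, ratios, config = tx_config()) {
  if (nrow(segments) == 0) {
    return(dplyr::mutate(segments, n_over = integer(), n_under = integer(),
                         p_over = numeric(), p_under = numeric(), p = numeric(),
                         q = numeric(), direction = character(),
                         significant = logical()))
  }
  tail_of <- setNames(ratios$tail, ratios$gene)
  n_universe <- nrow(ratios)
  k_over <- sum(ratios$tail == "over")
  k_under <- sum(ratios$tail == "under")
  counts <- purrr::map(segments$genes, function(gs) {
    tl <- tail_of[gs]
    tl <- tl[!is.na(tl)]
    c(n = length(tl), over = sum(tl == "over"), under = sum(tl == "under"))
  })
  n_draw <- purrr::map_dbl(counts, "n")
  n_over <- purrr::map_dbl(counts, "over")
  n_under <- purrr::map_dbl(counts, "under")
  p_over <- phyper(n_over - 1, k_over, n_universe - k_over, n_draw, lower.tail = FALSE)
  p_under <- phyper(n_under - 1, k_under, n_universe - k_under, n_draw, lower.tail = FALSE)
  p <- pmin(p_over, p_under)
  q <- p.adjust(p, method = "BH")
  direction <- dplyr::case_when(
    p_over < p_under ~ "over",
    p_under < p_over ~ "under",
    n_over > n_under ~ "over",
    n_under > n_over ~ "under",
    TRUE ~ "none"
  )
  win_count <- ifelse(direction == "over", n_over,
                      ifelse(direction == "under", n_under, 0))
  significant <- q < config$q_threshold &
    win_count >= config$min_tail_genes &
    ((direction == "over" & segments$ratio > 1) |
       (direction == "under" & segments$ratio < 1))
  dplyr::mutate(segments,
                n_over = as.integer(n_over), n_under = as.integer(n_under),
                p_over = p_over, p_under = p_under, p = p, q = q,
                direction = direction, significant = significant)
}

#' Merge overlapping significant windows into reported spans
#'
#' On a sliding grid a differentially expressed region is usually hit by
#' several consecutive overlapping significant windows; runs of such windows
#' with the same direction (on one chromosome) are merged into a single
#' reported span: start is the smallest window start, end the largest window
#' end, the genes are the union (ordered by position), the ratio is the most
#' extreme window's ratio and the q-value the smallest. Spans are sorted by
#' decreasing ratio.
#'
#' @param segments Scored segment tibble from [segment_significance()].
#' @return A tibble `(chrom, start, end, genes, gene, n_windows, ratio, q,
#'   direction)`; `gene` is the first gene in the span.
#' @export
merge_significant_spans <- function(segments) {
  sig <- segments[segments$significant, , drop = FALSE]
  empty <- tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          genes = list(), gene = character(), n_windows = integer(),
                          ratio = numeric(), q = numeric(), direction = character())
  if (nrow(sig) == 0) return(empty)
  sig <- sig[order(match(sig$chrom, unique(segments$chrom)), sig$start), , drop = FALSE]
  new_run <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                 sig$start[-1] > sig$end[-nrow(sig)] + 1 |
                 sig$direction[-1] != sig$direction[-nrow(sig)])
  run <- cumsum(new_run)
  spans <- purrr::map(split(seq_len(nrow(sig)), run), function(i) {
    s <- sig[i, , drop = FALSE]
    best <- if (s$direction[1] == "over") which.max(s$ratio) else which.min(s$ratio)
    span_genes <- unique(unlist(s$genes))
    tibble::tibble(
      chrom = s$chrom[1], start = min(s$start), end = max(s$end),
      genes = list(span_genes), gene = span_genes[1], n_windows = nrow(s),
      ratio = s$ratio[best], q = min(s$q), direction = s$direction[1]
    )
  })
  dplyr::bind_rows(spans) |>
    dplyr::arrange(dplyr::desc(.data$ratio), .data$gene)
}

#' Build and score a transcriptome map
#'
#' The full map stage: gene ratios between the two pools, 2.5% tail calling,
#' window grid construction, per-segment aggregation, hypergeometric
#' enrichment with FDR control, and merging of overlapping significant
#' windows into reported spans. With `config = tx_config(mode =
#' "single_gene")` the grid is fine enough that a span usually corresponds
#' to a single gene.
#'
#' @param pool_a,pool_b Pooled profiles from [pool_expression()].
#' @param loci Gene locus tibble.
#' @param chrom_lengths Tibble `(chrom, length)` or named vector; defaults
#'   to the lengths implied by `loci`.
#' @param config A [tx_config()].
#' @return A `tx_map` object: a list with `segments`, `spans`, `ratios`,
#'   `config`, `pools` and `n_genes`.
#' @export
transcriptome_map <- function(pool_a, pool_b, loci, chrom_lengths = NULL,
                              config = tx_config()) {
  if (is.null(chrom_lengths)) chrom_lengths <- chromosome_lengths(loci)
  ratios <- call_tails(gene_ratios(pool_a, pool_b), config$tail_fraction)
  windows <- build_windows(chrom_lengths, config$window_bp, config$shift_bp)
  assignment <- assign_genes(windows, loci)
  segments <- segment_stats(assignment, pool_a, pool_b)
  segments <- segment_significance(segments, ratios, config)
  structure(
    list(
      segments = segments,
      spans = merge_significant_spans(segments),
      ratios = ratios,
      config = config,
      pools = c(a = attr(pool_a, "pool") %||% "A", b = attr(pool_b, "pool") %||% "B"),
      n_genes = nrow(ratios),
      data_points = c(a = sum(pool_a$data_points), b = sum(pool_b$data_points))
    ),
    class = "tx_map"
  )
}

#' Intersection of the most extreme genes of two maps
#'
#' Takes the union of the `k` most overexpressed and `k` most underexpressed
#' entries (by ratio) of each gene-level table and returns the symbols shared
#' between the two. Tables shorter than `k` contribute all their rows, with
#' a warning.
#'
#' @param x,y Gene-level span tibbles (e.g. `map$spans`), sorted by ratio.
#' @param k Number of genes per direction (default 20).
#' @return Character vector of shared gene symbols, sorted.
#' @export
top_intersection <- function(x, y, k = 20) {
  pick <- function(tbl) {
    if (nrow(tbl) < k) {
      warn(sprintf("Table has only %d rows; using all of them per direction.", nrow(tbl)))
    }
    tbl <- tbl[order(-tbl$ratio), , drop = FALSE]
    rows <- unique(c(head(seq_len(nrow(tbl)), k), tail(seq_len(nrow(tbl)), k)))
    unique(unlist(tbl$genes[rows] %||% tbl$gene[rows]))
  }
  sort(intersect(pick(x), pick(y)))
}
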