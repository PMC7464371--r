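#' @export
print.tx_map <- function(x, ...) {
  cat("<tx_map> pools", x$pools["a"], "vs", x$pools["b"],
      sprintf("(%s mode)\n", x$config$mode))
  cat(sprintf("  %d segments over %d mapped loci; %d significant (q < %g), %d merged spans\n",
              nrow(x$segments), x$n_genes, sum(x$segments$significant),
              x$config$q_threshold, nrow(x$spans)))
  invisible(x)
}

#' Tidy a transcriptome map into its segment table
#'
#' @param x A `tx_map`.
#' @param ... Unused.
#' @return The segment tibble, with the gene list flattened to a
#'   space-separated string.
#' @method tidy tx_map
#' @export
tidy.tx_map <- function(x, ...) {
  seg <- x$segments
  dplyr::mutate(dplyr::select(seg, -"genes"),
                genes = vapply(seg$genes, paste, character(1), collapse = " "))
}

#' One-row summary of a transcriptome map
#'
#' @param x A `tx_map`.
#' @param ... Unused.
#' @return A one-row tibble: pools, mode, mapped loci, segment and
#'   significance counts, and the most extreme segment ratios.
#' @method glance tx_map
#' @export
glance.tx_map <- function(x, ...) {
  seg <- x$segments
  tibble::tibble(
    pool_a = unname(x$pools["a"]),
    pool_b = unname(x$pools["b"]),
    mode = x$config$mode,
    mapped_loci = x$n_genes,
    data_points_a = unname(x$data_points["a"]),
    data_points_b = unname(x$data_points["b"]),
    n_segments = nrow(seg),
    n_significant = sum(seg$significant),
    n_spans = nrow(x$spans),
    max_ratio = if (nrow(seg)) max(seg$ratio) else NA_real_,
    min_ratio = if (nrow(seg)) min(seg$ratio) else NA_real_
  )
}

#' Plot a transcriptome map
#'
#' Segment log2 expression ratios along the genome, one facet per
#' chromosome, with significant segments highlighted.
#'
#' @param object A `tx_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tx_map
#' @export
autoplot.tx_map <- function(object, ...) {
  seg <- dplyr::mutate(object$segments,
                       mid_mb = (.data$start + .data$end) / 2 / 1e6,
                       log2_ratio = log2(.data$ratio))
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$mid_mb, y = .data$log2_ratio)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red3"),
                                 name = "significant") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(
      x = "segment midpoint (Mb)",
      y = sprintf("log2 ratio (%s / %s)", object$pools["a"], object$pools["b"]),
      title = sprintf("Transcriptome map, %s mode", object$config$mode)
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.tx_report <- function(x, ...) {
  s <- x$summary
  cat("<tx_report>", s$pool_a, "vs", s$pool_b, "\n")
  cat(sprintf("  %d + %d samples; %d + %d data points; %d mapped loci\n",
              s$n_samples_a, s$n_samples_b, s$data_points_a, s$data_points_b,
              s$mapped_loci))
  cat(sprintf("  default map: %d/%d segments significant (%d over, %d under); %d merged regions\n",
              s$n_significant_default, s$n_segments_default,
              s$n_significant_over, s$n_significant_under, s$n_regions_default))
  cat(sprintf("  single-gene map: %d merged spans (%d over, %d under)\n",
              s$n_spans_single_gene, s$n_spans_over, s$n_spans_under))
  invisible(x)
}

#' @export
print.tx_design <- function(x, ...) {
  cat("<tx_design>", x$n_chromosomes, "chromosome(s) x",
      x$genes_per_chromosome, "genes, spacing", x$gene_spacing_bp, "bp\n")
  cat(sprintf("  %d datasets; pool A %d + pool B %d samples; noise sd %.2f; dropout %.2f; seed %d\n",
              nrow(x$datasets), sum(x$datasets$n_a), sum(x$datasets$n_b),
              x$noise_sd, x$dropout_rate, x$seed))
  invisible(x)
}

#' @export
print.tx_study <- function(x, ...) {
  cat("<tx_study>", length(x$expression), "datasets,",
      nrow(x$manifest), "samples,", nrow(x$loci), "genes")
  n_spiked <- sum(x$truth$expected_ratio != 1)
  cat(if (n_spiked > 0) sprintf(", %d spiked genes\n", n_spiked) else "\n")
  invisible(x)
}
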