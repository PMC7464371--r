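#' Map analysis configuration
#'
#' Collects the tunable parameters of a sliding-window map analysis. The
#' defaults are the standard settings for a genome-wide map: 500 kb windows
#' advanced in 250 kb steps, 2.5% ratio tails, at least three tail genes per
#' significant segment, q < 0.05 and a minimum of two expression data points
#' per gene ("sample number"). `mode = "single_gene"` switches to the
#' high-resolution grid (12,500 bp windows, 6,250 bp shift) in which a
#' significant segment usually corresponds to a single gene.
#'
#' @param window_bp Window (segment) width in base pairs.
#' @param shift_bp Sliding step in base pairs; must be a divisor of
#'   `window_bp` no larger than it.
#' @param tail_fraction Fraction of the gene ratio distribution flagged as
#'   over- (top) and underexpressed (bottom); 0 < `tail_fraction` < 0.5.
#' @param min_tail_genes Minimum number of same-direction tail genes a
#'   segment must contain to be called significant.
#' @param q_threshold Benjamini-Hochberg q-value cutoff for significance.
#' @param sample_number Minimum number of sample-level data points a gene
#'   needs, per pool, to enter the pooled profile.
#' @param target_median Common median every dataset's gene table is scaled to
#'   before pooling.
#' @param mode `"default"` (500 kb / 250 kb) or `"single_gene"`
#'   (12.5 kb / 6.25 kb; forces the window geometry).
#'
#' @return A list of class `tx_config`.
#' @examples
#' tx_config()
#' tx_config(mode = "single_gene")
#' @export
tx_config <- function(window_bp = 500000L,
                      shift_bp = 250000L,
                      tail_fraction = 0.025,
                      min_tail_genes = 3L,
                      q_threshold = 0.05,
                      sample_number = 2L,
                      target_median = 1,
                      mode = c("default", "single_gene")) {
  mode <- match.arg(mode)
  if (mode == "single_gene") {
    window_bp <- 12500L
    shift_bp <- 6250L
  }
  window_bp <- as.integer(window_bp)
  shift_bp <- as.integer(shift_bp)
  if (is.na(window_bp) || window_bp < 1L || is.na(shift_bp) || shift_bp < 1L) {
    abort("`window_bp` and `shift_bp` must be positive integers.")
  }
  if (shift_bp > window_bp) {
    abort("`shift_bp` must not exceed `window_bp`.")
  }
  if (window_bp %% shift_bp != 0L) {
    abort("`shift_bp` must divide `window_bp` so that consecutive windows tile evenly.")
  }
  if (!is.numeric(tail_fraction) || tail_fraction <= 0 || tail_fraction >= 0.5) {
    abort("`tail_fraction` must lie strictly between 0 and 0.5.")
  }
  if (target_median <= 0) abort("`target_median` must be positive.")
  structure(
    list(
      window_bp = window_bp,
      shift_bp = shift_bp,
      tail_fraction = tail_fraction,
      min_tail_genes = as.integer(min_tail_genes),
      q_threshold = q_threshold,
      sample_number = as.integer(sample_number),
      target_median = target_median,
      mode = mode
    ),
    class = "tx_config"
  )
}

#' @export
print.tx_config <- function(x, ...) {
  cat("<tx_config> mode =", x$mode, "\n")
  cat(sprintf(
    "  window %s bp / shift %s bp; tails %.3f; >=%d tail genes; q < %g; sample number %d\n",
    format(x$window_bp, big.mark = ","), format(x$shift_bp, big.mark = ","),
    x$tail_fraction, x$min_tail_genes, x$q_threshold, x$sample_number
  ))
  invisible(x)
}
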