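# Shared fixtures and independent oracles used across the suite.

study_manifest_path <- function() {
  system.file("extdata", "adsc_manifest.tsv", package = "txmap")
}

write_tsv_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Minimal valid manifest tibble.
tiny_manifest <- function(n = 2, pool = c("A", "B"), sex = c("M", "F")) {
  as_tx_manifest(tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    dataset_id = "d1",
    platform_id = "pf1",
    sex = rep_len(sex, n),
    pool = rep_len(pool, n),
    scale = "linear"
  ))
}

# Pooled profile with given gene values (data_points defaulting to 2).
make_pool <- function(genes, values, pool = "A", data_points = 2L) {
  structure(
    tibble::tibble(gene = genes, value = values,
                   data_points = rep_len(data_points, length(genes))),
    pool = pool, n_samples = 2L,
    class = c("tx_pool", class(tibble::tibble()))
  )
}

# Brute-force segment aggregation: re-scan every locus for every window.
oracle_segment_stats <- function(loci, pool_a, pool_b, chrom_lengths,
                                 window_bp, shift_bp) {
  val_a <- stats::setNames(pool_a$value, pool_a$gene)
  val_b <- stats::setNames(pool_b$value, pool_b$gene)
  rows <- list()
  for (i in seq_len(nrow(chrom_lengths))) {
    ch <- chrom_lengths$chrom[i]
    for (s in seq(1, chrom_lengths$length[i], by = shift_bp)) {
      e <- s + window_bp - 1
      in_win <- loci$chrom == ch & loci$start >= s & loci$start <= e &
        loci$gene %in% names(val_a) & loci$gene %in% names(val_b)
      if (!any(in_win)) next
      g <- loci$gene[in_win]
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = ch, start = s, end = e, n_genes = sum(in_win),
        value_a = mean(val_a[g]), value_b = mean(val_b[g]),
        ratio = mean(val_a[g]) / mean(val_b[g])
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Exhaustive hypergeometric upper tail: P(X >= k) drawing n from N with K marked.
oracle_hyper_upper <- function(k, K, N, n) {
  if (k <= 0) return(1)
  js <- seq(k, min(K, n))
  if (length(js) == 0 || k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Hand-rolled Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Pool-pure study layout: no dataset mixes the two pools, so rank-based
# within-dataset normalization cannot couple them (12 + 33 samples).
pure_datasets <- function() {
  tibble::tribble(
    ~dataset_id, ~platform_id, ~scale,   ~n_a, ~n_b,
    "dsA1",      "P201",       "linear",  4L,   0L,
    "dsA2",      "P6244",      "log2",    8L,   0L,
    "dsB1",      "P201",       "linear",  0L,   11L,
    "dsB2",      "P6480",      "log2",    0L,   11L,
    "dsB3",      "P570",       "log2",    0L,   11L
  )
}

# Run normalization + pooling + the default-resolution map for a study.
run_default_map <- function(study, config = tx_config()) {
  tables <- normalize_study(study$expression, study$manifest, study$annotation,
                            config$target_median)
  a <- pool_expression(tables, study$manifest, "A", config$sample_number)
  b <- pool_expression(tables, study$manifest, "B", config$sample_number)
  transcriptome_map(a, b, study$loci, config = config)
}
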