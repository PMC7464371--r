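test_that("window grids have the documented geometry at both resolutions", {
  w <- build_windows(c(chr1 = 600000))
  expect_equal(w$start, c(1, 250001, 500001))
  expect_equal(w$end[1], 500000)

  sg <- build_windows(c(chr1 = 20000), window_bp = 12500, shift_bp = 6250)
  expect_equal(sg$start[1:3], c(1, 6251, 12501))
  expect_equal(sg$end[1:3], c(12500, 18750, 25000))

  expect_error(build_windows(c(chr1 = 1e6), window_bp = 0),
               class = "txmap_validation_error")
})

test_that("genes join every window whose span contains their start, boundaries inclusive", {
  w <- build_windows(c(chr1 = 1.2e6))
  loci <- tibble::tibble(
    gene = c("at_start", "at_end", "mid"),
    chrom = "chr1",
    start = c(250001, 500000, 300000),
    end = c(250100, 500100, 300100)
  )
  a <- assign_genes(w, loci)
  expect_setequal(a$start[a$gene == "at_start"], c(1, 250001))
  expect_setequal(a$start[a$gene == "at_end"], c(1, 250001))
  expect_setequal(a$start[a$gene == "mid"], c(1, 250001))
  # away from the chromosome start a gene sits in window_bp / shift_bp windows
  far <- tibble::tibble(gene = "far", chrom = "chr1", start = 900000, end = 900100)
  expect_equal(nrow(assign_genes(w, far)), 2)
  # genes are ordered by start within each window
  first_win <- a[a$start == 1, ]
  expect_equal(first_win$gene, first_win$gene[order(first_win$gene_start)])

  expect_error(assign_genes(w, tibble::tibble(gene = "g", chrom = "chrX",
                                              start = 1, end = 2)),
               "chrX", class = "txmap_validation_error")
})

test_that("segment values are means of pooled gene values, ratio of means", {
  w <- build_windows(c(chr1 = 5e5))
  loci <- tibble::tibble(gene = c("G1", "G2", "G3"), chrom = "chr1",
                         start = c(1000, 2000, 3000), end = c(1500, 2500, 3500))
  a <- assign_genes(w, loci)
  seg <- segment_stats(a, make_pool(c("G1", "G2"), c(2, 4)),
                       make_pool(c("G1", "G2"), c(1, 1), "B"))
  expect_equal(seg$value_a, 3)
  expect_equal(seg$value_b, 1)
  expect_equal(seg$ratio, 3)
  expect_equal(seg$genes[[1]], c("G1", "G2"))

  # ratio of means, not mean of per-gene ratios
  seg2 <- segment_stats(a, make_pool(c("G1", "G2"), c(1, 8)),
                        make_pool(c("G1", "G2"), c(1, 2), "B"))
  expect_equal(seg2$ratio, 3)  # mean-of-ratios would give 2.5

  # a window with no genes having values in both pools yields no record
  seg3 <- segment_stats(a, make_pool("G3", 5), make_pool("G1", 5, "B"))
  expect_equal(nrow(seg3), 0)
})

test_that("segment aggregation matches a brute-force locus rescan on random genomes", {
  withr::with_seed(51, {
    for (rep in 1:20) {
      n_chrom <- sample(1:3, 1)
      chrom_lengths <- tibble::tibble(
        chrom = paste0("c", seq_len(n_chrom)),
        length = sample(3e5:2e6, n_chrom)
      )
      n_genes <- sample(10:60, 1)
      loci <- tibble::tibble(
        gene = sprintf("g%03d", seq_len(n_genes)),
        chrom = sample(chrom_lengths$chrom, n_genes, replace = TRUE),
        start = sapply(seq_len(n_genes), function(i) sample.int(2e6, 1))
      )
      loci <- loci[loci$start <= chrom_lengths$length[match(loci$chrom, chrom_lengths$chrom)], ]
      loci$end <- loci$start + 100
      shared <- sample(loci$gene, ceiling(nrow(loci) * 0.8))
      a <- make_pool(shared, rlnorm(length(shared)))
      b <- make_pool(sample(loci$gene, ceiling(nrow(loci) * 0.8)),
                     rlnorm(ceiling(nrow(loci) * 0.8)), "B")
      w <- build_windows(chrom_lengths)
      got <- segment_stats(assign_genes(w, loci), a, b)
      want <- oracle_segment_stats(loci, a, b, chrom_lengths, 500000, 250000)
      got <- dplyr::arrange(dplyr::select(got, -"genes"), chrom, start)
      want <- dplyr::arrange(want, chrom, start)
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
  })
})

test_that("hypergeometric enrichment p-values match exhaustive enumeration", {
  for (N in c(5, 12, 27, 50)) {
    for (K in unique(c(0, 1, floor(N / 4), floor(N / 2), N))) {
      for (n in unique(c(1, 3, floor(N / 3), N))) {
        for (k in 0:min(n, K)) {
          expect_equal(
            phyper(k - 1, K, N - K, n, lower.tail = FALSE),
            oracle_hyper_upper(k, K, N, n),
            tolerance = 1e-12
          )
        }
      }
    }
  }
})

test_that("segment significance applies the q-threshold, tail-count and direction rules", {
  seg <- tibble::tibble(
    chrom = "chr1", start = c(1, 250001, 500001), end = c(5e5, 7.5e5, 1e6),
    n_genes = c(5L, 5L, 4L),
    genes = list(paste0("t", 1:5), c("t1", "x1", "x2", "x3", "x4"),
                 paste0("y", 1:4)),
    value_a = c(3, 1, 0.4), value_b = c(1, 1, 1),
    ratio = c(3, 1, 0.4)
  )
  withr::with_seed(61, {
    ratios <- tibble::tibble(
      gene = c(paste0("t", 1:5), paste0("x", 1:4), paste0("y", 1:4),
               sprintf("z%03d", 1:187)),
      ratio = rlnorm(200), tail = "none"
    )
  })
  ratios$tail[ratios$gene %in% paste0("t", 1:5)] <- "over"
  out <- segment_significance(seg, ratios, tx_config())
  # first window: all five genes in the over tail
  expect_equal(out$n_over, c(5L, 1L, 0L))
  expect_equal(out$p_over[1], oracle_hyper_upper(5, 5, 200, 5), tolerance = 1e-12)
  expect_equal(out$p, pmin(out$p_over, out$p_under))
  expect_equal(out$q, oracle_bh(out$p))
  expect_true(out$significant[1])
  expect_equal(out$direction[1], "over")
  # no tail genes at all: p = 1, never significant
  expect_equal(out$p[3], 1)
  expect_false(out$significant[3])
  expect_true(all(out$q >= out$p))

  expect_equal(nrow(segment_significance(seg[0, ], ratios, tx_config())), 0)
})

test_that("Benjamini-Hochberg adjustment matches the hand-rolled step-up", {
  expect_equal(p.adjust(c(0.001, 0.02, 0.9), method = "BH"),
               c(0.003, 0.03, 0.9))
  withr::with_seed(71, {
    for (rep in 1:10) {
      p <- runif(sample(3:40, 1))^2
      q <- p.adjust(p, method = "BH")
      expect_equal(q, oracle_bh(p))
      ord <- order(p)
      expect_true(all(diff(q[ord]) >= -1e-15))
    }
  })
})

test_that("swapping pools inverts segment ratios and mirrors the enrichment", {
  withr::with_seed(81, {
    genes <- sprintf("g%03d", 1:80)
    loci <- tibble::tibble(gene = genes, chrom = "chr1",
                           start = seq(1, by = 50000, length.out = 80))
    loci$end <- loci$start + 1000
    a <- make_pool(genes, rlnorm(80) * rep(c(1, 3), c(70, 10)))
    b <- make_pool(genes, rlnorm(80), "B")
  })
  m_ab <- transcriptome_map(a, b, loci)
  m_ba <- transcriptome_map(b, a, loci)
  expect_equal(m_ba$segments$ratio, 1 / m_ab$segments$ratio)
  expect_equal(m_ba$segments$n_over, m_ab$segments$n_under)
  expect_equal(m_ba$segments$n_under, m_ab$segments$n_over)
  expect_equal(m_ba$segments$p_over, m_ab$segments$p_under)
  expect_equal(m_ba$segments$p_under, m_ab$segments$p_over)
  expect_equal(m_ba$segments$q, m_ab$segments$q)
})

test_that("consecutive overlapping significant windows merge into one directed span", {
  base <- tibble::tibble(
    chrom = "chr1",
    start = c(6251, 12501, 50001),
    end = c(18750, 25000, 62500),
    n_genes = 1L, genes = list("GA", c("GA", "GB"), "GC"),
    value_a = c(2, 2, 0.2), value_b = 1, ratio = c(2, 2.5, 0.2),
    n_over = 1L, n_under = 0L, p_over = 0.01, p_under = 1,
    p = 0.01, q = 0.01,
    direction = c("over", "over", "under"),
    significant = TRUE
  )
  spans <- merge_significant_spans(base)
  expect_equal(nrow(spans), 2)
  over <- spans[spans$direction == "over", ]
  expect_equal(over$start, 6251)
  expect_equal(over$end, 25000)
  expect_equal(over$ratio, 2.5)          # most extreme window of the run
  expect_equal(over$genes[[1]], c("GA", "GB"))
  under <- spans[spans$direction == "under", ]
  expect_equal(c(under$start, under$end), c(50001, 62500))  # isolated window

  none <- base
  none$significant <- FALSE
  expect_equal(nrow(merge_significant_spans(none)), 0)
})

test_that("top-k intersection compares the extreme genes of two ranked tables", {
  tbl <- tibble::tibble(gene = sprintf("g%02d", 1:10),
                        genes = as.list(sprintf("g%02d", 1:10)),
                        ratio = seq(5, 0.5, length.out = 10))
  expect_equal(top_intersection(tbl, tbl, k = 3),
               sort(c("g01", "g02", "g03", "g08", "g09", "g10")))
  other <- dplyr::mutate(tbl, gene = paste0("h", gene),
                         genes = as.list(paste0("h", unlist(genes))))
  expect_equal(top_intersection(tbl, other, k = 3), character(0))
  expect_warning(top_intersection(tbl[1:2, ], tbl, k = 3), "only 2 rows")
})
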