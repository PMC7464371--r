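ann2 <- tibble::tibble(platform_id = "pf1",
                       probe_id = c("p1", "p2", "p3", "p4"),
                       gene_symbol = c("G1", "G1", "G2", "G3"))

test_that("probe collapse averages present probe values per gene and sample", {
  expr <- tibble::tibble(probe_id = c("p1", "p2", "p3", "px"),
                         s1 = c(2, 4, 5, 99), s2 = c(1, 1, NA, 99))
  out <- collapse_probes(expr, ann2)
  expect_equal(out$gene, c("G1", "G2"))
  expect_equal(out$s1, c(3, 5))   # mean(2, 4); single probe
  expect_equal(out$s2[out$gene == "G1"], 1)
  expect_true(is.na(out$s2[out$gene == "G2"]))  # only probe absent -> no value

  three <- tibble::tibble(probe_id = c("p1", "p2", "p2b"), s1 = c(1, 1, 4))
  ann3 <- tibble::tibble(platform_id = "pf1", probe_id = c("p1", "p2", "p2b"),
                         gene_symbol = c("G1", "G1", "G1"))
  expect_equal(collapse_probes(three, ann3)$s1, 2)

  expect_error(collapse_probes(expr, ann2, platform_id = "other"),
               class = "txmap_validation_error")
})

test_that("pooling averages data points across datasets and applies the sample-number filter", {
  man <- tiny_manifest(4, pool = c("A", "A", "A", "B"), sex = c("M", "M", "M", "F"))
  tabs <- list(
    d1 = tibble::tibble(gene = c("G1", "G2"), s1 = c(4, 5), s2 = c(2, NA)),
    d2 = tibble::tibble(gene = c("G1", "G2"), s3 = c(6, NA))
  )
  pool <- pool_expression(tabs, man, "A", sample_number = 2)
  expect_equal(pool$value[pool$gene == "G1"], 4)       # mean(4, 2, 6)
  expect_equal(pool$data_points[pool$gene == "G1"], 3)
  expect_false("G2" %in% pool$gene)                    # one value < n = 2

  pool1 <- pool_expression(tabs, man, "A", sample_number = 1)
  expect_equal(pool1$value[pool1$gene == "G2"], 5)

  expect_error(pool_expression(tabs, tiny_manifest(2, pool = c("A", "A"),
                                                   sex = c("M", "M")), "B"),
               class = "txmap_validation_error")

  # invariant under permutation of samples within the pool
  tabs_perm <- list(d2 = tabs$d2,
                    d1 = tabs$d1[, c("gene", "s2", "s1")])
  expect_equal(as.data.frame(pool_expression(tabs_perm, man, "A", 2)),
               as.data.frame(pool))

  # conservation: data points sum to the number of present gene-level values
  expect_equal(sum(pool1$data_points),
               sum(!is.na(tabs$d1$s1)) + sum(!is.na(tabs$d1$s2)) + sum(!is.na(tabs$d2$s3)))
})

test_that("gene ratios are restricted to shared genes and invert under pool swap", {
  a <- make_pool(c("G1", "G2", "G3"), c(4, 3, 1), "A")
  b <- make_pool(c("G1", "G2", "G4"), c(2, 6, 9), "B")
  r <- gene_ratios(a, b)
  expect_equal(r$gene, c("G1", "G2"))
  expect_equal(r$ratio, c(2, 0.5))
  expect_equal(unique(r$tail), "none")

  r_swap <- gene_ratios(b, a)
  expect_equal(r$ratio * r_swap$ratio, c(1, 1))

  bz <- make_pool(c("G1", "G2"), c(2, 0), "B")
  expect_warning(rz <- gene_ratios(a, bz), "zero denominator")
  expect_equal(rz$gene, "G1")
})

test_that("tail calling flags ceil(fraction * N) genes per tail with deterministic ties", {
  withr::with_seed(41, {
    r <- tibble::tibble(gene = sprintf("g%03d", 1:200),
                        value_a = 1, value_b = 1,
                        ratio = rlnorm(200), tail = "none")
    out <- call_tails(r, 0.025)
    expect_equal(sum(out$tail == "over"), 5)
    expect_equal(sum(out$tail == "under"), 5)
    expect_setequal(out$gene[out$tail == "over"],
                    out$gene[order(-out$ratio)][1:5])
    expect_setequal(out$gene[out$tail == "under"],
                    out$gene[order(out$ratio)][1:5])
  })

  r39 <- tibble::tibble(gene = sprintf("g%02d", 1:39), ratio = seq_len(39) / 10,
                        tail = "none")
  expect_warning(out39 <- call_tails(r39, 0.025), "one gene per tail")
  expect_equal(sum(out39$tail == "over"), 1)
  expect_equal(sum(out39$tail == "under"), 1)
  # at exactly N = 1 / fraction the single-gene tails need no warning
  r40 <- tibble::tibble(gene = sprintf("g%02d", 1:40), ratio = seq(0.1, 4, 0.1),
                        tail = "none")
  expect_no_warning(out40 <- call_tails(r40, 0.025))
  expect_equal(sum(out40$tail != "none"), 2)

  tied <- tibble::tibble(gene = c("b", "a", "d", "c") , ratio = 1, tail = "none")
  expect_warning(out_tied <- call_tails(tied, 0.26), "tail boundary")
  expect_equal(out_tied$tail[out_tied$gene == "a"], "over")   # lexicographically first
  expect_equal(out_tied$tail[out_tied$gene == "d"], "under")  # lexicographically last

  # tails disjoint and bounded when N >= 2 / fraction
  withr::with_seed(42, {
    r2 <- tibble::tibble(gene = sprintf("g%03d", 1:100), ratio = rlnorm(100),
                         tail = "none")
    out2 <- call_tails(r2, 0.025)
    expect_equal(sum(out2$tail != "none"), 2 * ceiling(0.025 * 100))
    expect_false(any(out2$tail == "over" & out2$tail == "under"))
  })
})
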