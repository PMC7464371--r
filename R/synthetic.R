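# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

default_datasets <- function() {
  # 11 datasets on 8 platforms, 12 pool-A and 33 pool-B samples in total,
  # with the unequal per-dataset splits typical of a repository meta-analysis
  tibble::tribble(
    ~dataset_id, ~platform_id, ~scale,   ~n_a, ~n_b,
    "ds01",      "P201",       "linear",  2L,   2L,
    "ds02",      "P201",       "linear",  1L,   1L,
    "ds03",      "P201",       "linear",  1L,   2L,
    "ds04",      "P7363",      "log2",    0L,   2L,
    "ds05",      "P571",       "log2",    0L,   1L,
    "ds06",      "P6244",      "log2",    7L,   6L,
    "ds07",      "P6480",      "log2",    0L,   6L,
    "ds08",      "P6884",      "log2",    0L,   3L,
    "ds09",      "P13158",     "linear",  0L,   3L,
    "ds10",      "P10558",     "log2",    1L,   3L,
    "ds11",      "P570",       "log2",    0L,   4L
  )
}

#' Describe a synthetic multi-platform expression study
#'
#' The generator emulates the structure of a two-pool microarray
#' meta-analysis assembled from public repositories: several datasets on
#' different platforms, a mix of linear and log2 value encodings, one to a
#' few probes per gene with platform-specific dropout, unequal pool sizes,
#' and multiplicative lognormal measurement noise on positive intensities.
#' The default design has 11 datasets on 8 platforms with 12 samples in
#' pool A and 33 in pool B, and a genome of 2 chromosomes x 250 regularly
#' spaced genes (1 gene per 100 kb, so a default 500 kb window holds about
#' 5 genes).
#'
#' @param n_chromosomes,genes_per_chromosome,gene_spacing_bp Genome layout:
#'   genes start every `gene_spacing_bp` bases and span half the spacing.
#' @param datasets Tibble `(dataset_id, platform_id, scale, n_a, n_b)`
#'   giving, per dataset, the platform, value encoding and number of pool-A
#'   and pool-B samples.
#' @param probes_per_gene Integer range `c(min, max)` of probes per gene on
#'   each platform.
#' @param dropout_rate Probability that a probe measurement is missing.
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the true
#'   per-gene expression level.
#' @param noise_sd Standard deviation (natural-log scale) of the
#'   multiplicative per-probe measurement noise.
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return A list of class `tx_design`.
#' @export
study_design <- function(n_chromosomes = 2L,
                         genes_per_chromosome = 250L,
                         gene_spacing_bp = 100000L,
                         datasets = default_datasets(),
                         probes_per_gene = c(1L, 3L),
                         dropout_rate = 0.05,
                         baseline_meanlog = 6,
                         baseline_sdlog = 1,
                         noise_sd = 0.2,
                         seed = 1L) {
  if (n_chromosomes < 1 || genes_per_chromosome < 1 || gene_spacing_bp < 1) {
    abort("Genome layout counts must be positive.", class = "txmap_validation_error")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1).", class = "txmap_validation_error")
  }
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      genes_per_chromosome = as.integer(genes_per_chromosome),
      gene_spacing_bp = as.integer(gene_spacing_bp),
      datasets = tibble::as_tibble(datasets),
      probes_per_gene = as.integer(probes_per_gene),
      dropout_rate = dropout_rate,
      baseline_meanlog = baseline_meanlog,
      baseline_sdlog = baseline_sdlog,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "tx_design"
  )
}

#' Generate the synthetic genome of a study design
#'
#' Genes are placed deterministically at regular spacing: gene `j` (1-based)
#' on each chromosome starts at `1 + (j - 1) * gene_spacing_bp` and spans
#' half the spacing. Regular spacing makes window membership counts
#' analytically known.
#'
#' @param design A [study_design()].
#' @return A gene locus tibble `(gene, chrom, start, end)`.
#' @export
generate_genome <- function(design) {
  j <- seq_len(design$genes_per_chromosome)
  purrr::map(seq_len(design$n_chromosomes), function(i) {
    start <- 1 + (j - 1) * design$gene_spacing_bp
    tibble::tibble(
      gene = sprintf("g%02d.%04d", i, j),
      chrom = sprintf("chr%d", i),
      start = start,
      end = start + floor(design$gene_spacing_bp / 2) - 1
    )
  }) |>
    dplyr::bind_rows()
}

#' Declare spiked differential gene blocks
#'
#' Each row marks a contiguous block of genes whose true expression is
#' multiplied by `fold` in every sample of one pool — the ground truth the
#' pipeline should recover as a significant segment.
#'
#' @param chrom Chromosome of the block.
#' @param start_gene_index 1-based index of the first gene of the block on
#'   its chromosome.
#' @param n_genes Number of consecutive genes in the block.
#' @param fold Positive fold change applied to the pool's samples.
#' @param pool Pool label receiving the fold (`"A"` or `"B"`).
#' @return A tibble usable as the `spikes` argument of [generate_study()].
#' @export
spike_truth <- function(chrom, start_gene_index, n_genes, fold, pool = "A") {
  tibble::tibble(chrom = chrom, start_gene_index = as.integer(start_gene_index),
                 n_genes = as.integer(n_genes), fold = fold, pool = pool)
}

validate_spikes <- function(spikes, genome) {
  if (is.null(spikes) || nrow(spikes) == 0) return(invisible(NULL))
  if (any(spikes$fold <= 0)) {
    abort("Spike folds must be positive.", class = "txmap_validation_error")
  }
  for (ch in unique(spikes$chrom)) {
    s <- spikes[spikes$chrom == ch, , drop = FALSE]
    n_genes_chrom <- sum(genome$chrom == ch)
    if (n_genes_chrom == 0) {
      abort(paste0("Spike on chromosome absent from the genome: ", ch),
            class = "txmap_validation_error")
    }
    if (any(s$start_gene_index < 1 | s$start_gene_index + s$n_genes - 1 > n_genes_chrom)) {
      abort("Spike block extends beyond the genome.", class = "txmap_validation_error")
    }
    idx <- unlist(purrr::map2(s$start_gene_index, s$n_genes, ~seq(.x, .x + .y - 1)))
    if (anyDuplicated(idx)) {
      abort("Spike blocks overlap.", class = "txmap_validation_error")
    }
  }
  invisible(NULL)
}

#' Generate a synthetic multi-platform study
#'
#' Draws a true lognormal expression level per gene, applies any spiked
#' fold changes to the named pool, then emits per-dataset probe-level
#' matrices: every probe measurement is the pool-specific gene level times
#' independent multiplicative lognormal noise, dropped out at the platform's
#' dropout rate; datasets declared `log2` are written on the log2 scale.
#' Platform annotations (probe to gene symbol) and a manifest consistent
#' with the pools are emitted alongside, plus a per-gene truth table with
#' the expected pool-A / pool-B ratio.
#'
#' @param design A [study_design()].
#' @param genome Gene locus tibble; defaults to [generate_genome()] of the
#'   design.
#' @param spikes Optional [spike_truth()] tibble; blocks must not overlap.
#' @param seed Seed; defaults to `design$seed`.
#' @return A list of class `tx_study`: `manifest`, `expression` (named list
#'   of probe tibbles per dataset), `annotation` (combined tibble), `loci`,
#'   `truth`, `spikes`, `design`.
#' @export
generate_study <- function(design, genome = generate_genome(design),
                           spikes = NULL, seed = design$seed) {
  validate_spikes(spikes, genome)
  with_seed(seed, {
    n_genes <- nrow(genome)
    true_value <- exp(rnorm(n_genes, design$baseline_meanlog, design$baseline_sdlog))
    fold_a <- rep(1, n_genes)
    fold_b <- rep(1, n_genes)
    if (!is.null(spikes) && nrow(spikes) > 0) {
      for (i in seq_len(nrow(spikes))) {
        on_chrom <- which(genome$chrom == spikes$chrom[i])
        block <- on_chrom[seq(spikes$start_gene_index[i],
                              length.out = spikes$n_genes[i])]
        if (spikes$pool[i] == "A") fold_a[block] <- fold_a[block] * spikes$fold[i]
        else fold_b[block] <- fold_b[block] * spikes$fold[i]
      }
    }
    pool_value <- cbind(A = true_value * fold_a, B = true_value * fold_b)

    # per-platform probe universe
    platforms <- unique(design$datasets$platform_id)
    probe_sets <- lapply(platforms, function(pf) {
      npr <- sample(seq(design$probes_per_gene[1], design$probes_per_gene[2]),
                    n_genes, replace = TRUE)
      gene_idx <- rep(seq_len(n_genes), npr)
      probe_id <- sprintf("%s_%s_p%d", pf, genome$gene[gene_idx],
                          unlist(lapply(npr, seq_len)))
      list(gene_idx = gene_idx, probe_id = probe_id)
    })
    names(probe_sets) <- platforms
    annotation <- dplyr::bind_rows(lapply(platforms, function(pf) {
      tibble::tibble(platform_id = pf,
                     probe_id = probe_sets[[pf]]$probe_id,
                     gene_symbol = genome$gene[probe_sets[[pf]]$gene_idx])
    }))

    manifest_rows <- list()
    expression <- list()
    for (i in seq_len(nrow(design$datasets))) {
      ds <- design$datasets[i, ]
      n_s <- ds$n_a + ds$n_b
      if (n_s == 0) next
      pools <- c(rep("A", ds$n_a), rep("B", ds$n_b))
      sample_ids <- sprintf("%s_s%02d", ds$dataset_id, seq_len(n_s))
      ps <- probe_sets[[ds$platform_id]]
      n_p <- length(ps$probe_id)
      base <- pool_value[ps$gene_idx, pools, drop = FALSE]
      noise <- matrix(exp(rnorm(n_p * n_s, 0, design$noise_sd)), n_p, n_s)
      vals <- base * noise
      if (design$dropout_rate > 0) {
        vals[matrix(runif(n_p * n_s) < design$dropout_rate, n_p, n_s)] <- NA_real_
      }
      if (ds$scale == "log2") vals <- log2(vals)
      colnames(vals) <- sample_ids
      expression[[ds$dataset_id]] <- matrix_expr(vals, "probe_id", ps$probe_id)
      manifest_rows[[ds$dataset_id]] <- tibble::tibble(
        sample_id = sample_ids,
        dataset_id = ds$dataset_id,
        platform_id = ds$platform_id,
        sex = ifelse(pools == "A", "M", "F"),
        pool = pools,
        age = NA_character_,
        scale = ds$scale
      )
    }
    truth <- dplyr::mutate(genome,
                           true_value = true_value,
                           fold_a = fold_a, fold_b = fold_b,
                           expected_ratio = fold_a / fold_b)
    structure(
      list(
        manifest = as_tx_manifest(dplyr::bind_rows(manifest_rows)),
        expression = expression,
        annotation = annotation,
        loci = genome,
        truth = truth,
        spikes = spikes,
        design = design
      ),
      class = "tx_study"
    )
  })
}

#' Write a synthetic study to tab-delimited files
#'
#' Emits `manifest.tsv`, `loci.tsv`, `truth.tsv`, one `platform_<id>.tsv`
#' per platform and one `expr_<dataset>.tsv` per dataset, so a generated
#' study is self-describing on disk.
#'
#' @param study A `tx_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(study$manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(study$loci, file.path(dir, "loci.tsv"))
  readr::write_tsv(study$truth, file.path(dir, "truth.tsv"))
  for (pf in unique(study$annotation$platform_id)) {
    readr::write_tsv(study$annotation[study$annotation$platform_id == pf, -1],
                     file.path(dir, paste0("platform_", pf, ".tsv")))
  }
  for (ds in names(study$expression)) {
    readr::write_tsv(study$expression[[ds]], file.path(dir, paste0("expr_", ds, ".tsv")))
  }
  invisible(dir)
}
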