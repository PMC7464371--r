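---
title: "Sliding-window transcriptome maps from heterogeneous microarray studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window transcriptome maps from heterogeneous microarray studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txmap)
```

## The problem

Public expression repositories hold many small microarray studies of the same
biological contrast — here the motivating case is male versus female human
adipose-derived mesenchymal stem cells (hADSCs), a contrast in which no single
deposited series has enough donors of both sexes to be analysed on its own.
A meta-analysis must therefore integrate datasets measured on different
platforms, deposited on different scales (linear intensities or log2), with
different probe sets, and with very unequal group sizes (12 male versus 33
female samples in the motivating design).

`txmap` implements a *transcriptome map* approach to this problem: instead of
testing genes one at a time, pooled expression is laid out along the genome
and contiguous chromosomal segments that are coherently over- or
underexpressed between the two pools are identified. Regional signals of this
kind are robust to single-probe noise and directly expose co-regulated gene
clusters (paralog blocks, immunoglobulin loci, snoRNA clusters and the like).

## The pipeline

1. **Linearization.** Every sample's declared scale is enforced: `log2`
   samples are transformed $x \mapsto 2^x$. Samples whose scale is not
   declared are rejected — guessing the encoding is the classic way to ruin a
   meta-analysis.
2. **Intra-dataset quantile normalization.** Within one dataset the samples
   are forced onto a common distribution: the reference is the mean of the
   samples' sorted value vectors, ties receive the mean of the reference at
   the tied ranks, and missing values are ignored (unequal sample depths are
   reconciled by interpolation on a quantile grid). This is the
   `limma::normalizeQuantiles` rule.
3. **Probe collapse.** Per sample, a gene's value is the arithmetic mean of
   the present values of its annotated probes; unannotated probes are
   dropped, and a gene with no present probe has *no* value in that sample
   (never zero).
4. **Inter-dataset scaling.** Each dataset's gene table is multiplied by one
   positive factor bringing its overall median to a common target (default
   1), making values comparable across platforms without touching relative
   expression within a dataset.
5. **Pooling.** A pool's value for a gene is the mean of every sample-level
   value available across all of the pool's datasets, each *data point*
   weighted equally. The *sample number* filter (default $n = 2$) removes
   genes observed fewer than $n$ times in a pool, so no cross-dataset claim
   rests on a single measurement.
6. **Gene ratios and tails.** For genes present in both pools the expression
   ratio is $r_g = \bar{x}^A_g / \bar{x}^B_g$. The top and bottom 2.5% of
   the ratio distribution are flagged as the *over* and *under* tails.
7. **Segments.** Windows of 500 kb sliding by 250 kb (default mode) or
   12.5 kb sliding by 6.25 kb (single-gene mode) tile each chromosome,
   1-based and inclusive at both ends. A gene belongs to every window
   containing its start coordinate. A segment's value per pool is the mean
   of its genes' pooled values and its ratio is the ratio of those means —
   deliberately *not* the mean of per-gene ratios, so highly expressed genes
   carry proportionally more weight.
8. **Significance.** Each segment is tested for enrichment of tail genes
   against the genome-wide background with the hypergeometric distribution:
   drawing the segment's $n$ genes from the $N$ mapped genes of which $K$
   are in a tail,
   $p_{\text{over}} = P(X \ge n_{\text{over}})$, analogously for the under
   tail; the segment p-value is the smaller of the two, and q-values are
   Benjamini–Hochberg adjusted across all segments of the map. A segment is
   called significant when $q < 0.05$, its winning tail holds at least three
   tail genes, and its ratio agrees with the direction.
9. **Merged spans.** Runs of consecutive overlapping significant windows
   with one direction are merged into a single reported region (minimum
   start, maximum end, union of genes, the most extreme window's ratio, the
   smallest q).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `window_bp` / `shift_bp` | 500,000 / 250,000 bp | segment width and slide; single-gene mode forces 12,500 / 6,250 bp |
| `tail_fraction` | 0.025 | fraction of the ratio distribution per tail |
| `min_tail_genes` | 3 | same-direction tail genes a significant segment must hold |
| `q_threshold` | 0.05 | BH false-discovery cutoff |
| `sample_number` | 2 | minimum data points per gene and pool |
| `target_median` | 1 | common dataset median after scaling |

All defaults are the standard map-analysis settings for this family of
methods; changing `window_bp` trades regional power against localization.

## Design choices that were genuinely open

* **What the 2.5% tails are computed on.** Tails are defined on the
  distribution of gene expression *ratios*, not on raw per-pool expression:
  the maps are differential maps, and tail membership should mark
  differential genes. If per-pool tails were intended instead, only the
  interpretation of $K$ changes; the enrichment machinery is unchanged.
* **The segment statistic.** The regional test is hypergeometric enrichment
  of tail genes, the standard reading of "significance against the genome
  background" that is consistent with the minimum-tail-gene rule. It is
  deliberately isolated behind `segment_significance()` so a permutation
  null (shuffling the gene-to-locus assignment) can be swapped in.
* **Window membership by gene start.** A gene joins every window containing
  its start coordinate (not any overlap), which keeps each gene in exactly
  `window_bp / shift_bp` windows away from chromosome starts and makes
  window gene counts analytically predictable.
* **FDR family.** One map (one resolution, one pool ordering) is one
  multiple-testing family; over and under directions are tested jointly
  through the min-p with the direction recorded.
* **Single-gene-resolution significance.** With windows that hold a single
  gene, the hypergeometric p collapses to tail membership
  ($p = K/N \approx 0.025$ at best), which cannot clear a BH threshold
  across thousands of windows. Under the defaults the single-gene map is
  therefore a *ranking* instrument (its ordered ratio table feeds the top-k
  intersection of two analyses) while FDR-called regions come from the
  default resolution. This is an honest property of the chosen regional
  statistic, not a bug; users who want single-gene calls should lower
  `min_tail_genes` and supply a dedicated per-gene statistic.
* **Age intervals in inclusion filtering.** Donor ages in deposited studies
  are often ranges ("18–39") or bare declarations ("Adult"). A point age
  must exceed the adult threshold strictly; a declared range passes when its
  lower bound is at least the threshold, and a missing or declarative entry
  passes outright — study tables with such entries were included by the
  curators who assembled them, and the filter reproduces that behaviour.
* **Zero denominators.** A gene whose pool-B value is zero has no defined
  ratio and is excluded (with a logged count) rather than pseudo-counted.

## The synthetic study generator

`study_design()` / `generate_study()` emulate the structure of a
repository-assembled meta-analysis: 11 datasets on 8 platforms, a mix of
linear and log2 encodings, 1–3 probes per gene with 5% dropout, 12 pool-A
versus 33 pool-B samples, lognormal true gene levels
($\log$-mean 6, $\log$-sd 1) and multiplicative lognormal measurement noise
(default $\sigma = 0.2$ on the natural-log scale — a typical between-sample
spread for array intensities). The default genome is 2 chromosomes × 250
genes at one gene per 100 kb, matching the human gene density well enough
that a default window holds about 5 genes, while keeping a full pipeline run
around a third of a second so the stochastic validation suites (50-replicate
spike recovery and null control) finish in well under a minute each.

`spike_truth()` plants contiguous gene blocks with a known fold change in one
pool — the ground truth for recovery tests. What the generator deliberately
does **not** model: probe-sequence affinity effects, spatial artifacts,
donor covariates beyond the manifest fields, and correlated (batch-structured)
noise. Passing the synthetic suites therefore demonstrates the pipeline's
statistical correctness and calibration under its own model, not robustness
to every artifact of real arrays.

### The no-noise identity, precisely

With `noise_sd = 0` and no dropout the pipeline returns each spiked fold
*exactly* (to machine precision) under two structural conditions, both used
by the validation suite and worth understanding:

* no dataset mixes the two pools — quantile normalization couples the
  samples of a dataset through their ranks, so a spike present in half a
  dataset's samples would be redistributed by the common reference;
* dataset medians are untouched by the spike (guaranteed with a flat
  baseline, since a handful of spiked genes cannot move the median of a
  constant vector). With a lognormal baseline the background ratio is still
  one exact constant $c$ (the ratio of the two pools' scaling factors) and
  spiked genes sit exactly at $\text{fold} \times c$.

At segment level the recovered ratio is attenuated below the spiked fold:
a 500 kb window holding three spiked and two background genes reports the
ratio of window means, roughly $(3 \cdot 2.4 + 2)/5 \approx 1.9$ for a
fold-2.4 spike — the map's regional smoothing, visible in the validation
output.

## Numerical and determinism notes

* Coordinates are 1-based and inclusive everywhere inside the package; BED
  export converts to 0-based half-open (`start - 1`, `end`).
* Tail ties at the 2.5% boundary are broken by gene symbol order (over tail:
  lexicographically first; under tail: the mirror), with a warning, so runs
  are reproducible down to file hashes.
* Chromosomes keep their input order; windows are ordered by start; span
  tables by decreasing ratio then symbol.
* All generator randomness flows from one integer seed; the RNG state of the
  caller is restored afterwards.
* Windows with no gene measured in both pools produce no record and do not
  enter the FDR family.

## Known limitations

* The hypergeometric test treats genes as exchangeable units; long genes or
  unevenly spaced loci make window gene counts uneven, which the test
  accommodates only through the draw size $n$.
* Overlapping windows are tested as one BH family without accounting for
  their 50% overlap correlation; the null-control suite shows the resulting
  calls remain conservative in practice (observed significant-window
  fraction ≈ $10^{-4}$ against a $2 q$ bound of 0.10).
* Probe-to-gene annotation quality is taken as given; mapping errors
  propagate silently into gene values.

## A worked run

```{r example, eval = FALSE}
design <- study_design(seed = 7)
study <- generate_study(design,
                        spikes = spike_truth("chr1", 100, 3, 2.4, "A"))
report <- run_map_analysis(study$manifest, study$expression,
                           study$annotation, study$loci)
report
glance(report$map_default)
autoplot(report$map_default)
```

The spiked 3-gene block on chr1 (positions ~9.9–10.2 Mb) is recovered as the
single significant overexpressed region of the default map; the summary, the
segment table (`tidy(report$map_default)`) and the run log carry the data
point and mapped-locus accounting for both pools.
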