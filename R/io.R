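#' Read and validate a study sample manifest
#'
#' The manifest is the study design table: one row per array sample, giving
#' the dataset (series) it came from, its platform, the donor sex, the pool
#' it is analysed in and the scale (`linear` or `log2`) its expression values
#' are encoded on. Pool labels may carry a sub-pool in parentheses, e.g.
#' `"B (C)"` for a female sample that also belongs to the FGF-supplemented
#' sub-pool; these are split into `pool` and `subpool` columns. Optional
#' columns `age`, `passage` and `bmi` are kept for inclusion filtering;
#' `age` may be a number, a `mean ± sd`, a range like `(18-39)`, or a plain
#' declaration such as `Adult`.
#'
#' @param path Path to a tab-delimited manifest with a header naming at least
#'   `sample_id`, `dataset_id`, `platform_id`, `sex`, `pool`, `scale`.
#' @return A tibble of class `tx_manifest`, rows in file order.
#' @examples
#' m <- read_manifest(system.file("extdata", "adsc_manifest.tsv", package = "txmap"))
#' dplyr::count(m, pool, subpool)
#' @export
read_manifest <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("sample_id", "dataset_id", "platform_id", "sex", "pool", "scale")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("Manifest is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "txmap_format_error")
  }
  as_tx_manifest(tbl)
}

#' Coerce a data frame to a validated manifest
#'
#' @param tbl A data frame with the manifest columns of [read_manifest()].
#' @return A tibble of class `tx_manifest`.
#' @export
as_tx_manifest <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (!"subpool" %in% names(tbl)) tbl$subpool <- NA_character_
  # split "B (C)"-style pool labels into pool + subpool
  has_sub <- grepl("^\\s*(\\S+)\\s*\\((\\S+)\\)\\s*$", tbl$pool)
  tbl$subpool[has_sub] <- sub("^\\s*\\S+\\s*\\((\\S+)\\)\\s*$", "\\1", tbl$pool[has_sub])
  tbl$pool <- sub("^\\s*(\\S+?)\\s*(\\(.*\\))?\\s*$", "\\1", tbl$pool)
  for (col in c("age", "passage", "bmi")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_character_
    tbl[[col]][tbl[[col]] %in% c("", "N/A", "NA", "n/a")] <- NA_character_
  }
  validate_manifest(tbl)
  class(tbl) <- c("tx_manifest", class(tbl))
  tbl
}

validate_manifest <- function(tbl) {
  dup <- tbl$sample_id[duplicated(tbl$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate sample_id(s): ", paste(unique(dup), collapse = ", ")),
          class = "txmap_validation_error")
  }
  bad_sex <- !tbl$sex %in% c("M", "F")
  if (any(bad_sex)) {
    abort(paste0("sex must be 'M' or 'F'; offending sample(s): ",
                 paste(tbl$sample_id[bad_sex], collapse = ", ")),
          class = "txmap_validation_error")
  }
  bad_scale <- !tbl$scale %in% c("linear", "log2")
  if (any(bad_scale)) {
    abort(paste0("scale must be 'linear' or 'log2'; offending sample(s): ",
                 paste(tbl$sample_id[bad_scale], collapse = ", ")),
          class = "txmap_validation_error")
  }
  # pool A is the male pool, pool B the female pool
  bad_pool <- (tbl$pool == "A" & tbl$sex != "M") | (tbl$pool == "B" & tbl$sex != "F")
  if (any(bad_pool)) {
    abort(paste0("pool/sex inconsistency (A => M, B => F) for sample(s): ",
                 paste(tbl$sample_id[bad_pool], collapse = ", ")),
          class = "txmap_validation_error")
  }
  invisible(tbl)
}

#' Write a manifest back to tab-delimited text
#'
#' Inverse of [read_manifest()]: `read_manifest(write_manifest(m, path))`
#' reproduces `m`.
#'
#' @param manifest A `tx_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(as.data.frame(manifest), path, na = "")
  invisible(path)
}

#' Sample ids belonging to a pool
#'
#' Pools `A` and `B` select on the `pool` column; any other label (e.g. the
#' `C`/`D` sub-pools of the female samples) selects on `subpool`.
#'
#' @param manifest A `tx_manifest`.
#' @param pool Pool label.
#' @return Character vector of sample ids.
#' @export
pool_samples <- function(manifest, pool) {
  if (pool %in% c("A", "B")) {
    manifest$sample_id[manifest$pool == pool]
  } else {
    manifest$sample_id[!is.na(manifest$subpool) & manifest$subpool == pool]
  }
}

# Parse an age declaration into numeric [lower, upper] bounds.
# Forms: "52" / "40.2 ± 14.2" (mean ± sd -> point value at the mean) /
# "(18-39)" range / "Adult" or missing -> unknown (NA bounds).
parse_age_bounds <- function(x) {
  lower <- rep(NA_real_, length(x))
  upper <- rep(NA_real_, length(x))
  x <- ifelse(is.na(x), NA_character_, trimws(x))
  num <- suppressWarnings(as.numeric(x))
  pt <- !is.na(num)
  lower[pt] <- upper[pt] <- num[pt]
  pm <- grepl("±|\\+/-", x) & !pt
  if (any(pm)) {
    mean_part <- suppressWarnings(as.numeric(sub("^\\s*([0-9.]+).*$", "\\1", x[pm])))
    lower[pm] <- upper[pm] <- mean_part
  }
  rng <- grepl("^\\(?\\s*[0-9.]+\\s*[-–]\\s*[0-9.]+\\s*\\)?$", x) & !pt & !pm
  rng[is.na(rng)] <- FALSE
  if (any(rng)) {
    lo <- suppressWarnings(as.numeric(sub("^\\(?\\s*([0-9.]+).*$", "\\1", x[rng])))
    hi <- suppressWarnings(as.numeric(sub("^.*[-–]\\s*([0-9.]+)\\s*\\)?$", "\\1", x[rng])))
    lower[rng] <- lo
    upper[rng] <- hi
  }
  list(lower = lower, upper = upper)
}

#' Apply donor inclusion criteria to a manifest
#'
#' Retains adult (`age > min_age`), non-obese (`bmi < max_bmi`, strict) donors
#' at an early subculture passage. A record missing the field a criterion
#' tests passes that criterion: published study tables routinely carry
#' "Adult" or "N/A" entries for donors that were nonetheless included. An
#' age given as a range passes when its lower bound is at least `min_age`
#' (a declared adult range such as 18-39).
#'
#' Filtering is idempotent and always returns a subset of its input, in the
#' input order.
#'
#' @param manifest A `tx_manifest`.
#' @param min_age Exclusive adult age threshold in years (default 18).
#' @param max_bmi Exclusive BMI threshold in kg/m^2 (default 30).
#' @param passage_range Inclusive integer range of allowed subculture
#'   passages (default 1-4).
#' @return The filtered `tx_manifest`.
#' @export
filter_inclusion <- function(manifest, min_age = 18, max_bmi = 30,
                             passage_range = c(1L, 4L)) {
  age <- parse_age_bounds(manifest$age)
  point <- !is.na(age$lower) & age$lower == age$upper
  age_ok <- is.na(age$lower) |
    (point & age$lower > min_age) |
    (!point & age$lower >= min_age)
  bmi <- suppressWarnings(as.numeric(manifest$bmi))
  bmi_ok <- is.na(bmi) | bmi < max_bmi
  pas <- suppressWarnings(as.integer(manifest$passage))
  pas_ok <- is.na(pas) | (pas >= passage_range[1] & pas <= passage_range[2])
  out <- manifest[age_ok & bmi_ok & pas_ok, , drop = FALSE]
  class(out) <- class(manifest)
  out
}

#' Read a platform probe annotation
#'
#' Two tab-delimited columns, `probe_id` and `gene_symbol`. Probes with a
#' blank symbol are unmapped and dropped from the annotation; identical
#' duplicate rows are deduplicated; a probe mapped to two different symbols
#' is an error.
#'
#' @param path Path to the annotation file.
#' @param platform_id Platform label recorded alongside the mapping.
#' @return A tibble `(platform_id, probe_id, gene_symbol)`.
#' @export
read_platform_annotation <- function(path, platform_id) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tbl) < 2) {
    abort("Platform annotation needs two columns: probe_id, gene_symbol.",
          class = "txmap_format_error")
  }
  names(tbl)[1:2] <- c("probe_id", "gene_symbol")
  as_platform_annotation(tbl[, 1:2], platform_id)
}

#' @rdname read_platform_annotation
#' @param tbl A data frame with columns `probe_id`, `gene_symbol`.
#' @export
as_platform_annotation <- function(tbl, platform_id) {
  tbl <- tibble::as_tibble(tbl)
  n_total <- nrow(tbl)
  tbl$gene_symbol[is.na(tbl$gene_symbol)] <- ""
  tbl <- dplyr::distinct(tbl, .data$probe_id, .data$gene_symbol)
  tbl <- dplyr::filter(tbl, .data$gene_symbol != "")
  conflict <- tbl$probe_id[duplicated(tbl$probe_id)]
  if (length(conflict) > 0) {
    abort(paste0("Probe(s) mapped to conflicting symbols on ", platform_id, ": ",
                 paste(unique(conflict), collapse = ", ")),
          class = "txmap_validation_error")
  }
  if (nrow(tbl) == 0) {
    warn(paste0("Platform ", platform_id, " has no mapped probes."))
  }
  rlang::inform(sprintf("Platform %s: %d probes read, %d mapped to a gene symbol.",
                        platform_id, n_total, nrow(tbl)),
                class = "txmap_log")
  dplyr::mutate(tbl, platform_id = platform_id, .before = 1)
}

#' Read a gene locus table
#'
#' Tab-delimited columns `gene`, `chrom`, `start`, `end`; coordinates are
#' 1-based and inclusive at both ends (the convention used throughout the
#' package, including window boundaries). Each symbol must map to exactly one
#' locus; symbols on two chromosomes (or listed twice) are rejected.
#'
#' @param path Path to the locus file.
#' @return A tibble `(gene, chrom, start, end)`.
#' @export
read_gene_loci <- function(path) {
  tbl <- readr::read_tsv(path,
                         col_types = readr::cols(
                           gene = readr::col_character(),
                           chrom = readr::col_character(),
                           start = readr::col_double(),
                           end = readr::col_double()
                         ),
                         progress = FALSE)
  as_gene_loci(tbl)
}

#' @rdname read_gene_loci
#' @param tbl A data frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
as_gene_loci <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)[, c("gene", "chrom", "start", "end")]
  if (nrow(tbl) == 0) return(tbl)
  bad <- tbl$start > tbl$end | tbl$start < 1
  if (any(bad)) {
    abort(paste0("Invalid locus (start > end or start < 1) for: ",
                 paste(tbl$gene[bad], collapse = ", ")),
          class = "txmap_validation_error")
  }
  dup <- unique(tbl$gene[duplicated(tbl$gene)])
  if (length(dup) > 0) {
    abort(paste0("Gene symbol(s) with more than one locus: ",
                 paste(dup, collapse = ", ")),
          class = "txmap_validation_error")
  }
  tbl
}

#' Chromosome lengths implied by a locus table
#'
#' Convenience when no assembly length table is supplied: each chromosome is
#' taken to end at the last base covered by a gene.
#'
#' @param loci A locus tibble from [read_gene_loci()].
#' @return A tibble `(chrom, length)` in order of first appearance.
#' @export
chromosome_lengths <- function(loci) {
  dplyr::summarise(dplyr::group_by(loci, chrom = factor(.data$chrom, unique(.data$chrom))),
                   length = max(.data$end), .groups = "drop") |>
    dplyr::mutate(chrom = as.character(.data$chrom))
}

#' Read a probe-level expression matrix
#'
#' Tab-delimited: a `probe_id` column followed by one numeric column per
#' sample. Empty cells are recorded as missing data points (`NA`), never as
#' zero; a non-numeric cell is a format error reported with its row and
#' column.
#'
#' @param path Path to the expression file.
#' @return A tibble with `probe_id` and one double column per sample.
#' @export
read_expression <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(tbl)[1] <- "probe_id"
  for (j in seq(2, length.out = ncol(tbl) - 1)) {
    raw <- tbl[[j]]
    raw[!is.na(raw) & trimws(raw) == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric expression value '%s' at row %d, column '%s'.",
                    raw[bad[1]], bad[1], names(tbl)[j]),
            class = "txmap_format_error")
    }
    tbl[[j]] <- val
  }
  tbl
}
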