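#' Coordinate convention conversion
#'
#' BED intervals are 0-based half-open; VCF positions are 1-based. These
#' two helpers are the single conversion point in the package and are
#' inverses of each other.
#'
#' @param pos integer vector of positions.
#' @return converted positions.
#' @export
zero_to_one_based <- function(pos) as.integer(pos) + 1L

#' @rdname zero_to_one_based
#' @export
one_to_zero_based <- function(pos) as.integer(pos) - 1L

EXPRESSION_COLS <- c("gene_id", "group", "replicate", "log_mean", "log_sd",
                     "polymorphic")

#' Read a replicate-level allele-specific expression table
#'
#' Tab-separated with columns `gene_id`, `group` (one of the six sample
#' classes), `replicate`, `log_mean`, `log_sd`, `polymorphic`. Rows with a
#' non-positive `log_sd`, an unknown group, or duplicating a
#' (gene, group, replicate) key are rejected with their line numbers.
#'
#' @param path file path.
#' @return validated measurement tibble.
#' @export
read_expression_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           group = readr::col_character(),
                           replicate = readr::col_integer(),
                           log_mean = readr::col_double(),
                           log_sd = readr::col_double(),
                           polymorphic = readr::col_logical()))
  missing <- setdiff(EXPRESSION_COLS, names(tbl))
  if (length(missing)) {
    abort(paste0("missing column(s): ", toString(missing)))
  }
  line <- seq_len(nrow(tbl)) + 1L  # header is line 1
  bad_sd <- !is.finite(tbl$log_sd) | tbl$log_sd <= 0
  if (any(bad_sd)) {
    abort(paste0("non-positive or missing log_sd at line(s): ",
                 toString(head(line[bad_sd], 10))))
  }
  bad_grp <- !tbl$group %in% ASE_GROUPS
  if (any(bad_grp)) {
    abort(paste0("unknown group at line(s): ", toString(head(line[bad_grp], 10))))
  }
  dup <- duplicated(tbl[, c("gene_id", "group", "replicate")])
  if (any(dup)) {
    abort(paste0("duplicate (gene, group, replicate) at line(s): ",
                 toString(head(line[dup], 10))))
  }
  tbl
}

#' @rdname read_expression_table
#' @param measurements measurement tibble to write.
#' @export
write_expression_table <- function(measurements, path) {
  readr::write_tsv(measurements[, EXPRESSION_COLS], path)
  invisible(path)
}

#' Read / write peak intervals as BED
#'
#' BED is 0-based half-open. Three required columns; optional `name`,
#' `score` and a trailing `replicate_support` column (doublehit /
#' singlehit) are preserved when present.
#'
#' @param path file path.
#' @return tibble with `chrom`, `start`, `end` and any optional columns.
#' @export
read_peaks_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  if (ncol(raw) < 3) abort("BED needs at least 3 columns")
  names(raw)[1:3] <- c("chrom", "start", "end")
  if (ncol(raw) >= 4) names(raw)[4] <- "name"
  if (ncol(raw) >= 5) names(raw)[5] <- "score"
  if (ncol(raw) >= 6) names(raw)[6] <- "replicate_support"
  raw$start <- as.integer(raw$start)
  raw$end <- as.integer(raw$end)
  if (any(raw$start >= raw$end)) abort("BED intervals must satisfy start < end")
  if (any(raw$start < 0)) abort("BED coordinates must be non-negative")
  raw
}

#' @rdname read_peaks_bed
#' @param peaks tibble with at least `chrom`, `start`, `end`.
#' @export
write_peaks_bed <- function(peaks, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score",
                      "replicate_support"), names(peaks))
  out <- peaks[, cols]
  if (!"name" %in% cols && "replicate_support" %in% cols) {
    # keep BED column order valid: name and score placeholders
    out <- dplyr::mutate(out, name = ".", score = 0L, .after = "end")
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read strain variants from a minimal VCF
#'
#' Positions are 1-based. Heterozygous or missing-genotype records are
#' dropped at read time (only homozygous alternate sites are informative
#' for an inbred strain), with a message counting them. Kind is inferred
#' from allele lengths: equal-length 1-bp REF/ALT is a SNP, anything else
#' an indel (anchored at its POS base).
#'
#' @param path VCF file path.
#' @return tibble: `chrom`, `pos`, `ref`, `alt`, `kind`,
#'   `genotype_homozygous` (all `TRUE` after filtering).
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- if (ncol(v@gt) >= 2) {
    vcfR::extract.gt(v, element = "GT")[, 1]
  } else {
    rep(NA_character_, nrow(fix))
  }
  alleles <- lapply(strsplit(gsub("\\|", "/", gt), "/"), unique)
  hom <- !is.na(gt) & !grepl("\\.", gt) &
    vapply(alleles, length, integer(1)) == 1L &
    vapply(alleles, function(a) a[1] != "0", logical(1))
  n_drop <- sum(!hom)
  if (n_drop > 0) {
    inform(paste0(n_drop, " heterozygous or missing-genotype record(s) dropped"))
  }
  fix <- fix[hom, , drop = FALSE]
  tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    kind = ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1, "snp", "indel"),
    genotype_homozygous = TRUE
  )
}

#' Write variants as a minimal single-sample VCF 4.2
#'
#' @param variants tibble with `chrom`, `pos`, `ref`, `alt` and optionally
#'   `genotype_homozygous` (heterozygous rows are written GT=0/1).
#' @param path output path.
#' @export
#' @rdname read_variants_vcf
write_variants_vcf <- function(variants, path) {
  hom <- variants$genotype_homozygous %||% rep(TRUE, nrow(variants))
  gt <- ifelse(hom, "1/1", "0/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sample1", sep = "\t"))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", ".", "GT", gt, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

GENE_COLS <- c("id", "chrom", "strand", "start", "end", "tss")

#' Read / write gene models as TSV
#'
#' Columns `id`, `chrom`, `strand`, `start`, `end` (0-based half-open) and
#' `tss` (strand-aware: `start` on +, `end - 1` on -).
#'
#' @param path file path.
#' @return gene-model tibble.
#' @export
read_genes_tsv <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         id = readr::col_character(),
                         chrom = readr::col_character(),
                         strand = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer(),
                         tss = readr::col_integer()))
  missing <- setdiff(GENE_COLS, names(g))
  if (length(missing)) abort(paste0("missing column(s): ", toString(missing)))
  if (any(g$start >= g$end)) abort("gene spans must satisfy start < end")
  if (any(g$tss < g$start | g$tss >= g$end)) {
    abort("tss must lie within [start, end)")
  }
  g
}

#' @rdname read_genes_tsv
#' @param genes gene-model tibble to write.
#' @export
write_genes_tsv <- function(genes, path) {
  readr::write_tsv(genes[, GENE_COLS], path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed and package version of a pipeline run
#' so that outputs are auditable.
#'
#' @param path output path.
#' @param config named list of run parameters.
#' @param seed integer seed used.
#' @export
write_manifest <- function(path, config, seed) {
  manifest <- list(
    package = "hybridase",
    version = as.character(utils::packageVersion("hybridase")),
    seed = seed,
    config = config,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
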