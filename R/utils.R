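#' @keywords internal
"_PACKAGE"

#' @importFrom stats median p.adjust pnorm rnbinom rbinom rnorm runif
#'   binom.test t.test var complete.cases setNames lm predict quantile
#'   rlnorm
#' @importFrom utils adist read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

.check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters: %s",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

.stopifnot_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

## Derive a stage-specific 32-bit seed from a master seed so that each
## pipeline stage draws from an independent, reproducible stream.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * offset) %% .Machine$integer.max)
}

#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used by
#' all pipeline tables: tab separator, header, no factor conversion.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame`.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a BED3+ file of genomic intervals
#'
#' BED coordinates are 0-based half-open on disk; the returned
#' [GenomicRanges::GRanges] follows the Bioconductor 1-based closed
#' convention (`start = bed_start + 1`). Parsing is delegated to
#' [rtracklayer::import()].
#'
#' @param path Path to a BED file (no header, >= 3 columns).
#' @return A `GRanges` object; a 4th column, when present, becomes `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  sort(gr)
}

#' Write genomic intervals as BED3(+name)
#'
#' @param gr A `GRanges` object (1-based closed); written 0-based half-open.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a variant table from TSV or VCF
#'
#' TSV files must carry the columns `id`, `chrom`, `pos`, `ref`, `alts`
#' (comma-separated) and optionally `risk_allele`, `locus_id`. VCF files
#' are converted to the same layout (ID, CHROM, POS, REF, comma-joined
#' ALT).
#'
#' @param path Input path.
#' @param format `"tsv"` or `"vcf"`; guessed from the file extension by
#'   default.
#' @return A validated variant `data.frame`.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package", call. = FALSE)
    }
    fix <- as.data.frame(vcfR::getFIX(vcfR::read.vcfR(path, verbose = FALSE)),
                         stringsAsFactors = FALSE)
    df <- data.frame(
      id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alts = fix$ALT,
      risk_allele = NA_character_, locus_id = NA_character_,
      stringsAsFactors = FALSE)
  } else {
    df <- read_tsv(path)
  }
  validate_variants(df)
}

#' Convert a variant table to genomic intervals
#'
#' Variants are treated as 1-base points; indels span their reference
#' allele.
#'
#' @param variants Variant `data.frame` with columns `chrom`, `pos`, `ref`
#'   (and `id`).
#' @return A `GRanges`, one range per variant, named by `id`.
#' @export
variants_to_granges <- function(variants) {
  .stopifnot_cols(variants, c("chrom", "pos", "ref"), "variant table")
  gr <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos,
                              width = nchar(variants$ref))
  )
  if (!is.null(variants$id)) names(gr) <- variants$id
  gr
}
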