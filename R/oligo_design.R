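## Oligo design: allele-specific 170-bp test sequences centred on the
## variant, with fixed 15-bp synthesis adapters on both sides.

ADAPTER_5P <- "ACTGGCCGCTTGACG"
ADAPTER_3P <- "CACTGCGGCTCCTGC"
CORE_LENGTH <- 170L
UPSTREAM_FLANK <- 84L

#' Validate a variant table
#'
#' Checks the invariants required of every variant record: alleles are
#' non-empty ACGT strings, pairwise distinct within a variant, and
#' `pos >= 1`.
#'
#' @param variants `data.frame` with columns `id`, `chrom`, `pos`, `ref`,
#'   `alts` (comma-separated string), and optionally `risk_allele`,
#'   `locus_id`.
#' @return The validated table, with an `alts` list-column attached as
#'   attribute-free plain character splitting.
#' @export
validate_variants <- function(variants) {
  .stopifnot_cols(variants, c("id", "chrom", "pos", "ref", "alts"),
                  "variant table")
  if (any(variants$pos < 1)) stop("variant pos must be >= 1", call. = FALSE)
  for (i in seq_len(nrow(variants))) {
    alleles <- c(variants$ref[i], strsplit(variants$alts[i], ",")[[1]])
    if (any(nchar(alleles) == 0)) {
      stop("empty allele for variant ", variants$id[i], call. = FALSE)
    }
    .check_dna(alleles, paste0("allele of ", variants$id[i]))
    if (anyDuplicated(alleles)) {
      stop("alleles of variant ", variants$id[i], " are not pairwise distinct",
           call. = FALSE)
    }
  }
  variants
}

#' Reverse-complement a DNA sequence
#'
#' @param seq Character scalar or vector over {A,C,G,T}.
#' @return The reverse complement(s).
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Extract allele-specific genomic context sequences for one variant
#'
#' For a SNP the core sequence is 84 reference bases upstream, the allele
#' base, and 85 bases downstream (170 bp total). For indels the flanks are
#' chosen so the longest allele reaches exactly 170 bp, anchoring the first
#' allele base at core position 85 (1-based); all alleles of a variant
#' share byte-identical flanks.
#'
#' @param variant One-row variant `data.frame` (see [validate_variants()]).
#' @param genome A named [Biostrings::DNAStringSet] (chromosome name ->
#'   sequence). Soft-masked lowercase bases are uppercased.
#' @return `data.frame` with one row per allele: `variant_id`, `allele`,
#'   `core_seq`, `orientation = "forward"`.
#' @export
extract_context <- function(variant, genome) {
  variant <- validate_variants(variant)
  stopifnot(nrow(variant) == 1)
  chrom <- variant$chrom
  if (!chrom %in% names(genome)) {
    stop("chromosome ", chrom, " absent from genome", call. = FALSE)
  }
  chrom_seq <- toupper(as.character(genome[[chrom]]))
  chrom_len <- nchar(chrom_seq)
  alleles <- c(variant$ref, strsplit(variant$alts, ",")[[1]])
  longest <- max(nchar(alleles))
  pos <- variant$pos
  down_len <- CORE_LENGTH - UPSTREAM_FLANK - longest
  up_start <- pos - UPSTREAM_FLANK
  down_end <- pos + nchar(variant$ref) + down_len - 1L
  if (up_start < 1L || down_end > chrom_len) {
    stop("variant ", variant$id, " too close to a chromosome boundary",
         call. = FALSE)
  }
  up <- substr(chrom_seq, up_start, pos - 1L)
  ref_obs <- substr(chrom_seq, pos, pos + nchar(variant$ref) - 1L)
  if (ref_obs != variant$ref) {
    stop("reference allele mismatch at ", variant$id, ": genome has ",
         ref_obs, ", table has ", variant$ref, call. = FALSE)
  }
  down <- substr(chrom_seq, pos + nchar(variant$ref), down_end)
  data.frame(
    variant_id = variant$id,
    allele = alleles,
    core_seq = paste0(up, alleles, down),
    orientation = "forward",
    stringsAsFactors = FALSE
  )
}

#' Add fixed synthesis adapters to a core sequence
#'
#' @param core_seq Character vector of designed core sequences.
#' @return `ACTGGCCGCTTGACG + core + CACTGCGGCTCCTGC`; 200 bp for a 170-bp
#'   core.
#' @export
add_adapters <- function(core_seq) {
  if (any(nchar(core_seq) == 0)) stop("empty core sequence", call. = FALSE)
  .check_dna(core_seq, "core sequence")
  paste0(ADAPTER_5P, core_seq, ADAPTER_3P)
}

#' Design the full oligo set for a variant table
#'
#' Produces forward and reverse-complement records for every allele of
#' every variant. The reverse-complement core is the exact reverse
#' complement of the forward core; adapters are then added in the fixed
#' orientation.
#'
#' @param variants Variant table (see [validate_variants()]).
#' @param genome Named `DNAStringSet` or path to a FASTA file.
#' @return Design manifest `data.frame`: `variant_id`, `allele`,
#'   `orientation`, `oligo_id` (`variant|allele|orientation`), `core_seq`,
#'   `full_seq`.
#' @export
design_oligos <- function(variants, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  variants <- validate_variants(variants)
  fwd <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
    extract_context(variants[i, , drop = FALSE], genome)
  }))
  rev <- fwd
  rev$core_seq <- reverse_complement(fwd$core_seq)
  rev$orientation <- "reverse_complement"
  manifest <- rbind(fwd, rev)
  manifest$oligo_id <- paste(manifest$variant_id, manifest$allele,
                             manifest$orientation, sep = "|")
  manifest$full_seq <- add_adapters(manifest$core_seq)
  manifest[, c("variant_id", "allele", "orientation", "oligo_id",
               "core_seq", "full_seq")]
}

#' Write a design manifest as FASTA
#'
#' Record ids follow `variantID|allele|orientation`.
#'
#' @param manifest Output of [design_oligos()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_design_fasta <- function(manifest, path) {
  seqs <- Biostrings::DNAStringSet(manifest$full_seq)
  names(seqs) <- manifest$oligo_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
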