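## Target-gene assignment and evidence tiers from chromatin-looping,
## eQTL, and gene-proximity tables.

#' Assign target genes and an evidence tier to variants
#'
#' Targets are the union of promoter-looping genes and eQTL genes; when
#' both are empty, the nearest gene by genomic distance to the transcript
#' span (ties broken lexicographically by gene symbol). Tiers: (1) some
#' gene has both eQTL and looping support; (2) an eQTL for at least one
#' gene; (3) looping only; (4) neither.
#'
#' @param variants Variant table (`id`, `chrom`, `pos`, `ref`).
#' @param loop_table `data.frame` (`variant_id`, `gene`) of
#'   promoter-looping interactions.
#' @param eqtl_table `data.frame` (`variant_id`, `gene`) of eQTL genes.
#' @param genes `GRanges` of transcript spans with a `name` metadata
#'   column (e.g. from [read_bed()] on a BED4+ gene table).
#' @return `data.frame`: `variant_id`, `tier`, `target_genes`
#'   (comma-separated), `nearest_gene`, `nearest_distance`.
#' @export
assign_targets <- function(variants, loop_table, eqtl_table, genes) {
  stopifnot(length(genes) > 0, !is.null(S4Vectors::mcols(genes)$name))
  vgr <- variants_to_granges(variants)
  missing_chrom <- !(as.character(GenomicRanges::seqnames(vgr)) %in%
                       unique(as.character(GenomicRanges::seqnames(genes))))
  if (any(missing_chrom)) {
    stop("variant chromosome(s) absent from gene table: ",
         paste(unique(as.character(GenomicRanges::seqnames(vgr))[missing_chrom]),
               collapse = ", "), call. = FALSE)
  }
  gene_names <- S4Vectors::mcols(genes)$name

  do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
    vid <- variants$id[i]
    loops <- unique(loop_table$gene[loop_table$variant_id == vid])
    eqtls <- unique(eqtl_table$gene[eqtl_table$variant_id == vid])
    tier <- if (length(intersect(loops, eqtls)) > 0) 1L
            else if (length(eqtls) > 0) 2L
            else if (length(loops) > 0) 3L
            else 4L
    d <- GenomicRanges::distance(vgr[i], genes, ignore.strand = TRUE)
    d[is.na(d)] <- Inf                       # other chromosomes
    nearest_idx <- which(d == min(d))
    nearest <- sort(gene_names[nearest_idx])[1]
    targets <- union(loops, eqtls)
    if (length(targets) == 0) targets <- nearest
    data.frame(variant_id = vid, tier = tier,
               target_genes = paste(sort(targets), collapse = ","),
               nearest_gene = nearest,
               nearest_distance = min(d),
               stringsAsFactors = FALSE)
  }))
}
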