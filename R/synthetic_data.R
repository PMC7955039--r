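## Seeded synthetic-data generators: ground-truth inputs for every
## pipeline stage, emulating the study conditions (3 replicates, ~729
## barcodes per oligo, planted enhancer folds >= 1.5 and allelic ratios
## >= 1.25, peak sets with planted enrichment, replicated binomial
## allelic reads).

.random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate a random reference genome and variant table
#'
#' One chromosome per risk locus (each at least 2 kb), with variants
#' placed at least 200 bases from chromosome ends. About 1% of variants
#' are multi-allelic (three alleles). Reference alleles are read from the
#' generated genome; alternate alleles differ from the reference.
#'
#' @param n_variants Number of variants (>= 1).
#' @param n_loci Number of risk loci / chromosomes.
#' @param seed Integer seed.
#' @param chrom_length Chromosome length (default 2000).
#' @param multiallelic_frac Fraction of variants given a second alternate
#'   allele (default 0.01).
#' @return List: `genome` (`DNAStringSet`), `variants` (`data.frame` with
#'   `id`, `chrom`, `pos`, `ref`, `alts`, `risk_allele`, `locus_id`),
#'   `truth` (skeleton `data.frame` keyed by variant id).
#' @export
gen_reference_and_variants <- function(n_variants, n_loci = max(1L, n_variants %/% 4L),
                                       seed = 1, chrom_length = 2000L,
                                       multiallelic_frac = 0.01) {
  stopifnot(n_variants >= 1, chrom_length >= 500)
  set.seed(seed)
  chroms <- sprintf("chrL%02d", seq_len(n_loci))
  genome_chars <- lapply(chroms, function(ch) {
    sample(DNA_BASES, chrom_length, replace = TRUE)
  })
  names(genome_chars) <- chroms

  locus <- rep_len(seq_len(n_loci), n_variants)
  ## distinct, well-spaced positions within each locus
  pos <- integer(n_variants)
  for (l in seq_len(n_loci)) {
    idx <- which(locus == l)
    pos[idx] <- sort(sample(seq(200L, chrom_length - 200L), length(idx)))
  }
  n_multi <- sum(runif(n_variants) < multiallelic_frac)
  multi <- rep(FALSE, n_variants)
  if (n_multi > 0) multi[sample.int(n_variants, n_multi)] <- TRUE

  variants <- do.call(rbind, lapply(seq_len(n_variants), function(i) {
    ch <- chroms[locus[i]]
    ref <- genome_chars[[ch]][pos[i]]
    others <- setdiff(DNA_BASES, ref)
    n_alt <- if (multi[i]) 2L else 1L
    alts <- sample(others, n_alt)
    alleles <- c(ref, alts)
    data.frame(id = sprintf("var%04d", i), chrom = ch, pos = pos[i],
               ref = ref, alts = paste(alts, collapse = ","),
               risk_allele = sample(alleles, 1),
               locus_id = sprintf("locus%02d", locus[i]),
               stringsAsFactors = FALSE)
  }))
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                            character(1), collapse = ""))
  truth <- data.frame(variant_id = variants$id, is_enhancer = FALSE,
                      enhancer_fold = 1, is_allelic = FALSE,
                      allelic_ratio = 1, in_enriched_peakset = FALSE,
                      stringsAsFactors = FALSE)
  list(genome = genome, variants = variants, truth = truth)
}

#' Plant a motif consensus next to a variant
#'
#' Rewrites the genome so that the chosen allele of the variant completes
#' the consensus sequence of `pwm` (the per-column argmax bases): the
#' consensus is written into the reference flanks with the variant base
#' replaced by the reference allele, so the consensus appears verbatim
#' only in oligos carrying `allele`.
#'
#' @param sim Output of [gen_reference_and_variants()].
#' @param variant_id Variant to modify (a SNP).
#' @param pwm A `pwm` object.
#' @param allele The allele (typically the alternate) that completes the
#'   consensus.
#' @param motif_pos 1-based position of the variant base within the
#'   consensus (default: center).
#' @return The modified `sim`, with `truth` columns `planted_motif` and
#'   `planted_allele` filled in.
#' @export
plant_motif <- function(sim, variant_id, pwm, allele,
                        motif_pos = ceiling(pwm$width / 2)) {
  v <- sim$variants[sim$variants$id == variant_id, ]
  stopifnot(nrow(v) == 1, nchar(v$ref) == 1)
  consensus <- paste(DNA_BASES[apply(pwm$matrix, 2, which.max)],
                     collapse = "")
  cons_at_var <- substr(consensus, motif_pos, motif_pos)
  alleles <- c(v$ref, strsplit(v$alts, ",")[[1]])
  stopifnot(allele %in% alleles, allele == cons_at_var)
  chrom_seq <- strsplit(as.character(sim$genome[[v$chrom]]), "")[[1]]
  start <- v$pos - motif_pos + 1L
  chrom_seq[start:(start + pwm$width - 1L)] <- strsplit(consensus, "")[[1]]
  chrom_seq[v$pos] <- v$ref                   # genome keeps the reference
  sim$genome[[v$chrom]] <- Biostrings::DNAString(paste(chrom_seq,
                                                       collapse = ""))
  i <- match(variant_id, sim$truth$variant_id)
  sim$truth$planted_motif[i] <- pwm$tf_name
  sim$truth$planted_allele[i] <- allele
  sim
}

#' Simulate barcode-level MPRA counts for a design
#'
#' Each oligo receives a rounded-lognormal number of distinct barcodes
#' (target median `barcode_median`, log-sd `barcode_sigma`); each barcode
#' has a lognormal library abundance shared across samples. Plasmid
#' counts per replicate are negative binomial around the barcode
#' abundance; mRNA counts are negative binomial around abundance x
#' enhancer fold x allele ratio.
#'
#' @param manifest Design manifest from [design_oligos()] (or any table
#'   with `variant_id`, `allele`, `oligo_id`).
#' @param effects Optional `data.frame` (`variant_id`, `allele`, `fold`)
#'   of planted activity folds (fold >= 0; mRNA mean multiplier).
#'   Alleles absent from it get fold 1.
#' @param n_replicates Replicates per assay arm (default 3).
#' @param barcode_median Target median barcodes per oligo (default 729).
#' @param barcode_sigma Log-sd of the barcode-multiplicity lognormal
#'   (default 0.4).
#' @param dispersion Negative-binomial dispersion per barcode
#'   (default 0.05).
#' @param mean_depth Mean plasmid reads per barcode (default 30).
#' @param seed Integer seed.
#' @return List: `barcode_counts` (long `data.frame`: `barcode`,
#'   `oligo_id`, `sample`, `count`), `sample_sheet`, `barcode_map`
#'   (`barcode`, `oligo_id`), `truth` (per-allele planted folds).
#' @export
gen_mpra_counts <- function(manifest, effects = NULL, n_replicates = 3,
                            barcode_median = 729, barcode_sigma = 0.4,
                            dispersion = 0.05, mean_depth = 30, seed = 1) {
  if (!is.null(effects) && any(effects$fold < 0)) {
    stop("planted folds must be non-negative", call. = FALSE)
  }
  set.seed(seed)
  oligos <- unique(manifest[, c("variant_id", "allele", "oligo_id")])
  key <- paste(oligos$variant_id, oligos$allele)
  fold <- rep(1, nrow(oligos))
  if (!is.null(effects)) {
    m <- match(key, paste(effects$variant_id, effects$allele))
    fold[!is.na(m)] <- effects$fold[m[!is.na(m)]]
  }
  n_bc <- pmax(1L, as.integer(round(
    rlnorm(nrow(oligos), log(barcode_median), barcode_sigma))))
  samples <- c(sprintf("plasmid_rep%d", seq_len(n_replicates)),
               sprintf("mRNA_rep%d", seq_len(n_replicates)))
  roles <- rep(c("plasmid_DNA", "mRNA"), each = n_replicates)
  sample_sheet <- data.frame(sample = samples, role = roles,
                             replicate = rep(seq_len(n_replicates), 2),
                             stringsAsFactors = FALSE)
  total_bc <- sum(n_bc)
  barcode_ids <- sprintf("BC%07d", seq_len(total_bc))
  oligo_of_bc <- rep(oligos$oligo_id, n_bc)
  fold_of_bc <- rep(fold, n_bc)
  abundance <- mean_depth * rlnorm(total_bc, -0.125, 0.5)
  size <- 1 / dispersion

  counts <- lapply(seq_along(samples), function(j) {
    mu <- if (roles[j] == "mRNA") abundance * fold_of_bc else abundance
    rnbinom(total_bc, mu = mu, size = size)
  })
  barcode_counts <- data.frame(
    barcode = rep(barcode_ids, length(samples)),
    oligo_id = rep(oligo_of_bc, length(samples)),
    sample = rep(samples, each = total_bc),
    count = unlist(counts),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(variant_id = oligos$variant_id,
                      allele = oligos$allele, oligo_id = oligos$oligo_id,
                      fold = fold, n_barcodes = n_bc,
                      stringsAsFactors = FALSE)
  list(barcode_counts = barcode_counts, sample_sheet = sample_sheet,
       barcode_map = data.frame(barcode = barcode_ids,
                                oligo_id = oligo_of_bc,
                                stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate an oligo-level negative-binomial count matrix
#'
#' Convenience generator for calibration studies: oligo totals drawn
#' directly from a negative binomial with the given per-oligo dispersion,
#' with the mRNA arm scaled by a planted fold.
#'
#' @param n_oligos Number of oligos.
#' @param mu Mean plasmid count per oligo (default 2000).
#' @param dispersion NB dispersion (default 0.05).
#' @param fold Scalar or length-`n_oligos` vector of mRNA fold changes
#'   (default 1: null).
#' @param n_replicates Replicates per arm (default 3).
#' @param seed Integer seed.
#' @return List: `counts` (matrix), `groups` (named role vector),
#'   `fold`.
#' @export
gen_oligo_counts <- function(n_oligos, mu = 2000, dispersion = 0.05,
                             fold = 1, n_replicates = 3, seed = 1) {
  set.seed(seed)
  fold <- rep_len(fold, n_oligos)
  size <- 1 / dispersion
  samples <- c(sprintf("plasmid_rep%d", seq_len(n_replicates)),
               sprintf("mRNA_rep%d", seq_len(n_replicates)))
  counts <- cbind(
    matrix(rnbinom(n_oligos * n_replicates, mu = mu, size = size),
           n_oligos, n_replicates),
    matrix(rnbinom(n_oligos * n_replicates, mu = mu * fold, size = size),
           n_oligos, n_replicates)
  )
  dimnames(counts) <- list(sprintf("oligo%05d", seq_len(n_oligos)), samples)
  groups <- setNames(rep(c("plasmid_DNA", "mRNA"), each = n_replicates),
                     samples)
  list(counts = counts, groups = groups, fold = fold)
}

#' Simulate ChIP-seq peak sets and allelic read tables
#'
#' Peaks of width 200-1000 bases are placed over variants with
#' probability `p_target` (variants in `target_ids`) or `p_background`
#' (all others), independently per dataset. Allelic reads at heterozygous
#' in-peak variants are binomial draws per replicate around the planted
#' allele-1 ratio.
#'
#' @param variants Variant table.
#' @param n_datasets Number of ChIP-seq datasets.
#' @param target_ids Variant ids carrying the planted peak enrichment.
#' @param p_target,p_background In-peak probabilities (defaults 0.5 and
#'   0.1).
#' @param allelic_ratio Named vector (variant id -> allele-1 read
#'   probability); unnamed scalar applies to all (default 0.5).
#' @param n_reads Reads per replicate at a heterozygous site (default 40).
#' @param n_replicates Replicates per dataset (default 2).
#' @param het_prob Probability a variant is heterozygous in a dataset's
#'   cell line (default 1).
#' @param proteins Protein labels recycled across datasets.
#' @param cell_lines Cell-line labels recycled across datasets.
#' @param seed Integer seed.
#' @return List: `peak_sets` (named list of `GRanges`), `allelic_reads`
#'   (`data.frame` in the [score_allelic_reads()] layout), `truth`.
#' @export
gen_chipseq_data <- function(variants, n_datasets = 4,
                             target_ids = character(),
                             p_target = 0.5, p_background = 0.1,
                             allelic_ratio = 0.5, n_reads = 40,
                             n_replicates = 2, het_prob = 1,
                             proteins = paste0("TF", seq_len(n_datasets)),
                             cell_lines = "LCL1", seed = 1) {
  set.seed(seed)
  proteins <- rep_len(proteins, n_datasets)
  cell_lines <- rep_len(cell_lines, n_datasets)
  ratio_of <- function(vid) {
    if (!is.null(names(allelic_ratio)) && vid %in% names(allelic_ratio)) {
      allelic_ratio[[vid]]
    } else if (is.null(names(allelic_ratio))) allelic_ratio[1] else 0.5
  }
  peak_sets <- list()
  reads <- list()
  for (d in seq_len(n_datasets)) {
    ds <- sprintf("DS%03d", d)
    p_in <- ifelse(variants$id %in% target_ids, p_target, p_background)
    in_peak <- runif(nrow(variants)) < p_in
    widths <- sample(200:1000, sum(in_peak), replace = TRUE)
    offs <- vapply(widths, function(w) sample.int(w, 1L) - 1L, integer(1))
    starts <- pmax(1L, variants$pos[in_peak] - offs)
    peak_sets[[ds]] <- GenomicRanges::GRanges(
      seqnames = variants$chrom[in_peak],
      ranges = IRanges::IRanges(start = starts, width = widths))
    het <- runif(nrow(variants)) < het_prob
    for (i in which(het & in_peak)) {
      ratio <- ratio_of(variants$id[i])
      r1 <- rbinom(n_replicates, n_reads, ratio)
      reads[[length(reads) + 1L]] <- data.frame(
        variant_id = variants$id[i], cell_line = cell_lines[d],
        dataset_id = ds, protein = proteins[d],
        replicate = seq_len(n_replicates),
        reads_allele1 = r1, reads_allele2 = n_reads - r1,
        het = TRUE, in_peak = TRUE, stringsAsFactors = FALSE)
    }
  }
  allelic_reads <- if (length(reads)) do.call(rbind, reads) else
    data.frame(variant_id = character(), cell_line = character(),
               dataset_id = character(), protein = character(),
               replicate = integer(), reads_allele1 = integer(),
               reads_allele2 = integer(), het = logical(),
               in_peak = logical(), stringsAsFactors = FALSE)
  truth <- data.frame(
    variant_id = variants$id,
    in_enriched_peakset = variants$id %in% target_ids,
    allelic_binding_ratio = vapply(variants$id, ratio_of, numeric(1)),
    stringsAsFactors = FALSE)
  list(peak_sets = peak_sets, allelic_reads = allelic_reads, truth = truth)
}

#' Simulate looping, eQTL, and gene tables for a requested tier layout
#'
#' Builds a gene table (one gene near each variant plus decoys) and
#' looping/eQTL tables such that [assign_targets()] reproduces the
#' requested tier for every variant.
#'
#' @param variants Variant table.
#' @param tiers Integer vector (1-4) per variant, recycled.
#' @param seed Integer seed.
#' @return List: `genes` (`GRanges` with `name`), `loop_table`,
#'   `eqtl_table`, `truth` (`variant_id`, `tier`).
#' @export
gen_annotation_tables <- function(variants, tiers = 4L, seed = 1) {
  set.seed(seed)
  tiers <- rep_len(as.integer(tiers), nrow(variants))
  stopifnot(all(tiers %in% 1:4))
  gene_names <- sprintf("GENE%03d", seq_len(nrow(variants)))
  genes <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, variants$pos + 50L),
                              width = 100L))
  S4Vectors::mcols(genes)$name <- gene_names
  loop <- list(); eqtl <- list()
  for (i in seq_len(nrow(variants))) {
    vid <- variants$id[i]
    g <- gene_names[i]
    if (tiers[i] == 1L) {
      loop[[length(loop) + 1L]] <- data.frame(variant_id = vid, gene = g)
      eqtl[[length(eqtl) + 1L]] <- data.frame(variant_id = vid, gene = g)
    } else if (tiers[i] == 2L) {
      eqtl[[length(eqtl) + 1L]] <- data.frame(variant_id = vid, gene = g)
    } else if (tiers[i] == 3L) {
      loop[[length(loop) + 1L]] <- data.frame(variant_id = vid, gene = g)
    }
  }
  empty <- data.frame(variant_id = character(), gene = character(),
                      stringsAsFactors = FALSE)
  list(genes = genes,
       loop_table = if (length(loop)) do.call(rbind, loop) else empty,
       eqtl_table = if (length(eqtl)) do.call(rbind, eqtl) else empty,
       truth = data.frame(variant_id = variants$id, tier = tiers,
                          stringsAsFactors = FALSE))
}

#' Generate a set of informative random PWMs
#'
#' Each motif has one dominant base per column (probability
#' `dominance`), giving consensus sites that score near 100% relative
#' and random sequence that rarely does.
#'
#' @param n Number of motifs.
#' @param width Motif width (default 8).
#' @param dominance Probability of the dominant base (default 0.85).
#' @param families Family labels recycled across motifs (default: one
#'   family per motif).
#' @param seed Integer seed.
#' @return Named list of `pwm` objects (names `TF1`, `TF2`, ...).
#' @export
gen_pwms <- function(n, width = 8L, dominance = 0.85,
                     families = paste0("FAM", seq_len(n)), seed = 1) {
  set.seed(seed)
  families <- rep_len(families, n)
  out <- lapply(seq_len(n), function(i) {
    dom <- sample.int(4, width, replace = TRUE)
    mat <- matrix((1 - dominance) / 3, nrow = 4, ncol = width)
    mat[cbind(dom, seq_len(width))] <- dominance
    pwm(mat, tf_name = paste0("TF", i), family = families[i])
  })
  names(out) <- vapply(out, function(p) p$tf_name, character(1))
  out
}
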