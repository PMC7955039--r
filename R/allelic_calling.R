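## Allelic activity: per-barcode plasmid-normalized log ratios and a
## Student's t-test between alleles of each enhancer variant.

#' Plasmid-normalized per-barcode log2 activity ratios
#'
#' For each barcode of one allele, computes
#' `log2((rna/sf_rna + pc) / (dna/sf_dna + pc))` with the pseudocount
#' applied after size-factor scaling. Counts are pooled across replicates
#' within each assay arm (replicate counts summed, size factors summed),
#' giving one statistically independent ratio per barcode.
#'
#' @param barcode_counts Long `data.frame`: `barcode`, `sample`, `count`
#'   for one allele (all orientations pooled).
#' @param sample_sheet `data.frame`: `sample`, `role`.
#' @param sf Named size factors covering every sample.
#' @param pseudocount Added after normalization (default 1).
#' @return Numeric vector of log2 ratios, one per barcode.
#' @export
normalized_log_ratios <- function(barcode_counts, sample_sheet, sf,
                                  pseudocount = 1) {
  .stopifnot_cols(barcode_counts, c("barcode", "sample", "count"),
                  "barcode counts")
  rna_samples <- sample_sheet$sample[sample_sheet$role == "mRNA"]
  dna_samples <- sample_sheet$sample[sample_sheet$role == "plasmid_DNA"]
  barcodes <- unique(barcode_counts$barcode)
  if (length(barcodes) == 0) stop("allele has zero barcodes", call. = FALSE)

  get_counts <- function(samp) {
    m <- barcode_counts[barcode_counts$sample == samp, , drop = FALSE]
    v <- setNames(rep(0, length(barcodes)), barcodes)
    v[m$barcode] <- m$count
    v
  }
  dna_norm <- Reduce(`+`, lapply(dna_samples, get_counts)) /
    sum(sf[dna_samples])
  rna_norm <- Reduce(`+`, lapply(rna_samples, get_counts)) /
    sum(sf[rna_samples])
  unname(log2((rna_norm + pseudocount) / (dna_norm + pseudocount)))
}

#' Test one enhancer variant for allelic activity
#'
#' Two-sample Student's t-test (pooled variance) on the per-barcode log2
#' ratio lists of each unordered allele pair. The reported `delta_log2`
#' is mean(allele2) - mean(allele1) where allele1 is the reference when
#' present.
#'
#' @param ratios Named list of numeric vectors, one per allele.
#' @param variant_id Variant identifier.
#' @param ref_allele Reference allele name (orients the sign), or `NA`.
#' @return `data.frame`, one row per pair: `variant_id`, `allele1`,
#'   `allele2`, `n1`, `n2`, `delta_log2`, `fold_between_alleles`
#'   (`2^delta_log2`), `p_value`, `skipped`.
#' @export
test_allelic <- function(ratios, variant_id, ref_allele = NA) {
  alleles <- names(ratios)
  if (!is.na(ref_allele) && ref_allele %in% alleles) {
    alleles <- c(ref_allele, setdiff(alleles, ref_allele))
  }
  pairs <- utils::combn(alleles, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    x <- ratios[[pr[1]]]; y <- ratios[[pr[2]]]
    skipped <- length(x) < 2 || length(y) < 2
    if (skipped) {
      delta <- NA_real_; p <- NA_real_
    } else if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y)) {
      delta <- 0; p <- 1
    } else {
      tt <- t.test(y, x, var.equal = TRUE)
      delta <- mean(y) - mean(x)
      p <- tt$p.value
    }
    data.frame(variant_id = variant_id, allele1 = pr[1], allele2 = pr[2],
               n1 = length(x), n2 = length(y),
               delta_log2 = delta, fold_between_alleles = 2^delta,
               p_value = p, skipped = skipped,
               stringsAsFactors = FALSE)
  }))
}

#' Call allelic enhancer variants across a run
#'
#' Computes per-barcode normalized log ratios for every allele of every
#' enVar, tests all allele pairs, applies Benjamini-Hochberg correction
#' across all tested pairs in the run, and flags pairs with
#' `p_adj < padj_threshold` and a fold change of at least `fc_threshold`
#' (or at most its reciprocal) as allelic. A variant is an allelic enVar
#' if any of its pairs is allelic.
#'
#' @param barcode_counts Long `data.frame`: `barcode`, `oligo_id`,
#'   `sample`, `count` (oligo_id may carry an orientation suffix; pooled
#'   per allele).
#' @param sample_sheet `data.frame`: `sample`, `role`.
#' @param en_vars Character vector of enVar ids (only these are tested).
#' @param variants Optional variant table supplying `ref` per variant for
#'   sign orientation.
#' @param sf Named size factors; computed from an oligo-level matrix of
#'   `barcode_counts` when `NULL`.
#' @param fc_threshold Allelic fold-change threshold (default 1.25).
#' @param padj_threshold Adjusted-p threshold (default 0.05).
#' @param pseudocount Passed to [normalized_log_ratios()].
#' @return List with `pairs` (all pair tests, with `p_adj`, `is_allelic`)
#'   and `allelic_enVars` (character vector).
#' @export
call_allelic <- function(barcode_counts, sample_sheet, en_vars,
                         variants = NULL, sf = NULL,
                         fc_threshold = 1.25, padj_threshold = 0.05,
                         pseudocount = 1) {
  .stopifnot_cols(barcode_counts, c("barcode", "oligo_id", "sample", "count"),
                  "barcode counts")
  bc <- barcode_counts
  bc$allele_id <- merge_orientation(bc$oligo_id)
  bc$variant_id <- sub("\\|.*$", "", bc$allele_id)
  bc$allele <- sub("^[^|]*\\|", "", bc$allele_id)

  if (is.null(sf)) {
    agg <- tapply(bc$count, list(bc$allele_id, bc$sample), sum)
    agg[is.na(agg)] <- 0
    sf <- size_factors(agg)
  }

  bc_by_variant <- split(bc, bc$variant_id)
  tests <- lapply(en_vars, function(v) {
    sub <- bc_by_variant[[v]]
    if (is.null(sub) || nrow(sub) == 0) return(NULL)
    alleles <- sort(unique(sub$allele))
    ratios <- lapply(alleles, function(a) {
      normalized_log_ratios(sub[sub$allele == a, , drop = FALSE],
                            sample_sheet, sf, pseudocount)
    })
    names(ratios) <- alleles
    ref <- if (!is.null(variants)) variants$ref[match(v, variants$id)] else NA
    test_allelic(ratios, v, ref_allele = ref)
  })
  pairs <- do.call(rbind, tests)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(list(pairs = pairs, allelic_enVars = character()))
  }
  pairs$p_adj <- NA_real_
  ok <- !pairs$skipped
  pairs$p_adj[ok] <- p.adjust(pairs$p_value[ok], method = "BH")
  pairs$is_allelic <- ok & !is.na(pairs$p_adj) &
    pairs$p_adj < padj_threshold &
    (pairs$fold_between_alleles >= fc_threshold |
       pairs$fold_between_alleles <= 1 / fc_threshold)
  list(pairs = pairs,
       allelic_enVars = sort(unique(pairs$variant_id[pairs$is_allelic])))
}

#' Genotype-dependence summary per enhancer variant
#'
#' One row per enVar: the maximum activity fold change across its alleles
#' and the normalized fold change between non-reference and reference
#' alleles (the most significant pair for multi-allelic variants), with
#' the allelic flag — the table behind an activity-vs-dependence scatter.
#'
#' @param allelic Output of [call_allelic()].
#' @param activity Output of [test_activity()] (after [call_enhancers()]).
#' @param en_vars enVar ids.
#' @return `data.frame`: `variant_id`, `max_activity_fold`,
#'   `genotype_dependence` (fold, non-reference over reference),
#'   `is_allelic`.
#' @export
genotype_dependence_summary <- function(allelic, activity, en_vars) {
  act_variant <- sub("\\|.*$", "", activity$oligo_id)
  do.call(rbind, lapply(en_vars, function(v) {
    act <- activity[act_variant == v & !activity$excluded, , drop = FALSE]
    prs <- allelic$pairs[allelic$pairs$variant_id == v & !allelic$pairs$skipped, ,
                         drop = FALSE]
    dep <- NA_real_; flag <- FALSE
    if (nrow(prs) > 0) {
      best <- prs[order(prs$p_adj), ][1, ]
      dep <- best$fold_between_alleles
      flag <- any(prs$is_allelic)
    }
    data.frame(variant_id = v,
               max_activity_fold = if (nrow(act)) max(2^act$log2_fold_change) else NA_real_,
               genotype_dependence = dep,
               is_allelic = flag,
               stringsAsFactors = FALSE)
  }))
}
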