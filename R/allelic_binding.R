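## Allele-specific ChIP-seq read imbalance at heterozygous variants:
## per-dataset scoring across replicates, three consistency filters, and
## the imbalance-strength summary.

#' Allelic imbalance strength
#'
#' `1 - weak/strong` read counts: 0 for balanced reads, 0.5 when the
#' strong allele has twice the reads of the weak allele, approaching 1
#' for complete imbalance.
#'
#' @param reads_a,reads_b Non-negative read counts for the two alleles
#'   (vectorized).
#' @return Numeric in `[0, 1)`.
#' @export
strength <- function(reads_a, reads_b) {
  if (any(reads_a < 0 | reads_b < 0)) stop("read counts must be non-negative",
                                           call. = FALSE)
  if (any(reads_a + reads_b == 0)) {
    stop("strength undefined when both read counts are zero", call. = FALSE)
  }
  1 - pmin(reads_a, reads_b) / pmax(reads_a, reads_b)
}

#' Score one (variant, dataset) for allelic binding across replicates
#'
#' The reproducibility score is the minimum per-replicate strength when
#' all replicates prefer the same allele, and 0 otherwise (a replicate
#' with tied reads prefers neither allele and breaks consistency). The
#' call is allelic when the score exceeds `ars_threshold`, a two-sided
#' binomial test against 0.5 on the replicate-summed reads gives
#' `p < 0.05`, and the summed reads reach `min_total`.
#'
#' @param reads_allele1,reads_allele2 Integer vectors, one entry per
#'   replicate. Replicates with zero total reads are dropped (flagged).
#' @param ars_threshold Score threshold (default 0.4).
#' @param min_total Minimum summed reads (default 6).
#' @param score_fun Optional replacement scoring function taking the two
#'   replicate read vectors and returning a score in `[0, 1]`; the
#'   default implements the replicate-consistent minimum strength.
#' @return List: `score`, `is_allelic`, `preferred_allele` (1, 2 or `NA`),
#'   `consistent` (replicate directions agree), `binom_p`, `total_reads`,
#'   `n_replicates_used`, `dropped_replicates`.
#' @export
call_allelic_dataset <- function(reads_allele1, reads_allele2,
                                 ars_threshold = 0.4, min_total = 6,
                                 score_fun = NULL) {
  stopifnot(length(reads_allele1) == length(reads_allele2),
            length(reads_allele1) >= 1)
  tot <- reads_allele1 + reads_allele2
  dropped <- sum(tot == 0)
  keep <- tot > 0
  a1 <- reads_allele1[keep]; a2 <- reads_allele2[keep]
  if (length(a1) == 0) {
    return(list(score = NA_real_, is_allelic = FALSE,
                preferred_allele = NA_integer_, consistent = NA,
                binom_p = NA_real_, total_reads = 0L,
                n_replicates_used = 0L, dropped_replicates = dropped))
  }
  direction <- sign(a1 - a2)                  # +1 prefers allele1, 0 tie
  consistent <- all(direction == direction[1]) && direction[1] != 0
  if (is.null(score_fun)) {
    score <- if (consistent) min(strength(a1, a2)) else 0
  } else {
    score <- score_fun(a1, a2)
  }
  total1 <- sum(a1); total2 <- sum(a2)
  binom_p <- binom.test(total1, total1 + total2, p = 0.5)$p.value
  is_allelic <- score > ars_threshold && binom_p < 0.05 &&
    (total1 + total2) >= min_total
  preferred <- if (consistent) {
    if (direction[1] > 0) 1L else 2L
  } else if (total1 != total2 && score > 0) {
    if (total1 > total2) 1L else 2L
  } else NA_integer_
  list(score = score, is_allelic = is_allelic,
       preferred_allele = preferred, consistent = consistent,
       binom_p = binom_p, total_reads = total1 + total2,
       n_replicates_used = length(a1), dropped_replicates = dropped)
}

#' Score every (variant, dataset) in an allelic read table
#'
#' Only records that are heterozygous in the assayed cell line and inside
#' a peak are considered; replicates of one dataset are combined by
#' [call_allelic_dataset()].
#'
#' @param reads `data.frame`: `variant_id`, `cell_line`, `dataset_id`,
#'   `protein`, `replicate`, `reads_allele1`, `reads_allele2`, `het`
#'   (logical), `in_peak` (logical).
#' @param ars_threshold,min_total,score_fun See [call_allelic_dataset()].
#' @return `data.frame`, one row per (variant, dataset) considered:
#'   identifiers plus `score`, `is_allelic`, `preferred_allele`,
#'   `consistent`, `binom_p`, `total_reads`.
#' @export
score_allelic_reads <- function(reads, ars_threshold = 0.4, min_total = 6,
                                score_fun = NULL) {
  .stopifnot_cols(reads, c("variant_id", "cell_line", "dataset_id",
                           "protein", "replicate", "reads_allele1",
                           "reads_allele2", "het", "in_peak"),
                  "allelic read table")
  reads <- reads[reads$het & reads$in_peak, , drop = FALSE]
  if (nrow(reads) == 0) {
    return(data.frame(variant_id = character(), cell_line = character(),
                      dataset_id = character(), protein = character(),
                      score = numeric(), is_allelic = logical(),
                      preferred_allele = integer(), consistent = logical(),
                      binom_p = numeric(), total_reads = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(reads$variant_id, reads$dataset_id, drop = TRUE)
  do.call(rbind, lapply(split(reads, key), function(g) {
    call <- call_allelic_dataset(g$reads_allele1, g$reads_allele2,
                                 ars_threshold = ars_threshold,
                                 min_total = min_total,
                                 score_fun = score_fun)
    data.frame(variant_id = g$variant_id[1], cell_line = g$cell_line[1],
               dataset_id = g$dataset_id[1], protein = g$protein[1],
               score = call$score, is_allelic = call$is_allelic,
               preferred_allele = call$preferred_allele,
               consistent = call$consistent, binom_p = call$binom_p,
               total_reads = call$total_reads, stringsAsFactors = FALSE)
  }))
}

#' Apply the three allelic-consistency filters
#'
#' A (variant, protein) allelic event is retained iff:
#' (1) the variant is allelic in at least `min_allelic_frac` (default
#' 50%) of the datasets in which it was heterozygous for that protein;
#' (2) one allele is preferred in at least `min_same_allele_frac`
#' (default 75%) of the allelic datasets; and (3) every allelic dataset
#' has replicate-consistent direction.
#'
#' @param calls Output of [score_allelic_reads()] — all considered
#'   datasets, allelic or not (the non-allelic rows supply the
#'   heterozygosity denominator).
#' @param min_allelic_frac,min_same_allele_frac Filter thresholds.
#' @return `data.frame`, one row per retained (variant, protein):
#'   `variant_id`, `protein`, `consensus_allele`, `n_allelic`, `n_het`,
#'   `frac_allelic`, `frac_same_allele`.
#' @export
apply_consistency_filters <- function(calls, min_allelic_frac = 0.5,
                                      min_same_allele_frac = 0.75) {
  if (nrow(calls) == 0) return(calls[0, c("variant_id", "protein")])
  key <- interaction(calls$variant_id, calls$protein, drop = TRUE)
  rows <- lapply(split(calls, key), function(g) {
    n_het <- nrow(g)
    al <- g[g$is_allelic, , drop = FALSE]
    n_allelic <- nrow(al)
    if (n_het == 0 || n_allelic == 0) return(NULL)
    if (n_allelic / n_het < min_allelic_frac) return(NULL)
    pref <- table(al$preferred_allele)
    consensus <- as.integer(names(pref)[which.max(pref)])
    frac_same <- max(pref) / n_allelic
    if (frac_same < min_same_allele_frac) return(NULL)
    if (!all(al$consistent)) return(NULL)
    data.frame(variant_id = g$variant_id[1], protein = g$protein[1],
               consensus_allele = consensus, n_allelic = n_allelic,
               n_het = n_het, frac_allelic = n_allelic / n_het,
               frac_same_allele = frac_same, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), protein = character(),
                      consensus_allele = integer(), n_allelic = integer(),
                      n_het = integer(), frac_allelic = numeric(),
                      frac_same_allele = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Summarize retained allelic-binding events per (variant, protein)
#'
#' Strengths of allelic datasets are first aggregated per cell line
#' (median), then the median across cell lines is reported, alongside the
#' "(k of n)" dataset counts.
#'
#' @param retained Output of [apply_consistency_filters()].
#' @param calls Output of [score_allelic_reads()].
#' @return `data.frame`: `variant_id`, `protein`, `consensus_allele`,
#'   `median_strength`, `n_allelic`, `n_het`, `label` like `"(2 of 5)"`.
#' @export
summarize_allelic_profile <- function(retained, calls) {
  if (nrow(retained) == 0) {
    return(cbind(retained, median_strength = numeric(0), label = character(0)))
  }
  med <- vapply(seq_len(nrow(retained)), function(i) {
    g <- calls[calls$variant_id == retained$variant_id[i] &
                 calls$protein == retained$protein[i] & calls$is_allelic, ,
               drop = FALSE]
    per_cell <- tapply(g$score, g$cell_line, median)
    median(per_cell)
  }, numeric(1))
  retained$median_strength <- med
  retained$label <- sprintf("(%d of %d)", retained$n_allelic, retained$n_het)
  retained
}
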