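## Resampling-based enrichment of a variant set within peak sets:
## observed overlap vs a null built by repeatedly drawing size-matched
## sets from a negative variant pool.

#' Count input regions overlapping a peak set
#'
#' A region counts once if it intersects at least one peak by at least
#' one base; chromosomes absent from the peak set contribute zero.
#'
#' @param regions `GRanges` of input regions (variants as 1-base ranges).
#' @param peaks `GRanges` of peaks.
#' @return Integer overlap count, between 0 and `length(regions)`.
#' @export
count_overlap <- function(regions, peaks) {
  # chromosomes absent from the peak set legitimately contribute zero;
  # silence the disjoint-seqlevels warning that encodes that situation
  suppressWarnings(
    sum(IRanges::overlapsAny(regions, peaks, ignore.strand = TRUE))
  )
}

#' Resampling enrichment of a variant set in one peak dataset
#'
#' Builds a null distribution of overlap counts from `n_iter` draws of
#' `length(input)` loci (without replacement) from the negative set, and
#' reports the z-score and one-sided upper-tail normal p-value of the
#' observed overlap.
#'
#' When the null is degenerate (`sd = 0`): if the observed overlap does
#' not exceed the null mean, `p = 1`; otherwise the result is flagged
#' `degenerate` and `p` is reported as `1/n_iter` (an upper bound).
#'
#' @param input `GRanges` of input variants.
#' @param negative `GRanges` of negative-set variants
#'   (`length >= length(input)`).
#' @param peaks `GRanges` of one peak dataset.
#' @param n_iter Number of resampling iterations (default 2000).
#' @param seed Integer seed.
#' @param name Dataset label carried into the result.
#' @return One-row `data.frame`: `dataset`, `n_input`, `observed_overlap`,
#'   `expected_mean`, `expected_sd`, `z_score`, `p_value`, `fold`,
#'   `degenerate`.
#' @export
reli_enrichment <- function(input, negative, peaks, n_iter = 2000,
                            seed = 1, name = "peaks") {
  if (length(negative) < length(input)) {
    stop("negative set must be at least as large as the input set",
         call. = FALSE)
  }
  obs <- count_overlap(input, peaks)
  neg_in_peak <- suppressWarnings(
    IRanges::overlapsAny(negative, peaks, ignore.strand = TRUE))
  n_in <- length(input)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_iter), function(i) {
    sum(neg_in_peak[sample.int(length(negative), n_in)])
  }, numeric(1))
  mu <- mean(null_counts)
  sdev <- stats::sd(null_counts)
  degenerate <- FALSE
  if (sdev == 0) {
    if (obs <= mu) {
      z <- 0; p <- 1
    } else {
      degenerate <- TRUE
      z <- Inf; p <- 1 / n_iter
    }
  } else {
    z <- (obs - mu) / sdev
    p <- pnorm(z, lower.tail = FALSE)
  }
  data.frame(dataset = name, n_input = n_in, observed_overlap = obs,
             expected_mean = mu, expected_sd = sdev, z_score = z,
             p_value = p, fold = if (mu > 0) obs / mu else ifelse(obs > 0, Inf, 0),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Batch enrichment across peak datasets with Bonferroni correction
#'
#' Runs [reli_enrichment()] for every dataset and applies Bonferroni
#' correction over the number of datasets actually tested.
#'
#' @param input,negative `GRanges` (see [reli_enrichment()]).
#' @param peak_sets Named list of `GRanges`, one per dataset.
#' @param n_iter Iterations per dataset.
#' @param seed Master seed; each dataset uses a derived sub-seed.
#' @return `data.frame` of per-dataset results with `p_corrected`, sorted
#'   by `p_corrected`.
#' @export
reli_batch <- function(input, negative, peak_sets, n_iter = 2000, seed = 1) {
  stopifnot(length(peak_sets) > 0, !is.null(names(peak_sets)))
  res <- do.call(rbind, lapply(seq_along(peak_sets), function(i) {
    reli_enrichment(input, negative, peak_sets[[i]], n_iter = n_iter,
                    seed = derive_seed(seed, i), name = names(peak_sets)[i])
  }))
  res$p_corrected <- pmin(1, res$p_value * length(peak_sets))
  res[order(res$p_corrected, res$p_value), ]
}
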