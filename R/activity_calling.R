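## Enhancer-activity calling: mRNA vs plasmid differential test per oligo
## under a negative-binomial model, then enAllele/enVar decision rules.

#' Median-of-ratios size factors
#'
#' Classic count-library normalization: each sample's factor is the median
#' across zero-free rows of the ratio between its count and the row
#' geometric mean.
#'
#' @param counts Integer matrix, oligos x samples.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  zero_free <- rowSums(counts == 0) == 0
  if (!any(zero_free)) {
    stop("no zero-free row: add a pseudocount or filter low-count oligos",
         call. = FALSE)
  }
  log_geo <- rowMeans(log(counts[zero_free, , drop = FALSE]))
  sf <- apply(counts[zero_free, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geo))
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("size factors must be finite and positive", call. = FALSE)
  }
  sf
}

## Per-oligo method-of-moments NB dispersion from normalized counts:
## alpha = (s^2 - mu) / mu^2, averaging within-group moments so that a
## true group effect does not inflate the estimate.
.dispersion_mom <- function(norm_counts, groups) {
  n <- nrow(norm_counts)
  groups_u <- unique(groups)
  mu_mat <- matrix(0, n, length(groups_u))
  s2_mat <- matrix(0, n, length(groups_u))
  for (k in seq_along(groups_u)) {
    m <- norm_counts[, groups == groups_u[k], drop = FALSE]
    mu_mat[, k] <- rowMeans(m)
    s2_mat[, k] <- apply(m, 1, var)
  }
  mu <- rowMeans(mu_mat)
  s2 <- rowMeans(s2_mat)
  list(mu = mu, alpha = (s2 - mu) / mu^2)
}

#' Estimate per-oligo negative-binomial dispersions
#'
#' Raw per-oligo dispersions come from the method of moments on
#' size-factor-normalized counts (within-group moments averaged across
#' groups). With the few replicates typical of MPRA (n = 3 per group)
#' these raw values are far too noisy to plug into a Wald test, so the
#' default `"trended"` method fits a mean-dependent trend
#' `alpha(mu) = a0 + a1/mu` to the raw values by least squares and uses
#' the fitted value for every oligo; `"per_oligo"` uses each oligo's own
#' moment estimate. Both are floored at `floor_alpha`.
#'
#' @param norm_counts Normalized count matrix (oligos x samples).
#' @param groups Character vector (length = ncol) of group labels.
#' @param method `"trended"` (default) or `"per_oligo"`.
#' @param floor_alpha Lower bound on the dispersion (default 0.01).
#' @return Numeric vector of dispersions, one per oligo.
#' @export
estimate_dispersions <- function(norm_counts, groups,
                                 method = c("trended", "per_oligo"),
                                 floor_alpha = 0.01) {
  method <- match.arg(method)
  mom <- .dispersion_mom(norm_counts, groups)
  if (method == "per_oligo") {
    return(pmax(mom$alpha, floor_alpha))
  }
  ok <- is.finite(mom$alpha) & is.finite(mom$mu) & mom$mu > 0
  if (sum(ok) < 10 || stats::sd(1 / mom$mu[ok]) < 1e-12) {
    trend <- rep(mean(mom$alpha[ok]), length(mom$alpha))
  } else {
    fit <- lm(alpha ~ inv_mu,
              data = data.frame(alpha = mom$alpha[ok],
                                inv_mu = 1 / mom$mu[ok]))
    trend <- rep(NA_real_, length(mom$alpha))
    trend[ok] <- predict(fit)
    trend[!ok] <- mean(mom$alpha[ok])
  }
  pmax(trend, floor_alpha)
}

#' Test per-oligo enhancer activity (mRNA vs plasmid)
#'
#' For each oligo, computes the log2 fold change of mean normalized mRNA
#' counts over mean normalized plasmid counts and a two-sided Wald p-value
#' under a negative-binomial model: `SE^2(log2FC) = (1/ln2)^2 *
#' [ (1/n_R)(1/mu_R + alpha) + (1/n_D)(1/mu_D + alpha) ]` by the delta
#' method, with dispersion `alpha` from [estimate_dispersions()].
#' P-values are Benjamini-Hochberg adjusted across all tested oligos.
#'
#' Oligos with zero mRNA counts in every sample get the sentinel
#' `log2_fold_change = -10` and are never called active; oligos with zero
#' plasmid counts everywhere are excluded (`excluded = TRUE`).
#'
#' @param counts Integer matrix, oligos x samples.
#' @param groups Named character vector mapping sample -> role
#'   (`"plasmid_DNA"` or `"mRNA"`), or unnamed in column order.
#' @param dispersion_method Passed to [estimate_dispersions()].
#' @param sf Optional precomputed size factors.
#' @return `data.frame`: `oligo_id`, `base_mean`, `mean_plasmid`,
#'   `mean_rna` (normalized group means), `log2_fold_change`, `p_value`,
#'   `p_adj`, `excluded`.
#' @export
test_activity <- function(counts, groups,
                          dispersion_method = c("trended", "per_oligo"),
                          sf = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  groups <- as.character(groups)
  if (!all(sort(unique(groups)) == c("mRNA", "plasmid_DNA"))) {
    stop("groups must contain exactly the roles plasmid_DNA and mRNA",
         call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  is_rna <- groups == "mRNA"
  n_rna <- sum(is_rna); n_dna <- sum(!is_rna)

  mu_rna <- rowMeans(norm[, is_rna, drop = FALSE])
  mu_dna <- rowMeans(norm[, !is_rna, drop = FALSE])
  excluded <- mu_dna == 0
  zero_rna <- mu_rna == 0

  alpha <- estimate_dispersions(norm[!excluded & !zero_rna, , drop = FALSE],
                                groups, method = dispersion_method)
  alpha_all <- rep(NA_real_, nrow(counts))
  alpha_all[!excluded & !zero_rna] <- alpha

  lfc <- log2(mu_rna / mu_dna)
  se2 <- (1 / log(2)^2) * ((1 / n_rna) * (1 / mu_rna + alpha_all) +
                             (1 / n_dna) * (1 / mu_dna + alpha_all))
  z <- lfc / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  p[excluded] <- NA_real_
  lfc[zero_rna & !excluded] <- -10
  p[zero_rna & !excluded] <- 1

  out <- data.frame(
    oligo_id = rownames(counts),
    base_mean = rowMeans(norm),
    mean_plasmid = mu_dna,
    mean_rna = mu_rna,
    log2_fold_change = lfc,
    p_value = p,
    p_adj = NA_real_,
    excluded = excluded,
    stringsAsFactors = FALSE
  )
  out$p_adj[!excluded] <- p.adjust(out$p_value[!excluded], method = "BH")
  rownames(out) <- NULL
  out
}

#' Call enhancer alleles, enhancer variants, and the negative set
#'
#' An oligo is an enAllele when `p_adj < padj_threshold` and its linear
#' fold change is at least `fc_threshold`; a variant is an enVar when any
#' of its alleles is an enAllele; the negative set (for enrichment
#' analyses) is the variants with no allele reaching `p_adj < 0.05` and a
#' fold change above `negative_fc`.
#'
#' @param results Output of [test_activity()].
#' @param oligo_variants Named character vector mapping oligo_id ->
#'   variant id (defaults to the text before the first `|`).
#' @param fc_threshold enAllele fold-change threshold (default 1.5).
#' @param padj_threshold Adjusted-p threshold (default 0.05).
#' @param negative_fc Fold change above which a variant leaves the
#'   negative set (default 1.10).
#' @return List with `results` (input plus `is_enAllele`), `enAlleles`,
#'   `enVars`, `non_enVars` (character vectors).
#' @export
call_enhancers <- function(results, oligo_variants = NULL,
                           fc_threshold = 1.5, padj_threshold = 0.05,
                           negative_fc = 1.10) {
  if (is.null(oligo_variants)) {
    oligo_variants <- setNames(sub("\\|.*$", "", results$oligo_id),
                               results$oligo_id)
  }
  fold <- 2^results$log2_fold_change
  results$is_enAllele <- !results$excluded &
    !is.na(results$p_adj) & results$p_adj < padj_threshold &
    fold >= fc_threshold
  variant <- unname(oligo_variants[results$oligo_id])
  enAlleles <- results$oligo_id[results$is_enAllele]
  enVars <- sort(unique(variant[results$is_enAllele]))
  active_any <- !results$excluded & !is.na(results$p_adj) &
    results$p_adj < 0.05 & fold > negative_fc
  tested_variants <- sort(unique(variant[!results$excluded]))
  non_enVars <- setdiff(tested_variants, unique(variant[active_any]))
  list(results = results, enAlleles = enAlleles, enVars = enVars,
       non_enVars = non_enVars)
}
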