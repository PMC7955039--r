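## Binding-site altering events, variant overlapping vs variant adjacent
## TF classification, and the family-level proportions tests.

#' Padded allele sequences for motif scoring
#'
#' Each allele of a variant is padded with `pad` bases of genomic flank
#' on both sides — enough to cover any known human TF binding site at
#' the default 25 — and the allele's position within the padded sequence
#' is recorded.
#'
#' @param variant One-row variant table.
#' @param genome Named `DNAStringSet`.
#' @param pad Flank length (default 25).
#' @return Named list (one entry per allele) of lists `seq`,
#'   `variant_range` (1-based inclusive positions of the allele bases).
#' @export
padded_allele_seqs <- function(variant, genome, pad = 25L) {
  variant <- validate_variants(variant)
  chrom_seq <- toupper(as.character(genome[[variant$chrom]]))
  alleles <- c(variant$ref, strsplit(variant$alts, ",")[[1]])
  pos <- variant$pos
  up <- substr(chrom_seq, pos - pad, pos - 1L)
  down <- substr(chrom_seq, pos + nchar(variant$ref),
                 pos + nchar(variant$ref) + pad - 1L)
  out <- lapply(alleles, function(a) {
    list(seq = paste0(up, a, down),
         variant_range = c(pad + 1L, pad + nchar(a)))
  })
  names(out) <- alleles
  out
}

#' Detect binding-site altering events between alleles
#'
#' For every motif and unordered allele pair, compares the best relative
#' PWM scores of windows overlapping the variant; an event is recorded
#' when one allele scores at or above `strong_threshold` percent and the
#' other below `weak_threshold` percent.
#'
#' @param allele_seqs Output of [padded_allele_seqs()].
#' @param pwms Named list of `pwm` objects.
#' @param variant_id Variant identifier carried into the result.
#' @param strong_threshold,weak_threshold Relative-score thresholds
#'   (defaults 70 and 40).
#' @param restrict_to_variant Compare only windows covering the variant
#'   (default `TRUE`).
#' @return `data.frame`: `variant_id`, `tf_name`, `family`,
#'   `strong_allele`, `weak_allele`, `strong_score`, `weak_score`.
#' @export
detect_altering_events <- function(allele_seqs, pwms, variant_id = NA,
                                   strong_threshold = 70,
                                   weak_threshold = 40,
                                   restrict_to_variant = TRUE) {
  stopifnot(length(allele_seqs) >= 2)
  alleles <- names(allele_seqs)
  rows <- list()
  for (p in pwms) {
    rel <- vapply(allele_seqs, function(a) {
      relative_best_score(p, a$seq, variant_range = a$variant_range,
                          restrict_to_variant = restrict_to_variant)$relative
    }, numeric(1))
    for (pr in utils::combn(alleles, 2, simplify = FALSE)) {
      s <- rel[pr]
      if (anyNA(s)) next
      hi <- which.max(s); lo <- which.min(s)
      if (s[hi] >= strong_threshold && s[lo] < weak_threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = variant_id, tf_name = p$tf_name, family = p$family,
          strong_allele = pr[hi], weak_allele = pr[lo],
          strong_score = unname(s[hi]), weak_score = unname(s[lo]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(variant_id = character(), tf_name = character(),
                      family = character(), strong_allele = character(),
                      weak_allele = character(), strong_score = numeric(),
                      weak_score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify allelically bound TFs as variant overlapping or adjacent
#'
#' A TF with allelic ChIP-seq reads at the variant and a binding-site
#' altering event for any of its motifs is variant overlapping; with
#' allelic reads but no altering event it is variant adjacent. TFs
#' without allelic reads are not classified.
#'
#' @param allelic_proteins Character vector of proteins with retained
#'   allelic binding at this variant (from
#'   [apply_consistency_filters()]).
#' @param events Altering events for this variant (from
#'   [detect_altering_events()]).
#' @param pwms Motif collection; TFs absent from it are flagged
#'   `no_motif`.
#' @return `data.frame`: `tf_name`, `class`
#'   (`variant_overlapping`/`variant_adjacent`), `no_motif`.
#' @export
classify_tfs <- function(allelic_proteins, events, pwms) {
  motif_tfs <- unique(vapply(pwms, function(p) p$tf_name, character(1)))
  altered <- unique(events$tf_name)
  data.frame(
    tf_name = allelic_proteins,
    class = ifelse(allelic_proteins %in% altered,
                   "variant_overlapping", "variant_adjacent"),
    no_motif = !(allelic_proteins %in% motif_tfs),
    stringsAsFactors = FALSE
  )
}

#' Two-proportion z-test
#'
#' Pooled-variance z statistic for the difference between two binomial
#' proportions, with a two-sided normal p-value.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List: `z`, `p_value`, `p1`, `p2`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Family-level enrichment of altering events at allelic enVars
#'
#' For each motif family, compares the fraction of allelic enVars with a
#' binding-site altering event against the same fraction at non-allelic
#' enVars (two-sided two-proportion z-test, BH-corrected across
#' families). The full table is returned; `reported` marks rows passing
#' the event-count and significance filters.
#'
#' @param events_allelic,events_background Altering-event tables for the
#'   allelic and non-allelic enVar sets.
#' @param n_allelic,n_background Number of variants scored in each set.
#' @param min_events Minimum allelic-set events to report (default 3).
#' @param padj_threshold Reporting threshold on `p_adj` (default 1e-4).
#' @return `data.frame` per family: `family`, `n_events_allelic`,
#'   `n_events_background`, `frac_allelic`, `frac_background`, `z`,
#'   `p_value`, `p_adj`, `reported`.
#' @export
overlapping_family_enrichment <- function(events_allelic, events_background,
                                          n_allelic, n_background,
                                          min_events = 3,
                                          padj_threshold = 1e-4) {
  families <- sort(unique(c(events_allelic$family, events_background$family)))
  if (length(families) == 0 || n_allelic == 0 || n_background == 0) {
    stop("no events or empty variant sets", call. = FALSE)
  }
  count_vars <- function(ev, fam) {
    length(unique(ev$variant_id[ev$family == fam]))
  }
  rows <- lapply(families, function(fam) {
    x1 <- count_vars(events_allelic, fam)
    x2 <- count_vars(events_background, fam)
    zt <- two_proportion_z(x1, n_allelic, x2, n_background)
    data.frame(family = fam, n_events_allelic = x1, n_events_background = x2,
               frac_allelic = zt$p1, frac_background = zt$p2,
               z = zt$z, p_value = zt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out$reported <- out$n_events_allelic >= min_events &
    out$p_adj < padj_threshold
  out[order(out$p_adj), ]
}

#' Family-level motif enrichment in allelic enVar sequences
#'
#' Scans the full-length enVar core sequences and their dinucleotide
#' scrambles for motif hits (best relative score at or above
#' `hit_threshold` anywhere in the sequence) and compares per-family hit
#' fractions between foreground and background with a two-sided
#' two-proportion z-test, BH-corrected across families.
#'
#' @param seqs Character vector of (typically 170-bp) sequences.
#' @param pwms Named list of `pwm` objects.
#' @param seed Seed for the dinucleotide shuffles.
#' @param hit_threshold Relative-score hit cutoff (default 70).
#' @param min_sites Minimum foreground hits to report (default 5).
#' @param padj_threshold Reporting threshold on `p_adj` (default 1e-4).
#' @return `data.frame` per family: hit counts/fractions, `z`, `p_value`,
#'   `p_adj`, `reported`.
#' @export
adjacent_motif_enrichment <- function(seqs, pwms, seed = 1,
                                      hit_threshold = 70, min_sites = 5,
                                      padj_threshold = 1e-4) {
  stopifnot(length(seqs) > 0)
  bg <- vapply(seq_along(seqs), function(i) {
    dinuc_shuffle(seqs[i], seed = derive_seed(seed, i))
  }, character(1))
  families <- sort(unique(vapply(pwms, function(p) p$family, character(1))))
  hit_mat <- function(sequences) {
    vapply(families, function(fam) {
      fam_pwms <- Filter(function(p) p$family == fam, pwms)
      vapply(sequences, function(s) {
        any(vapply(fam_pwms, function(p) {
          r <- relative_best_score(p, s)$relative
          !is.na(r) && r >= hit_threshold
        }, logical(1)))
      }, logical(1))
    }, logical(length(sequences)))
  }
  fg_hits <- hit_mat(seqs)
  bg_hits <- hit_mat(bg)
  rows <- lapply(seq_along(families), function(i) {
    x1 <- sum(fg_hits[, i]); x2 <- sum(bg_hits[, i])
    zt <- two_proportion_z(x1, length(seqs), x2, length(bg))
    data.frame(family = families[i], n_hits_fg = x1, n_hits_bg = x2,
               frac_fg = zt$p1, frac_bg = zt$p2, z = zt$z,
               p_value = zt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out$reported <- out$n_hits_fg >= min_sites & out$p_adj < padj_threshold
  out[order(out$p_adj), ]
}

#' Best-hit position offsets relative to the variant
#'
#' For each classified TF, locates the best-scoring motif window in each
#' allele's padded sequence (restricted to variant-overlapping windows
#' for variant overlapping TFs, unrestricted otherwise) and reports the
#' offset of the window center from the variant center.
#'
#' @param tf_classes Output of [classify_tfs()].
#' @param allele_seqs Output of [padded_allele_seqs()].
#' @param pwms Motif collection (motifs of unclassified TFs ignored).
#' @return `data.frame`: `tf_name`, `class`, `allele`, `offset`
#'   (window center minus variant center, bases; negative = upstream).
#' @export
hit_position_distribution <- function(tf_classes, allele_seqs, pwms) {
  rows <- list()
  for (i in seq_len(nrow(tf_classes))) {
    tf <- tf_classes$tf_name[i]
    cls <- tf_classes$class[i]
    tf_pwms <- Filter(function(p) p$tf_name == tf, pwms)
    if (length(tf_pwms) == 0) next
    for (al in names(allele_seqs)) {
      a <- allele_seqs[[al]]
      var_center <- mean(a$variant_range)
      best <- NULL
      for (p in tf_pwms) {
        h <- relative_best_score(p, a$seq, variant_range = a$variant_range,
                                 restrict_to_variant =
                                   cls == "variant_overlapping")
        if (!is.na(h$relative) &&
            (is.null(best) || h$relative > best$relative)) {
          best <- c(h, list(width = p$width))
        }
      }
      if (is.null(best)) next
      center <- best$offset + (best$width - 1) / 2
      rows[[length(rows) + 1L]] <- data.frame(
        tf_name = tf, class = cls, allele = al,
        offset = center - var_center, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(tf_name = character(), class = character(),
                      allele = character(), offset = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
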