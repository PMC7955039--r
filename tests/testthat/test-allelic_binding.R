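test_that("strength statistic matches its closed form on worked examples", {
  expect_equal(strength(100, 50), 0.5)      # strong allele has twice the reads
  expect_equal(strength(7, 7), 0)
  expect_equal(strength(77, 18), 1 - 18 / 77)
  expect_equal(strength(18, 77), strength(77, 18))     # label symmetry
  expect_equal(strength(3 * 77, 3 * 18), strength(77, 18))  # scale invariance
  expect_error(strength(0, 0), "undefined")
  expect_error(strength(-1, 5), "non-negative")
})

test_that("replicated imbalanced reads are called allelic; weak or conflicting are not", {
  hit <- call_allelic_dataset(c(77, 66), c(18, 23))
  expect_true(hit$is_allelic)
  expect_equal(hit$preferred_allele, 1L)
  expect_equal(hit$score, min(1 - 18 / 77, 1 - 23 / 66))

  weak <- call_allelic_dataset(9, 7)
  expect_false(weak$is_allelic)
  expect_lt(weak$score, 0.4)

  conflict <- call_allelic_dataset(c(30, 12), c(10, 28))
  expect_equal(conflict$score, 0)
  expect_false(conflict$is_allelic)

  tied <- call_allelic_dataset(c(20, 15), c(20, 25))
  expect_equal(tied$score, 0)              # tied replicate breaks consistency

  low <- call_allelic_dataset(5, 0)        # strength 1 but < 6 total reads
  expect_false(low$is_allelic)

  dropped <- call_allelic_dataset(c(40, 0), c(10, 0))
  expect_equal(dropped$dropped_replicates, 1L)
  expect_equal(dropped$n_replicates_used, 1L)
})

make_calls <- function(is_allelic, preferred, consistent = TRUE,
                       variant = "v1", protein = "TF1") {
  n <- length(is_allelic)
  data.frame(variant_id = variant, cell_line = paste0("CL", seq_len(n)),
             dataset_id = paste0("DS", seq_len(n)), protein = protein,
             score = ifelse(is_allelic, 0.6, 0.1), is_allelic = is_allelic,
             preferred_allele = preferred,
             consistent = rep_len(consistent, n),
             binom_p = ifelse(is_allelic, 0.001, 0.5),
             total_reads = 80L, stringsAsFactors = FALSE)
}

test_that("consistency filters implement the 50% / 75% / replicate rules", {
  # allelic in 1 of 4 heterozygous datasets (25%) -> removed
  f1 <- apply_consistency_filters(make_calls(c(TRUE, FALSE, FALSE, FALSE),
                                             c(1L, NA, NA, NA)))
  expect_equal(nrow(f1), 0L)

  # allelic in 2 of 4 (exactly 50%) -> boundary kept
  f2 <- apply_consistency_filters(make_calls(c(TRUE, TRUE, FALSE, FALSE),
                                             c(1L, 1L, NA, NA)))
  expect_equal(nrow(f2), 1L)
  expect_equal(f2$consensus_allele, 1L)

  # 3 of 4 allelic datasets prefer allele 1 (exactly 75%) -> kept
  f3 <- apply_consistency_filters(make_calls(rep(TRUE, 4), c(1L, 1L, 1L, 2L)))
  expect_equal(nrow(f3), 1L)
  expect_equal(f3$frac_same_allele, 0.75)

  # 2 allelic datasets preferring opposite alleles (50% < 75%) -> removed
  f4 <- apply_consistency_filters(make_calls(c(TRUE, TRUE), c(1L, 2L)))
  expect_equal(nrow(f4), 0L)

  # replicate-inconsistent allelic dataset -> removed
  f5 <- apply_consistency_filters(make_calls(c(TRUE, TRUE), c(1L, 1L),
                                             consistent = c(TRUE, FALSE)))
  expect_equal(nrow(f5), 0L)
})

test_that("filters only remove events, never add them", {
  calls <- make_calls(c(TRUE, TRUE, FALSE), c(1L, 1L, NA))
  kept <- apply_consistency_filters(calls)
  expect_true(all(paste(kept$variant_id, kept$protein) %in%
                    paste(calls$variant_id, calls$protein)))
})

test_that("profile summary reports the median strength and (k of n) label", {
  calls <- make_calls(c(TRUE, TRUE, TRUE, FALSE), c(1L, 1L, 1L, NA))
  calls$score[calls$is_allelic] <- c(0.5, 0.7, 0.9)
  kept <- apply_consistency_filters(calls)
  prof <- summarize_allelic_profile(kept, calls)
  expect_equal(prof$median_strength, 0.7)
  expect_identical(prof$label, "(3 of 4)")
})

test_that("null binomial reads rarely reach an allelic call", {
  set.seed(31)
  n_data <- 400
  frac <- mean(vapply(seq_len(n_data), function(i) {
    r1 <- rbinom(2, 40, 0.5)
    call_allelic_dataset(r1, 40 - r1)$is_allelic
  }, logical(1)))
  expect_lt(frac, 0.05)
})

test_that("a planted 0.8 / 0.2 imbalance is recovered reliably", {
  set.seed(37)
  hits <- vapply(1:500, function(i) {
    r1 <- rbinom(2, 40, 0.8)
    call_allelic_dataset(r1, 40 - r1)$is_allelic
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("score_allelic_reads honours het/in_peak gating end to end", {
  v <- data.frame(id = c("v1", "v2"), chrom = "chr1", pos = c(300L, 600L),
                  ref = "A", alts = "G", stringsAsFactors = FALSE)
  chip <- gen_chipseq_data(v, n_datasets = 4, target_ids = c("v1", "v2"),
                           p_target = 1, allelic_ratio = c(v1 = 0.85, v2 = 0.5),
                           n_reads = 60, n_replicates = 2, seed = 5)
  calls <- score_allelic_reads(chip$allelic_reads)
  expect_true(all(calls$is_allelic[calls$variant_id == "v1"]))
  expect_false(any(calls$is_allelic[calls$variant_id == "v2"]))
  kept <- apply_consistency_filters(calls)
  expect_true("v1" %in% kept$variant_id)
  expect_false("v2" %in% kept$variant_id)

  none <- chip$allelic_reads
  none$het <- FALSE
  expect_equal(nrow(score_allelic_reads(none)), 0L)
})
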