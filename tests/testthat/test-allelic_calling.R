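sheet2 <- data.frame(sample = c("p1", "p2", "m1", "m2"),
                     role = c("plasmid_DNA", "plasmid_DNA", "mRNA", "mRNA"),
                     replicate = c(1L, 2L, 1L, 2L))

long_counts <- function(bc, sample, count) {
  data.frame(barcode = bc, sample = sample, count = count,
             stringsAsFactors = FALSE)
}

test_that("normalized log ratios match the closed form with pseudocount 1", {
  sf <- setNames(rep(1, 4), sheet2$sample)
  # rna = dna everywhere -> all ratios 0 (dna pooled over 2 reps, sf sums)
  bc <- rbind(long_counts(c("b1", "b2"), "p1", c(4, 8)),
              long_counts(c("b1", "b2"), "p2", c(4, 8)),
              long_counts(c("b1", "b2"), "m1", c(4, 8)),
              long_counts(c("b1", "b2"), "m2", c(4, 8)))
  r <- normalized_log_ratios(bc, sheet2, sf)
  expect_equal(r, rep(0, 2))               # one ratio per barcode

  # pseudocount arithmetic: rna 0, dna 3 in each replicate, sf 1
  # pooled: rna 0/2, dna 6/2 = 3 -> log2((0+1)/(3+1)) = -2
  bc0 <- rbind(long_counts("b1", "p1", 3), long_counts("b1", "p2", 3),
               long_counts("b1", "m1", 0), long_counts("b1", "m2", 0))
  expect_equal(normalized_log_ratios(bc0, sheet2, sf), log2(1 / 4))

  # rna exactly 2x dna at large counts -> ratios approach 1
  big <- 1e6
  bc2 <- rbind(long_counts("b1", "p1", big), long_counts("b1", "p2", big),
               long_counts("b1", "m1", 2 * big), long_counts("b1", "m2", 2 * big))
  expect_equal(normalized_log_ratios(bc2, sheet2, sf), 1,
               tolerance = 1e-5)

  expect_error(normalized_log_ratios(bc0[0, ], sheet2, sf), "zero barcodes")
})

test_that("identical allele ratio lists give t = 0, p = 1, not allelic", {
  ratios <- list(A = c(0.1, 0.2, 0.3, 0.4), G = c(0.1, 0.2, 0.3, 0.4))
  res <- test_allelic(ratios, "v1", ref_allele = "A")
  expect_equal(res$delta_log2, 0)
  expect_equal(res$p_value, 1)
})

test_that("allele-label symmetry flips delta and inverts the fold", {
  set.seed(5)
  ratios <- list(A = rnorm(40, 0, 0.5), G = rnorm(40, 0.6, 0.5))
  fwd <- test_allelic(ratios, "v1", ref_allele = "A")
  rev <- test_allelic(ratios[c("G", "A")], "v1", ref_allele = "G")
  expect_equal(fwd$delta_log2, -rev$delta_log2)
  expect_equal(fwd$fold_between_alleles, 1 / rev$fold_between_alleles)
  expect_equal(fwd$p_value, rev$p_value)
  # against the base pooled-variance t-test as oracle
  tt <- t.test(ratios$G, ratios$A, var.equal = TRUE)
  expect_equal(fwd$p_value, tt$p.value)
})

test_that("the 25% fold rule gates significance", {
  # strongly significant but small shift: delta under log2(1.25)
  set.seed(8)
  delta_small <- 0.2                       # fold 1.15 < 1.25
  ratios <- list(A = rnorm(5000, 0, 0.3), G = rnorm(5000, delta_small, 0.3))
  man <- test_allelic(ratios, "v1")
  man$p_adj <- man$p_value
  expect_lt(man$p_adj, 0.05)
  expect_lt(man$fold_between_alleles, 1.25)
})

test_that("planted allelic shift of one log2 unit is detected at high power", {
  set.seed(7)
  n_var <- 60; planted <- 1:30
  pairs <- do.call(rbind, lapply(seq_len(n_var), function(i) {
    d <- if (i %in% planted) 1.0 else 0
    test_allelic(list(A = rnorm(300, 0, 0.8), G = rnorm(300, d, 0.8)),
                 sprintf("v%03d", i), ref_allele = "A")
  }))
  pairs$p_adj <- p.adjust(pairs$p_value, "BH")
  pairs$is_allelic <- pairs$p_adj < 0.05 &
    (pairs$fold_between_alleles >= 1.25 | pairs$fold_between_alleles <= 0.8)
  expect_gte(mean(pairs$is_allelic[planted]), 0.9)
  expect_lte(mean(pairs$is_allelic[-planted]), 0.1)
})

test_that("detection rate rises with the planted shift", {
  rates <- vapply(c(0, 0.2, 0.5, 1.0), function(d) {
    set.seed(13)
    hits <- vapply(1:40, function(i) {
      r <- test_allelic(list(A = rnorm(80, 0, 0.8), G = rnorm(80, d, 0.8)),
                        "v")
      r$p_value < 0.05 &&
        (r$fold_between_alleles >= 1.25 || r$fold_between_alleles <= 0.8)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("end-to-end allelic calling recovers a planted 2x allele ratio", {
  man <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(variant_id = sprintf("v%02d", i), allele = c("A", "G"),
               oligo_id = sprintf("v%02d|%s|forward", i, c("A", "G")),
               stringsAsFactors = FALSE)
  }))
  eff <- data.frame(variant_id = rep(sprintf("v%02d", 1:10), each = 2),
                    allele = rep(c("A", "G"), 10),
                    fold = rep(c(2, 4), c(19, 1)))  # v10|G planted at 2x
  mpra <- gen_mpra_counts(man, effects = eff, barcode_median = 300, seed = 21)
  variants <- data.frame(id = sprintf("v%02d", 1:10), ref = "A",
                         stringsAsFactors = FALSE)
  res <- call_allelic(mpra$barcode_counts, mpra$sample_sheet,
                      en_vars = sprintf("v%02d", 1:10), variants = variants)
  expect_identical(res$allelic_enVars, "v10")
  v10 <- res$pairs[res$pairs$variant_id == "v10", ]
  expect_gt(v10$fold_between_alleles, 1.25)
  # null variants calibrate: no other pair reaches both gates
  expect_false(any(res$pairs$is_allelic[res$pairs$variant_id != "v10"]))
})

test_that("genotype dependence summary reports the most significant pair", {
  allelic <- list(pairs = data.frame(
    variant_id = c("v1", "v1"), allele1 = c("A", "A"), allele2 = c("C", "G"),
    n1 = 10, n2 = 10, delta_log2 = c(0.5, 1),
    fold_between_alleles = c(2^0.5, 2), p_value = c(0.2, 0.001),
    skipped = FALSE, p_adj = c(0.2, 0.002), is_allelic = c(FALSE, TRUE),
    stringsAsFactors = FALSE))
  activity <- data.frame(oligo_id = c("v1|A", "v1|C", "v1|G"),
                         log2_fold_change = c(0, 0.5, 1),
                         excluded = FALSE, stringsAsFactors = FALSE)
  s <- genotype_dependence_summary(allelic, activity, "v1")
  expect_equal(s$max_activity_fold, 2)
  expect_equal(s$genotype_dependence, 2)    # pair with smallest p_adj
  expect_true(s$is_allelic)
})
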