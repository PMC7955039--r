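# Shared fixtures, all built in code.

# A deterministic toy genome: one 600-bp chromosome whose sequence is a
# fixed pseudo-random ACGT string (seeded), exposed as a DNAStringSet.
toy_genome <- function(len = 600L, chrom = "chr1", seed = 42) {
  set.seed(seed)
  seqs <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(seqs) <- chrom
  seqs
}

toy_variant <- function(id = "rs1", chrom = "chr1", pos = 300L,
                        genome = toy_genome(), alt = NULL) {
  ref <- substr(as.character(genome[[chrom]]), pos, pos)
  if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  data.frame(id = id, chrom = chrom, pos = pos, ref = ref, alts = alt,
             risk_allele = alt, locus_id = "L1", stringsAsFactors = FALSE)
}

# A sharply informative width-6 PWM with consensus ACGTAC.
toy_pwm <- function(dominance = 0.91, name = "TFX", family = "FAMX") {
  cons <- c(1, 2, 3, 4, 1, 2)
  mat <- matrix((1 - dominance) / 3, nrow = 4, ncol = 6)
  mat[cbind(cons, 1:6)] <- dominance
  pwm(mat, tf_name = name, family = family)
}

# Brute-force window scorer used as the independent oracle for the
# scanner: explicit per-position loop over log2(p/bg).
oracle_window_score <- function(p, window, strand = "+") {
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    window <- paste(rev(comp[strsplit(window, "")[[1]]]), collapse = "")
  }
  chars <- strsplit(window, "")[[1]]
  total <- 0
  for (j in seq_along(chars)) {
    total <- total + log2(p$matrix[chars[j], j] / p$background[[chars[j]]])
  }
  unname(total)
}

dinuc_counts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  table(paste0(chars[-length(chars)], chars[-1]))
}
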