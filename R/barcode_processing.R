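## Barcode processing: constant-region read filtering, barcode -> oligo
## association, and oligo-level count matrices.

BARCODE_LENGTH <- 20L

#' Extract a barcode from a reporter read via the constant-region filter
#'
#' A read is laid out as `[20-bp barcode][constant region]`. The read is
#' kept iff the Levenshtein distance between its constant segment and the
#' reference constant region is at most `max_dist` AND the two bases
#' directly adjacent to the barcode (the first two bases of the constant
#' segment) match the reference exactly.
#'
#' @param reads Character vector of read sequences.
#' @param constant_ref Reference constant region (from the reporter
#'   3' UTR, immediately 3' of the barcode slot).
#' @param max_dist Maximum Levenshtein distance in the constant region
#'   (default 4).
#' @param barcode_len Barcode length (default 20).
#' @return `data.frame` with columns `read`, `barcode` (`NA` on
#'   rejection), `accepted`, `reason` (`""`, `"too_short"`,
#'   `"adjacent_mismatch"`, or `"constant_distance"`).
#' @export
match_constant_region <- function(reads, constant_ref, max_dist = 4L,
                                  barcode_len = BARCODE_LENGTH) {
  stopifnot(nchar(constant_ref) >= 2)
  n <- length(reads)
  barcode <- rep(NA_character_, n)
  reason <- character(n)
  min_len <- barcode_len + 2L
  too_short <- nchar(reads) < min_len
  reason[too_short] <- "too_short"
  ok <- !too_short
  if (any(ok)) {
    const_seg <- substr(reads[ok], barcode_len + 1L,
                        barcode_len + nchar(constant_ref))
    adj_ok <- substr(const_seg, 1L, 2L) == substr(constant_ref, 1L, 2L)
    dist <- as.integer(adist(const_seg, constant_ref))
    pass <- adj_ok & dist <= max_dist
    idx <- which(ok)
    barcode[idx[pass]] <- substr(reads[idx[pass]], 1L, barcode_len)
    reason[idx[!adj_ok]] <- "adjacent_mismatch"
    reason[idx[adj_ok & dist > max_dist]] <- "constant_distance"
  }
  data.frame(read = reads, barcode = barcode,
             accepted = !is.na(barcode), reason = reason,
             stringsAsFactors = FALSE)
}

#' Build a barcode-to-oligo map, dropping ambiguous barcodes
#'
#' Barcodes observed with two or more distinct oligos are discarded; the
#' remainder map uniquely.
#'
#' @param observations `data.frame` with columns `barcode`, `oligo_id`
#'   (repeated observations allowed).
#' @return `data.frame` (`barcode`, `oligo_id`), one row per retained
#'   barcode; attribute `n_ambiguous` records how many barcodes were
#'   dropped.
#' @export
build_barcode_map <- function(observations) {
  if (nrow(observations) == 0) {
    out <- data.frame(barcode = character(), oligo_id = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_ambiguous") <- 0L
    return(out)
  }
  .stopifnot_cols(observations, c("barcode", "oligo_id"), "observations")
  uniq <- unique(observations[, c("barcode", "oligo_id")])
  tab <- table(uniq$barcode)
  ambiguous <- names(tab)[tab > 1]
  out <- uniq[!(uniq$barcode %in% ambiguous), , drop = FALSE]
  out <- out[order(out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ambiguous") <- length(ambiguous)
  out
}

## Collapse "variant|allele|orientation" oligo ids to "variant|allele":
## forward and reverse-complement synthesis products of one allele are a
## single analysis unit.
merge_orientation <- function(oligo_id) {
  sub("\\|(forward|reverse_complement)$", "", oligo_id)
}

#' Summarize barcode counts to an oligo-level count matrix
#'
#' Maps each observed barcode to its oligo, sums counts per
#' (oligo, sample), merges forward/reverse-complement records of an
#' allele into one row, and removes oligos with fewer than `min_barcodes`
#' distinct barcodes in the plasmid control.
#'
#' @param barcode_counts Long `data.frame`: `barcode`, `sample`, `count`.
#' @param map Barcode map from [build_barcode_map()].
#' @param sample_sheet `data.frame`: `sample`, `role`
#'   (`plasmid_DNA`/`mRNA`), `replicate`.
#' @param min_barcodes Minimum distinct plasmid-control barcodes per oligo
#'   (default 30).
#' @return List with `counts` (integer matrix, oligos x samples),
#'   `barcode_multiplicity` (named vector, distinct plasmid barcodes per
#'   retained oligo), `unmapped` (per-sample tally of counts whose barcode
#'   was not in the map), and `filtered_oligos` (ids removed by the
#'   minimum-barcode filter).
#' @export
count_barcodes <- function(barcode_counts, map, sample_sheet,
                           min_barcodes = 30L) {
  .stopifnot_cols(barcode_counts, c("barcode", "sample", "count"),
                  "barcode counts")
  .stopifnot_cols(sample_sheet, c("sample", "role"), "sample sheet")
  if (nrow(map) == 0) stop("barcode map is empty", call. = FALSE)
  samples <- sample_sheet$sample
  bc <- barcode_counts[barcode_counts$sample %in% samples, , drop = FALSE]

  idx <- match(bc$barcode, map$barcode)
  mapped <- !is.na(idx)
  unmapped <- vapply(samples, function(s) {
    sum(bc$count[!mapped & bc$sample == s])
  }, numeric(1))
  bc <- bc[mapped, , drop = FALSE]
  bc$oligo <- merge_orientation(map$oligo_id[idx[mapped]])

  oligos <- sort(unique(bc$oligo))
  counts <- matrix(0L, nrow = length(oligos), ncol = length(samples),
                   dimnames = list(oligos, samples))
  agg <- tapply(bc$count, list(bc$oligo, bc$sample), sum)
  counts[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0L, agg)
  storage.mode(counts) <- "integer"

  zero_cols <- colSums(counts) == 0
  if (any(zero_cols)) {
    warning("sample(s) with zero mapped barcodes: ",
            paste(samples[zero_cols], collapse = ", "))
  }

  plasmid_samples <- sample_sheet$sample[sample_sheet$role == "plasmid_DNA"]
  in_plasmid <- bc[bc$sample %in% plasmid_samples & bc$count > 0, , drop = FALSE]
  mult <- tapply(in_plasmid$barcode, in_plasmid$oligo,
                 function(b) length(unique(b)))
  multiplicity <- setNames(rep(0L, length(oligos)), oligos)
  multiplicity[names(mult)] <- as.integer(mult)

  keep <- multiplicity >= min_barcodes
  list(
    counts = counts[keep, , drop = FALSE],
    barcode_multiplicity = multiplicity[keep],
    unmapped = unmapped,
    filtered_oligos = oligos[!keep]
  )
}

#' Write a count matrix with a JSON metadata sidecar
#'
#' @param counted Output of [count_barcodes()].
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(counted, path) {
  df <- data.frame(oligo = rownames(counted$counts),
                   counted$counts, check.names = FALSE)
  write_tsv(df, path)
  meta <- list(
    min_barcode_filter = "barcode_multiplicity >= 30 unless overridden",
    n_oligos = nrow(counted$counts),
    n_filtered = length(counted$filtered_oligos),
    unmapped = as.list(counted$unmapped)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
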