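## PWM scoring machinery: construction, MEME-minimal parsing, log2
## likelihood scoring, relative (percent-of-maximum) scores, and the
## dinucleotide shuffle used to build background sequence sets.

#' Construct a position weight matrix object
#'
#' Probabilities are regularized with a per-cell pseudocount and columns
#' renormalized, so every probability is strictly positive before the log
#' transformation.
#'
#' @param matrix Numeric 4 x width matrix of base probabilities, rows in
#'   A, C, G, T order (row names optional).
#' @param tf_name Transcription factor name.
#' @param family Motif family label; falls back to `tf_name`.
#' @param background Base frequencies (default uniform 0.25).
#' @param pseudocount Added to every cell before renormalization
#'   (default 1e-3).
#' @return An object of class `pwm`: list with `tf_name`, `family`,
#'   `matrix`, `background`, `width`, `logodds` (log2 p/bg), `max_score`.
#' @export
pwm <- function(matrix, tf_name, family = tf_name,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 1e-3) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PWM matrix must have 4 rows (A,C,G,T)",
                              call. = FALSE)
  if (ncol(matrix) < 4) stop("PWM width must be >= 4", call. = FALSE)
  if (any(abs(colSums(matrix) - 1) > 1e-6)) {
    stop("PWM columns must each sum to 1", call. = FALSE)
  }
  mat <- sweep(matrix + pseudocount, 2, colSums(matrix + pseudocount), "/")
  rownames(mat) <- DNA_BASES
  background <- background / sum(background)
  logodds <- log2(mat / background)
  obj <- list(tf_name = tf_name, family = family, matrix = mat,
              background = background, width = ncol(mat),
              logodds = logodds, max_score = sum(apply(logodds, 2, max)))
  class(obj) <- "pwm"
  obj
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (family %s), width %d, max score %.2f bits\n",
              x$tf_name, x$family, x$width, x$max_score))
  invisible(x)
}

#' Read motifs from a MEME-minimal text file
#'
#' Supports the minimal format: an optional `Background letter
#' frequencies` line, and per motif a `MOTIF name` line followed by a
#' `letter-probability matrix` header and its rows. A `FAMILY name` line
#' between a MOTIF line and its matrix (an extension) sets the family
#' label; otherwise the alternate motif name, then the motif name, is
#' used.
#'
#' @param path Path to the MEME file.
#' @param pseudocount Passed to [pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1 && bg_at < length(lines)) {
    tok <- strsplit(trimws(lines[bg_at + 1]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg[names(vals)] <- vals
  }
  motif_at <- grep("^MOTIF", lines)
  if (length(motif_at) == 0) stop("no MOTIF records in ", path, call. = FALSE)
  out <- list()
  bounds <- c(motif_at, length(lines) + 1L)
  for (k in seq_along(motif_at)) {
    block <- lines[motif_at[k]:(bounds[k + 1] - 1L)]
    head_tok <- strsplit(trimws(block[1]), "\\s+")[[1]]
    name <- head_tok[2]
    alt <- if (length(head_tok) >= 3) head_tok[3] else NA_character_
    fam_line <- grep("^FAMILY", block, value = TRUE)
    family <- if (length(fam_line)) {
      strsplit(trimws(fam_line[1]), "\\s+")[[1]][2]
    } else if (!is.na(alt)) alt else name
    mat_at <- grep("^letter-probability matrix", block)
    if (length(mat_at) != 1) {
      stop("motif ", name, " lacks a letter-probability matrix", call. = FALSE)
    }
    rows <- list()
    for (ln in block[-seq_len(mat_at)]) {
      if (grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", ln)) {
        rows[[length(rows) + 1L]] <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
      } else if (length(rows) > 0) break
    }
    mat <- t(do.call(rbind, rows))
    out[[name]] <- pwm(mat, tf_name = name, family = family,
                       background = bg, pseudocount = pseudocount)
  }
  out
}

#' Write motifs in MEME-minimal format
#'
#' @param pwms Named list of `pwm` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, pwms[[1]]$background),
                     collapse = " "), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s %s", p$tf_name, p$family), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", p$width),
               con)
    for (j in seq_len(p$width)) {
      writeLines(paste(sprintf("%.6f", p$matrix[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

.seq_to_idx <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  if (anyNA(idx)) stop("sequence contains non-ACGT characters", call. = FALSE)
  idx
}

#' Log2-likelihood score of one window under a PWM
#'
#' Sum over positions of `log2(p_base / background_base)`. The reverse
#' strand scores the reverse complement of the window.
#'
#' @param pwm A `pwm` object.
#' @param window Sequence of length exactly `pwm$width`.
#' @param strand `"+"` or `"-"`.
#' @return Score in bits.
#' @export
loglik_score <- function(pwm, window, strand = "+") {
  if (nchar(window) != pwm$width) {
    stop("window length must equal PWM width", call. = FALSE)
  }
  if (strand == "-") window <- reverse_complement(window)
  idx <- .seq_to_idx(window)
  sum(pwm$logodds[cbind(idx, seq_along(idx))])
}

## All window scores of a sequence on both strands. Returns a data.frame
## (offset = 1-based window start on the forward sequence, strand, score).
scan_pwm <- function(pwm, seq) {
  idx <- .seq_to_idx(seq)
  n <- length(idx) - pwm$width + 1L
  if (n < 1) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  }
  starts <- seq_len(n)
  score_strand <- function(lo) {
    vapply(starts, function(s) {
      w <- idx[s:(s + pwm$width - 1L)]
      sum(lo[cbind(w, seq_len(pwm$width))])
    }, numeric(1))
  }
  fwd <- score_strand(pwm$logodds)
  ## reverse strand: complement rows (A<->T, C<->G) and reverse columns
  lo_rc <- pwm$logodds[4:1, pwm$width:1, drop = FALSE]
  rev <- score_strand(lo_rc)
  data.frame(offset = c(starts, starts),
             strand = rep(c("+", "-"), each = n),
             score = c(fwd, rev), stringsAsFactors = FALSE)
}

#' Best relative PWM score in a sequence
#'
#' Scans both strands of `seq`; the best log2-likelihood score is mapped
#' to the percentage of the motif's maximum achievable score
#' (`100 * score / max_score`). Negative scores stay negative. When
#' `variant_range` is given and `restrict_to_variant = TRUE`, only
#' windows covering at least one base of that range compete.
#'
#' @param pwm A `pwm` object (`max_score` must be positive).
#' @param seq Sequence (e.g. an allele padded with 25 bp of flank).
#' @param variant_range Integer `c(start, end)`, 1-based inclusive
#'   positions of the variant allele within `seq`, or `NULL`.
#' @param restrict_to_variant Restrict windows to those overlapping
#'   `variant_range` (default `FALSE`).
#' @return List: `relative` (percent), `score` (bits), `offset`, `strand`
#'   of the best window; `relative = NA` when no window qualifies.
#' @export
relative_best_score <- function(pwm, seq, variant_range = NULL,
                                restrict_to_variant = FALSE) {
  if (pwm$max_score <= 0) {
    stop("uninformative PWM: maximum achievable score is not positive",
         call. = FALSE)
  }
  hits <- scan_pwm(pwm, seq)
  if (restrict_to_variant) {
    if (is.null(variant_range)) {
      stop("variant_range required when restrict_to_variant = TRUE",
           call. = FALSE)
    }
    covers <- hits$offset <= variant_range[2] &
      (hits$offset + pwm$width - 1L) >= variant_range[1]
    hits <- hits[covers, , drop = FALSE]
  }
  if (nrow(hits) == 0) {
    return(list(relative = NA_real_, score = NA_real_,
                offset = NA_integer_, strand = NA_character_))
  }
  best <- hits[which.max(hits$score), ]
  list(relative = 100 * best$score / pwm$max_score, score = best$score,
       offset = best$offset, strand = best$strand)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: samples uniformly from the sequences with
#' exactly the same dinucleotide counts (hence identical length, start
#' and end bases, and mononucleotide composition) via a random Eulerian
#' path on the dinucleotide multigraph.
#'
#' @param seq Sequence of length >= 2.
#' @param seed Integer seed.
#' @return A shuffled sequence with identical dinucleotide counts.
#' @export
dinuc_shuffle <- function(seq, seed = 1) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < 2) stop("sequence must have length >= 2", call. = FALSE)
  set.seed(seed)
  ## edge list of the dinucleotide multigraph
  from <- chars[-n]; to <- chars[-1]
  verts <- unique(chars)
  last <- chars[n]
  repeat {
    ## pick a random "last edge" into each non-terminal vertex, then check
    ## the chosen last-edge tree connects to the terminal vertex
    last_edge <- vapply(verts, function(v) {
      if (v == last) return(NA_integer_)
      cand <- which(from == v)
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    reaches <- vapply(verts, function(v) {
      steps <- 0L
      while (v != last && steps <= length(verts)) {
        v <- to[last_edge[[v]]]
        steps <- steps + 1L
      }
      v == last
    }, logical(1))
    if (all(reaches)) break
  }
  ## per-vertex edge orderings: random, with the chosen last edge last
  out_edges <- split(seq_len(n - 1L), from)
  ordering <- lapply(names(out_edges), function(v) {
    e <- out_edges[[v]]
    le <- last_edge[[v]]
    if (!is.na(le)) {
      rest <- setdiff(e, le)
      c(rest[sample.int(length(rest))], le)
    } else {
      e[sample.int(length(e))]
    }
  })
  names(ordering) <- names(out_edges)
  ptr <- setNames(rep(1L, length(ordering)), names(ordering))
  walk <- character(n)
  walk[1] <- chars[1]
  v <- chars[1]
  for (i in 2:n) {
    e <- ordering[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    v <- to[e]
    walk[i] <- v
  }
  paste(walk, collapse = "")
}
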