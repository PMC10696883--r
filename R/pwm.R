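#' Convert a position frequency matrix to a log-odds scoring matrix
#'
#' FIMO-style construction: per-position base probabilities are estimated
#' from counts with a background-weighted pseudocount, then divided by the
#' background and log2-transformed, giving weights in bits. A score of 0
#' marks a window no more likely under the motif than under the background,
#' which is the sign convention behind the "PWM score < 0 means non-binding"
#' filter.
#'
#' @param pfm A `pfm` object (see [read_jaspar_pfm()]).
#' @param background Base probabilities in `A,C,G,T` order, summing to 1
#'   (uniform by default).
#' @param pseudocount Total pseudocount added per column, split across bases
#'   proportionally to the background (FIMO's default 0.1).
#' @return An object of class `pwm_log_odds`: list with `weights`
#'   (4 x w, bits), `background`, `pseudocount`, `width`, `motif_id`.
#' @export
pfm_to_log_odds <- function(pfm, background = rep(0.25, 4), pseudocount = 0.1) {
  stopifnot(inherits(pfm, "pfm"))
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    abort("background must be 4 positive probabilities summing to 1")
  }
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  counts <- pfm$counts
  colsum <- colSums(counts)
  if (pseudocount == 0 && any(colsum == 0)) {
    abort("degenerate PFM: zero column sum with pseudocount 0",
          class = "crnntfbs_degenerate_error")
  }
  prob <- sweep(counts + pseudocount * background, 2L,
                colsum + pseudocount, "/")
  weights <- log2(prob / background)
  rownames(weights) <- DNA_BASES
  structure(
    list(weights = weights, background = background,
         pseudocount = pseudocount, width = pfm$width,
         motif_id = pfm$motif_id),
    class = "pwm_log_odds"
  )
}

#' @export
print.pwm_log_odds <- function(x, ...) {
  cat(sprintf("<pwm_log_odds> %s, width %d, pseudocount %g (bits)\n",
              x$motif_id, x$width, x$pseudocount))
  print(round(x$weights, 3))
  invisible(x)
}

#' Score a single window under a log-odds matrix
#'
#' Sums the per-position weights of the window's bases. A window containing
#' `N` is unmatchable and scores `-Inf`.
#'
#' @param lom A `pwm_log_odds` object.
#' @param window DNA string of exactly the matrix width.
#' @return Score in bits.
#' @export
score_window <- function(lom, window) {
  stopifnot(inherits(lom, "pwm_log_odds"))
  window <- assert_dna(window)
  if (nchar(window) != lom$width) {
    abort(sprintf("window length %d != matrix width %d",
                  nchar(window), lom$width),
          class = "crnntfbs_input_error")
  }
  idx <- match(seq_chars(window), DNA_BASES)
  if (anyNA(idx)) return(-Inf)
  sum(lom$weights[cbind(idx, seq_len(lom$width))])
}

# all window scores of one sequence on the forward strand; NA-free ACGT only
score_all_offsets <- function(lom, seq) {
  w <- lom$width
  chars <- match(seq_chars(seq), DNA_BASES)
  L <- length(chars)
  n_off <- L - w + 1L
  scores <- numeric(n_off)
  for (p in seq_len(w)) {
    base_at <- chars[p:(p + n_off - 1L)]
    col <- lom$weights[, p]
    contrib <- unname(col[base_at])
    contrib[is.na(contrib)] <- -Inf      # N anywhere in window
    scores <- scores + contrib
  }
  scores
}

#' Best-scoring PWM hit in a sequence
#'
#' Slides the log-odds matrix along the sequence (and its reverse
#' complement when `both_strands`) and returns the maximal-scoring window.
#' Ties are broken by the smallest offset, then the `+` strand.
#'
#' @param lom A `pwm_log_odds` object.
#' @param seq DNA string of length >= matrix width.
#' @param both_strands Scan both strands (default `TRUE`, FIMO's default).
#' @return One-row tibble: `offset` (0-based window start on the forward
#'   strand), `strand`, `window_seq`, `score` (bits).
#' @export
best_hit <- function(lom, seq, both_strands = TRUE) {
  seq <- assert_dna(seq)
  w <- lom$width
  if (nchar(seq) < w) {
    abort("sequence shorter than matrix width",
          class = "crnntfbs_input_error")
  }
  fwd <- score_all_offsets(lom, seq)
  n_off <- length(fwd)
  best <- list(score = -Inf, offset = NA_integer_, strand = "+")
  take <- function(scores, strand) {
    i <- which.max(scores)
    s <- scores[i]
    # offsets are reported on the forward strand: a hit at offset j of the
    # reverse complement covers forward positions [L - w - j, L - j)
    off <- if (strand == "+") i - 1L else n_off - i
    if (s > best$score ||
        (s == best$score && off < best$offset) ||
        (s == best$score && off == best$offset && strand == "+")) {
      best <<- list(score = s, offset = as.integer(off), strand = strand)
    }
  }
  take(fwd, "+")
  if (both_strands) take(score_all_offsets(lom, reverse_complement(seq)), "-")
  win <- substr(seq, best$offset + 1L, best$offset + w)
  tibble(offset = best$offset, strand = best$strand,
         window_seq = if (best$strand == "+") win else reverse_complement(win),
         score = best$score)
}

#' Scan many sequences with a log-odds matrix
#'
#' Applies [best_hit()] to every record and returns one row per sequence.
#'
#' @param lom A `pwm_log_odds` object.
#' @param seqs Sequence tibble (`id`, `seq`).
#' @param both_strands Scan both strands.
#' @return Tibble with columns `peak_id`, `best_offset`, `strand`,
#'   `best_window`, `score`.
#' @export
pwm_scan <- function(lom, seqs, both_strands = TRUE) {
  hits <- purrr::map(seqs$seq, ~ best_hit(lom, .x, both_strands = both_strands))
  dplyr::bind_cols(
    tibble(peak_id = seqs$id),
    dplyr::bind_rows(hits)
  ) |>
    rename(best_offset = "offset", best_window = "window_seq")
}

#' Consensus sequence of a PFM
#'
#' @param pfm A `pfm` object.
#' @return DNA string of the per-column majority bases.
#' @export
pfm_consensus <- function(pfm) {
  paste(DNA_BASES[apply(pfm$counts, 2L, which.max)], collapse = "")
}
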