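#' Filter peaks by q-value
#'
#' Retains peaks whose q-value is strictly below `q_threshold` (expressed
#' on the linear scale, e.g. `1e-5`); narrowPeak stores `-log10(q)`, so the
#' comparison is `qvalue_mlog10 > -log10(q_threshold)`. Input order is
#' preserved.
#'
#' @param peaks Peak tibble from [read_narrowpeak()].
#' @param q_threshold Linear q-value threshold in `(0, 1]`.
#' @return The retained peaks.
#' @export
filter_peaks <- function(peaks, q_threshold) {
  if (q_threshold <= 0 || q_threshold > 1) {
    abort("q_threshold must be in (0, 1]", class = "crnntfbs_input_error")
  }
  keep <- !is.na(peaks$qvalue_mlog10) &
    peaks$qvalue_mlog10 > -log10(q_threshold)
  out <- peaks[keep, ]
  if (nrow(out) == 0L) inform("no peaks pass the q-value threshold")
  out
}

#' Remove negative peaks that overlap positive peaks
#'
#' Drops every negative sharing at least one base with any positive on the
#' same chromosome (half-open overlap: `a.start < b.end && b.start <
#' a.end`); abutting intervals are kept. Survivors keep their input order;
#' the number removed is attached as attribute `n_removed` and reported.
#'
#' @param negatives,positives Peak tibbles.
#' @return The surviving negatives.
#' @export
remove_overlapping <- function(negatives, positives) {
  if (nrow(negatives) == 0L || nrow(positives) == 0L) {
    attr(negatives, "n_removed") <- 0L
    return(negatives)
  }
  gr <- function(p) GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(start = p$start + 1L, end = p$end)
  )
  # the two sets legitimately live on different chromosome sets; silence
  # the seqlevel-mismatch note findOverlaps emits for that case
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr(negatives), gr(positives))
  )
  drop <- unique(S4Vectors::queryHits(hits))
  out <- if (length(drop) > 0L) negatives[-drop, ] else negatives
  attr(out, "n_removed") <- length(drop)
  if (length(drop) > 0L) {
    inform(sprintf("%d negative peak(s) overlapped a positive and were removed",
                   length(drop)))
  }
  out
}

#' Sliding-window scan of one sequence
#'
#' Evaluates the scorer on every window of the given width (stride 1 by
#' default) and returns the highest-scoring window; ties go to the
#' smallest offset.
#'
#' @param scorer Function mapping a character vector of windows to numeric
#'   scores (e.g. [crnn_scorer()]).
#' @param seq A DNA string of length >= `window`.
#' @param window Window width in nucleotides.
#' @param stride Step between window starts.
#' @return One-row tibble: `best_offset` (0-based), `best_window`, `score`.
#' @export
scan_sequence <- function(scorer, seq, window, stride = 1L) {
  seq <- assert_dna(seq)
  L <- nchar(seq)
  if (L < window) {
    abort(sprintf("sequence length %d < window %d", L, window),
          class = "crnntfbs_input_error")
  }
  starts <- seq.int(1L, L - window + 1L, by = stride)
  wins <- substring(seq, starts, starts + window - 1L)
  scores <- scorer(wins)
  i <- which.max(scores)
  tibble(best_offset = starts[i] - 1L, best_window = wins[i],
         score = scores[i])
}

#' Sliding-window scan of many sequences
#'
#' Enumerates all windows of all sequences and evaluates the scorer in one
#' batched call (important for neural scorers), then keeps the best window
#' per sequence; ties go to the smallest offset.
#'
#' @param scorer Function: character vector of windows -> numeric scores.
#' @param seqs Sequence tibble (`id`, `seq`), all of length >= `window`;
#'   shorter records are dropped with a message.
#' @param window Window width (nt).
#' @param stride Step between window starts.
#' @return Scan tibble: `peak_id`, `best_offset`, `best_window`, `score`.
#' @export
scan_sequences <- function(scorer, seqs, window, stride = 1L) {
  short <- nchar(seqs$seq) < window
  if (any(short)) {
    inform(sprintf("%d sequence(s) shorter than the scan window were dropped",
                   sum(short)))
    seqs <- seqs[!short, ]
  }
  if (nrow(seqs) == 0L) {
    return(tibble(peak_id = character(), best_offset = integer(),
                  best_window = character(), score = double()))
  }
  win_tbl <- purrr::map2_dfr(seqs$id, seqs$seq, function(id, s) {
    starts <- seq.int(1L, nchar(s) - window + 1L, by = stride)
    tibble(peak_id = id, best_offset = starts - 1L,
           best_window = substring(s, starts, starts + window - 1L))
  })
  win_tbl$score <- scorer(win_tbl$best_window)
  win_tbl |>
    group_by(.data$peak_id) |>
    filter(row_number() == which.max(.data$score)) |>
    ungroup() |>
    # restore input sequence order
    arrange(match(.data$peak_id, seqs$id))
}

#' Attach within-set percentiles to scan results
#'
#' Percentile of each score relative to the full result set:
#' `100 * rank / N` with midranks for ties, so the maximum score maps
#' to 100 and equal scores share a percentile.
#'
#' @param results Scan tibble with a `score` column.
#' @return The tibble with a `percentile` column added.
#' @export
assign_percentiles <- function(results) {
  if (nrow(results) == 0L) {
    abort("no scan results", class = "crnntfbs_input_error")
  }
  mutate(results,
         percentile = 100 * rank(.data$score, ties.method = "average") /
           nrow(results))
}

#' Discover non-canonical binding sites
#'
#' Intersects neural and PWM scan results on the same peaks and returns
#' those classified as binding by the neural model (score strictly greater
#' than `rnn_min`) yet non-binding under the log-odds PWM (score strictly
#' below `pwm_max`) — the filter that surfaces sites a position-weight
#' matrix cannot represent. Each selected peak also reports whether its
#' best neural window contains the CNNG core motif on either strand.
#'
#' @param rnn_results Scan tibble of the neural scorer (`peak_id`,
#'   `best_offset`, `best_window`, `score`).
#' @param pwm_results Scan tibble of the PWM scorer over the same peaks.
#' @param rnn_min Neural score cut-off (default 0.99, strict).
#' @param pwm_max PWM score cut-off in bits (default 0, strict).
#' @return Tibble sorted by decreasing neural score: `peak_id`,
#'   `rnn_offset`, `rnn_window`, `rnn_score`, `pwm_offset`, `pwm_window`,
#'   `pwm_score`, `cnng_present`.
#' @export
discover_noncanonical <- function(rnn_results, pwm_results,
                                  rnn_min = 0.99, pwm_max = 0) {
  if (!setequal(rnn_results$peak_id, pwm_results$peak_id)) {
    abort("neural and PWM results cover different peak ids",
          class = "crnntfbs_alignment_error")
  }
  merged <- left_join(
    rename(rnn_results, rnn_offset = "best_offset",
           rnn_window = "best_window", rnn_score = "score"),
    rename(select(pwm_results, "peak_id", "best_offset", "best_window",
                  "score"),
           pwm_offset = "best_offset", pwm_window = "best_window",
           pwm_score = "score"),
    by = "peak_id"
  )
  out <- merged |>
    filter(.data$rnn_score > rnn_min, .data$pwm_score < pwm_max) |>
    arrange(desc(.data$rnn_score))
  out$cnng_present <- vapply(out$rnn_window, iupac_contains, logical(1),
                             pattern = "CNNG", both_strands = TRUE,
                             USE.NAMES = FALSE)
  out
}

#' In-silico saturation mutagenesis
#'
#' Scores every possible single-nucleotide substitution of a sequence
#' (3 per position, `3 * L` in total) with the given scorer and reports
#' each variant's score and its delta to the parent score. Positions are
#' reported 1-based, matching how variant positions are written in
#' wet-lab tables.
#'
#' @param seq Parent DNA string (N-free, scorer-compatible length).
#' @param scorer Function: character vector of sequences -> numeric scores.
#' @param parent_id Id recorded in the output (default `"parent"`).
#' @return Tibble with one row per variant: `parent_id`, `position`
#'   (1-based), `ref_base`, `alt_base`, `variant_seq`, `score`, `delta`
#'   (variant minus parent score); attribute `parent_score`.
#' @export
#' @examples
#' counts_a <- function(x) lengths(regmatches(x, gregexpr("A", x))) / nchar(x)
#' saturation_mutagenesis("ACGT", counts_a)
saturation_mutagenesis <- function(seq, scorer, parent_id = "parent") {
  seq <- assert_dna(seq, allow_n = FALSE)
  L <- nchar(seq)
  if (L < 1L) abort("empty sequence", class = "crnntfbs_input_error")
  chars <- seq_chars(seq)
  grid <- tidyr::expand_grid(position = seq_len(L), alt_base = DNA_BASES) |>
    mutate(ref_base = chars[.data$position]) |>
    filter(.data$alt_base != .data$ref_base)
  grid$variant_seq <- vapply(seq_len(nrow(grid)), function(i) {
    v <- chars
    v[grid$position[i]] <- grid$alt_base[i]
    paste(v, collapse = "")
  }, character(1))
  scores <- scorer(c(seq, grid$variant_seq))
  parent_score <- scores[1L]
  out <- tibble(
    parent_id = parent_id,
    position = grid$position, ref_base = grid$ref_base,
    alt_base = grid$alt_base, variant_seq = grid$variant_seq,
    score = scores[-1L], delta = scores[-1L] - parent_score
  )
  attr(out, "parent_score") <- parent_score
  out
}

#' Select the variants with the largest predicted effect
#'
#' @param effects Variant tibble from [saturation_mutagenesis()].
#' @param k Number of variants to keep.
#' @return The `k` variants with largest `|delta|`; ties broken by
#'   position, then alphabetical alternative base.
#' @export
select_top_variants <- function(effects, k) {
  if (k > nrow(effects)) {
    abort(sprintf("k = %d exceeds the %d available variants", k,
                  nrow(effects)), class = "crnntfbs_input_error")
  }
  effects |>
    arrange(desc(abs(.data$delta)), .data$position, .data$alt_base) |>
    slice(seq_len(k))
}
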