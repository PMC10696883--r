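peak_row <- function(id, chrom, start, end, qv = 10, score = 1) {
  tibble::tibble(peak_id = id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end),
                 summit_offset = as.integer((end - start) %/% 2),
                 chip_score = score, qvalue_mlog10 = qv)
}

test_that("q-value filtering converts linear thresholds to -log10", {
  peaks <- dplyr::bind_rows(peak_row("a", "chr1", 0, 100, qv = 4),
                            peak_row("b", "chr1", 200, 300, qv = 6),
                            peak_row("c", "chr1", 400, 500, qv = 9))
  kept <- filter_peaks(peaks, 1e-5)        # q < 1e-5  <=>  -log10(q) > 5
  expect_equal(kept$peak_id, c("b", "c"))
  expect_equal(nrow(filter_peaks(peaks, 1)), 3L)
  expect_equal(nrow(filter_peaks(peaks[0, ], 1e-5)), 0L)
  expect_error(filter_peaks(peaks, 0), class = "crnntfbs_input_error")
})

test_that("overlap removal uses half-open intervals per chromosome", {
  pos <- peak_row("p", "chr1", 150, 250)
  negs <- dplyr::bind_rows(peak_row("n1", "chr1", 100, 200),   # overlaps
                           peak_row("n2", "chr1", 250, 350),   # abuts
                           peak_row("n3", "chr2", 150, 250))   # other chrom
  out <- suppressMessages(remove_overlapping(negs, pos))
  expect_equal(out$peak_id, c("n2", "n3"))
  expect_equal(attr(out, "n_removed"), 1L)
  all_kept <- remove_overlapping(negs, peak_row("p", "chr9", 0, 10))
  expect_equal(nrow(all_kept), 3L)
})

test_that("sliding-window scans return the arg-max window", {
  count_a <- function(w) vapply(strsplit(w, ""), function(x)
    sum(x == "A"), numeric(1))
  hit <- scan_sequence(count_a, "TTAAAT", window = 3L)
  expect_equal(hit$best_offset, 2L)
  expect_equal(hit$best_window, "AAA")

  solo <- scan_sequence(count_a, "ACGT", window = 4L)
  expect_equal(solo$best_offset, 0L)
  expect_error(scan_sequence(count_a, "ACG", window = 4L),
               class = "crnntfbs_input_error")

  # a 100-nt peak at window 20, stride 1 evaluates exactly 81 windows
  n_seen <- NULL
  counting_scorer <- function(w) { n_seen <<- length(w); count_a(w) }
  scan_sequence(counting_scorer, paste(rep("A", 100), collapse = ""), 20L)
  expect_equal(n_seen, 81L)
})

test_that("batched scans equal brute-force maxima over random scorers", {
  withr::local_seed(81)
  # deterministic but structureless scorer
  hash_score <- function(w) {
    vapply(w, function(x) {
      sum(utf8ToInt(x) * seq_len(nchar(x))) %% 97
    }, numeric(1), USE.NAMES = FALSE)
  }
  seqs <- tibble::tibble(id = sprintf("s%d", 1:10), seq = random_dna(10, 30))
  res <- scan_sequences(hash_score, seqs, window = 8L)
  for (i in 1:10) {
    wins <- substring(seqs$seq[i], 1:23, 8:30)
    sc <- hash_score(wins)
    expect_equal(res$score[i], max(sc))
    expect_equal(res$best_offset[i], which.max(sc) - 1L)  # first max wins
  }
  # sequences shorter than the window are dropped with a message
  mixed <- dplyr::bind_rows(seqs, tibble::tibble(id = "tiny", seq = "ACGT"))
  expect_message(out <- scan_sequences(hash_score, mixed, window = 8L),
                 "dropped")
  expect_false("tiny" %in% out$peak_id)
})

test_that("percentiles follow the midrank formula", {
  r4 <- assign_percentiles(tibble::tibble(peak_id = letters[1:4],
                                          score = c(0.1, 0.4, 0.2, 0.3)))
  expect_equal(sort(r4$percentile), c(25, 50, 75, 100))
  expect_equal(r4$percentile[r4$score == 0.4], 100)

  ties <- assign_percentiles(tibble::tibble(peak_id = letters[1:3],
                                            score = c(1, 1, 1)))
  expect_equal(unique(ties$percentile), 100 * 2 / 3)
  one <- assign_percentiles(tibble::tibble(peak_id = "x", score = 5))
  expect_equal(one$percentile, 100)
})

test_that("the non-canonical filter applies both strict thresholds", {
  rnn <- tibble::tibble(peak_id = c("p1", "p2", "p3", "p4"),
                        best_offset = 0L,
                        best_window = c("AGGTTTTTCCACTTTGGGGC",
                                        "GGGCAAAACCGGTTTTGCGG",
                                        "AGGTTTTTCCACTTTGGGGC",
                                        "AGGTTTTTCCACTTTGGGGC"),
                        score = c(0.995, 0.995, 0.9, 0.99))
  pwm <- tibble::tibble(peak_id = c("p1", "p2", "p3", "p4"),
                        best_offset = 0L, best_window = "AAACCGGTTT",
                        score = c(-2.1, 3.0, -5, -1))
  found <- discover_noncanonical(rnn, pwm)
  expect_equal(found$peak_id, "p1")            # p2 canonical, p3 weak,
  expect_false(found$cnng_present)             # p4 at threshold (strict)
  expect_true(discover_noncanonical(rnn, pwm, rnn_min = 0.99)$peak_id[1] == "p1")
  expect_error(discover_noncanonical(rnn[1:3, ], pwm),
               class = "crnntfbs_alignment_error")
})

test_that("tightening discovery thresholds never adds peaks", {
  withr::local_seed(82)
  n <- 40
  rnn <- tibble::tibble(peak_id = sprintf("p%d", 1:n), best_offset = 0L,
                        best_window = random_dna(n, 20), score = runif(n))
  pwm <- tibble::tibble(peak_id = rnn$peak_id, best_offset = 0L,
                        best_window = random_dna(n, 10),
                        score = runif(n, -5, 5))
  base <- discover_noncanonical(rnn, pwm, rnn_min = 0.3, pwm_max = 2)
  tighter <- discover_noncanonical(rnn, pwm, rnn_min = 0.6, pwm_max = 0)
  expect_true(all(tighter$peak_id %in% base$peak_id))
})

test_that("saturation mutagenesis enumerates all 3L distinct variants", {
  gc_frac <- function(w) vapply(strsplit(w, ""), function(x)
    mean(x %in% c("G", "C")), numeric(1))
  eff <- saturation_mutagenesis("GGGCAAAACCGGTTTTGCGG", gc_frac,
                                parent_id = "Pos_Ctrl")
  expect_equal(nrow(eff), 60L)
  expect_equal(length(unique(eff$variant_seq)), 60L)
  expect_equal(unname(table(eff$position)), rep(3L, 20L), ignore_attr = TRUE)

  # position-12 single-base exchanges reproduce the printed variant panel
  p12 <- eff[eff$position == 12L, ]
  expect_equal(p12$ref_base, rep("G", 3))
  expect_equal(sort(p12$variant_seq),
               sort(c("GGGCAAAACCGATTTTGCGG",     # G>A
                      "GGGCAAAACCGCTTTTGCGG",     # G>C
                      "GGGCAAAACCGTTTTTGCGG")))   # G>T
  novel <- saturation_mutagenesis("AGGTTTTTCCACTTTGGGGC", gc_frac,
                                  parent_id = "Novel")
  expect_equal(novel$variant_seq[novel$position == 12L &
                                   novel$alt_base == "G"],
               "AGGTTTTTCCAGTTTGGGGC")
})

test_that("variants round-trip: applying (position, alt) rebuilds the seq", {
  withr::local_seed(83)
  gc_frac <- function(w) vapply(strsplit(w, ""), function(x)
    mean(x %in% c("G", "C")), numeric(1))
  parent <- random_dna(1, 20)
  eff <- saturation_mutagenesis(parent, gc_frac)
  for (i in sample(nrow(eff), 10)) {
    rebuilt <- parent
    substr(rebuilt, eff$position[i], eff$position[i]) <- eff$alt_base[i]
    expect_identical(rebuilt, eff$variant_seq[i])
    expect_equal(sum(strsplit(parent, "")[[1]] !=
                       strsplit(eff$variant_seq[i], "")[[1]]), 1L)
  }
})

test_that("top-variant selection matches an exhaustive sorting oracle", {
  withr::local_seed(84)
  eff <- tibble::tibble(
    parent_id = "x", position = sample(1:20, 60, replace = TRUE),
    ref_base = "A", alt_base = sample(c("C", "G", "T"), 60, replace = TRUE),
    variant_seq = random_dna(60, 20),
    score = runif(60), delta = runif(60, -1, 1)
  )
  top <- select_top_variants(eff, k = 5)
  oracle <- eff[order(-abs(eff$delta), eff$position, eff$alt_base), ][1:5, ]
  expect_equal(top, oracle)
  expect_equal(nrow(select_top_variants(eff, k = 60)), 60L)
  expect_error(select_top_variants(eff, k = 61),
               class = "crnntfbs_input_error")

  single <- select_top_variants(
    tibble::tibble(parent_id = "y", position = 1:3, ref_base = "A",
                   alt_base = c("C", "G", "T"), variant_seq = "A",
                   score = 0.5, delta = c(-0.8, -0.1, 0.05)), k = 1)
  expect_equal(single$delta, -0.8)
})
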