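#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by ungroup summarise
#'   bind_rows left_join row_number n desc slice pull rename across
#' @importFrom stats rnorm runif rbinom setNames cor quantile sd predict
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# split a DNA string into a character vector of single bases
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

assert_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq)) {
    abort(sprintf("%s must be a single character string", what))
  }
  allowed <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", allowed), "", toupper(seq))
  if (nzchar(bad)) {
    abort(sprintf(
      "invalid character(s) '%s' in %s: alphabet is {%s}",
      paste(unique(seq_chars(bad)), collapse = ","), what,
      paste(seq_chars(allowed), collapse = ",")
    ), class = "crnntfbs_alphabet_error")
  }
  toupper(seq)
}

assert_dna_vec <- function(seqs, allow_n = TRUE, what = "sequences") {
  seqs <- toupper(seqs)
  allowed <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad)) {
    abort(sprintf(
      "%d %s contain characters outside {%s} (first offender: '%s')",
      sum(bad), what, paste(seq_chars(allowed), collapse = ","),
      seqs[which(bad)[1L]]
    ), class = "crnntfbs_alphabet_error")
  }
  seqs
}

# 32-bit FNV-1a string hash reduced mod 2^31 - 1; used to derive per-record
# RNG streams that are stable under reordering of a collection.
fnv1a31 <- function(x) {
  vapply(x, function(s) {
    bytes <- utf8ToInt(s)
    h <- 2166136261
    for (b in bytes) {
      h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
      h <- (h * 16777619) %% 2^31
    }
    as.integer(h %% (2^31 - 1))
  }, integer(1), USE.NAMES = FALSE)
}

# derive a child seed below 2^31 from a parent seed and a string label
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) + fnv1a31(label)) %% (2^31 - 1)) + 1L
}
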