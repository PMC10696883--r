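#' Read a FASTA file into a tibble of sequence records
#'
#' Sequences are uppercased and validated against the DNA alphabet
#' `{A,C,G,T,N}`. Record order in the file is preserved.
#'
#' @param path Path to a FASTA file. An empty file yields an empty tibble.
#' @return A tibble with columns `id` (character), `seq` (character, upper
#'   case) and `length` (integer, nucleotides).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">Pos_Ctrl", "GGGCAAAACCGGTTTTGCGG"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  non_blank <- which(nzchar(trimws(lines)))
  if (length(non_blank) == 0L) {
    return(tibble(id = character(), seq = character(), length = integer()))
  }
  if (!startsWith(trimws(lines[non_blank[1L]]), ">")) {
    abort(sprintf(
      "malformed FASTA: line %d contains sequence before any '>' header",
      non_blank[1L]
    ), class = "crnntfbs_parse_error")
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- assert_dna_vec(unname(as.character(ss)), what = "FASTA sequences")
  if (anyDuplicated(ids)) {
    warn(sprintf("duplicated FASTA ids (first: '%s')", ids[anyDuplicated(ids)]))
  }
  tibble(id = unname(ids), seq = unname(seqs), length = nchar(seqs))
}

#' Write sequence records to a FASTA file
#'
#' @param records A tibble with columns `id` and `seq` (as from
#'   [read_fasta()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  ss <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Reverse complement of DNA sequences
#'
#' Watson-Crick complement, reversed. `N` maps to `N`. Vectorised; an
#' involution (applying it twice returns the input).
#'
#' @param seq Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @export
#' @examples
#' reverse_complement("AACCGGTT") # palindromic consensus
reverse_complement <- function(seq) {
  seq <- assert_dna_vec(seq)
  empty <- !nzchar(seq)
  out <- seq
  if (any(!empty)) {
    out[!empty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[!empty]))
    )
  }
  out
}

#' One-hot encode a DNA sequence
#'
#' Produces an `L x 4` numeric matrix with columns in `A,C,G,T` order. Rows
#' for `N` are all-zero, so the model can learn to ignore unknown bases; row
#' sums are therefore exactly 1 for called bases and 0 for `N`.
#'
#' @param seq A single DNA string over `{A,C,G,T,N}`.
#' @return Numeric matrix of dimension `nchar(seq) x 4`, column names
#'   `A,C,G,T`, with attribute `source_length`.
#' @seealso [one_hot_decode()]
#' @export
one_hot_encode <- function(seq) {
  seq <- assert_dna(seq)
  chars <- if (nzchar(seq)) seq_chars(seq) else character()
  m <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  idx <- match(chars, DNA_BASES)            # NA for N
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  attr(m, "source_length") <- length(chars)
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' All-zero rows decode to `N`.
#'
#' @param mat A matrix produced by [one_hot_encode()].
#' @return A DNA string.
#' @export
one_hot_decode <- function(mat) {
  if (nrow(mat) == 0L) return("")
  base <- apply(mat, 1L, function(r) {
    if (sum(r) == 0) "N" else DNA_BASES[which.max(r)]
  })
  paste(base, collapse = "")
}

#' Test whether a sequence contains an IUPAC pattern
#'
#' Position-wise matching of an IUPAC degenerate pattern (e.g. the CNNG core
#' motif) against every window of `seq`, optionally also against its reverse
#' complement.
#'
#' @param seq A DNA string over `{A,C,G,T,N}`.
#' @param pattern An IUPAC string (codes `A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`).
#' @param both_strands Also check the reverse complement of `seq`.
#' @return `TRUE` if any window matches.
#' @export
#' @examples
#' iupac_contains("GGGCAAAACCGGTTTTGCGG", "CNNG", both_strands = TRUE)
iupac_contains <- function(seq, pattern, both_strands = FALSE) {
  seq <- assert_dna(seq)
  pattern <- toupper(pattern)
  bad <- setdiff(unique(seq_chars(pattern)), names(IUPAC_CODES))
  if (length(bad) > 0L) {
    abort(sprintf("invalid IUPAC code(s) in pattern: %s",
                  paste(bad, collapse = ",")),
          class = "crnntfbs_pattern_error")
  }
  if (nchar(pattern) == 0L || nchar(seq) < nchar(pattern)) return(FALSE)
  hit <- function(s) {
    Biostrings::countPattern(pattern, Biostrings::DNAString(s),
                             fixed = FALSE) > 0L
  }
  hit(seq) || (both_strands && hit(reverse_complement(seq)))
}

#' Read a JASPAR-format position frequency matrix
#'
#' Parses the JASPAR text format (a `>ID NAME` header followed by four
#' bracketed count rows labelled `A,C,G,T` in any order) into a PFM whose
#' rows are always in `A,C,G,T` order.
#'
#' @param path Path to a JASPAR `.jaspar`/`.pfm` text file.
#' @return An object of class `pfm`: a list with `counts` (4 x w numeric
#'   matrix, rownames `A,C,G,T`), `width` and `motif_id`.
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[1L], ">")) {
    abort("malformed JASPAR file: missing '>' header",
          class = "crnntfbs_parse_error")
  }
  motif_id <- strsplit(sub("^>", "", lines[1L]), "\\s+")[[1L]][1L]
  body <- lines[-1L]
  rows <- list()
  for (ln in body) {
    base <- toupper(substr(ln, 1L, 1L))
    if (!base %in% DNA_BASES) {
      abort(sprintf("malformed JASPAR count row: '%s'", ln),
            class = "crnntfbs_parse_error")
    }
    num_part <- sub("^.", "", ln)
    nums <- regmatches(num_part, gregexpr("-?[0-9.]+", num_part))[[1L]]
    rows[[base]] <- as.numeric(nums)
  }
  missing <- setdiff(DNA_BASES, names(rows))
  if (length(missing) > 0L) {
    abort(sprintf("JASPAR file missing base row(s): %s",
                  paste(missing, collapse = ",")),
          class = "crnntfbs_parse_error")
  }
  widths <- lengths(rows[DNA_BASES])
  if (length(unique(widths)) != 1L) {
    abort("ragged JASPAR count rows: all four bases must have equal width",
          class = "crnntfbs_parse_error")
  }
  counts <- do.call(rbind, rows[DNA_BASES])
  rownames(counts) <- DNA_BASES
  new_pfm(counts, motif_id)
}

new_pfm <- function(counts, motif_id = "motif") {
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (any(counts < 0)) abort("PFM counts must be non-negative")
  if (any(colSums(counts) <= 0)) {
    abort("PFM has a column with no positive entry")
  }
  rownames(counts) <- DNA_BASES
  structure(list(counts = counts, width = ncol(counts), motif_id = motif_id),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s, width %d\n", x$motif_id, x$width))
  print(x$counts)
  invisible(x)
}

#' Read an ENCODE narrowPeak (or plain BED) file into a peak tibble
#'
#' narrowPeak is BED6+4: column 7 is the enrichment `signalValue` (used here
#' as the ChIP-Seq score), column 9 is the -log10 q-value, and column 10 the
#' summit offset from `start`. Peaks with summit `-1` fall back to the
#' interval midpoint with a warning. Plain BED (>= 4 columns) is accepted;
#' the summit then defaults to the midpoint and score/q-value are `NA`.
#'
#' @param path Path to a tab-separated narrowPeak/BED file.
#' @return A tibble with columns `peak_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `summit_offset`, `chip_score` and `qvalue_mlog10`
#'   (-log10 of the q-value).
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  empty <- tibble(
    peak_id = character(), chrom = character(),
    start = integer(), end = integer(), summit_offset = integer(),
    chip_score = double(), qvalue_mlog10 = double()
  )
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return(empty)
  df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                        progress = FALSE, comment = "#")
  if (nrow(df) == 0L) return(empty)
  nc <- ncol(df)
  if (nc < 4L) abort("BED file needs at least 4 columns",
                     class = "crnntfbs_parse_error")
  start <- suppressWarnings(as.numeric(df[[2L]]))
  end <- suppressWarnings(as.numeric(df[[3L]]))
  if (anyNA(start) || anyNA(end) ||
      any(start != floor(start)) || any(end != floor(end))) {
    abort("non-integer coordinates in BED/narrowPeak file",
          class = "crnntfbs_parse_error")
  }
  if (any(start >= end)) {
    abort(sprintf("invalid interval (start >= end) at line %d",
                  which(start >= end)[1L]),
          class = "crnntfbs_validation_error")
  }
  mid <- as.integer(floor((end - start) / 2))
  if (nc >= 10L) {
    summit <- suppressWarnings(as.integer(df[[10L]]))
    no_summit <- is.na(summit) | summit < 0L
    if (any(no_summit)) {
      warn(sprintf(
        "%d peak(s) without a called summit; using interval midpoint",
        sum(no_summit)
      ))
      summit[no_summit] <- mid[no_summit]
    }
    chip_score <- suppressWarnings(as.numeric(df[[7L]]))
    qv <- suppressWarnings(as.numeric(df[[9L]]))
    if (any(!is.na(qv) & qv < 0 & qv != -1)) {
      abort("negative -log10(q) in narrowPeak column 9",
            class = "crnntfbs_validation_error")
    }
    qv[qv == -1] <- NA_real_
  } else {
    summit <- mid
    chip_score <- NA_real_
    qv <- NA_real_
  }
  bad_summit <- summit >= (end - start)
  if (any(bad_summit)) {
    abort("summit offset outside peak interval",
          class = "crnntfbs_validation_error")
  }
  tibble(
    peak_id = as.character(df[[4L]]),
    chrom = as.character(df[[1L]]),
    start = as.integer(start), end = as.integer(end),
    summit_offset = as.integer(summit),
    chip_score = chip_score, qvalue_mlog10 = qv
  )
}

#' Extract fixed-length summit-centred windows for peaks
#'
#' Returns the `2 * flank` nucleotide window centred on each peak summit
#' (100 nt at the default flank of 50). Two sequence sources are supported:
#' a genome-style source whose ids are chromosome names (the summit is
#' resolved at `start + summit_offset` in absolute coordinates) and a
#' peak-sequence source whose ids are peak ids (the summit is
#' `summit_offset` within the attached sequence). Windows overrunning their
#' contig are dropped with a warning rather than clipped, so every returned
#' sequence has the same length.
#'
#' @param peaks Peak tibble from [read_narrowpeak()].
#' @param source Sequence tibble from [read_fasta()] (columns `id`, `seq`).
#' @param flank Half-window in nucleotides (default 50).
#' @return A sequence tibble (`id`, `seq`, `length`) with `id` equal to
#'   `peak_id`; dropped peaks are absent.
#' @export
extract_summit_window <- function(peaks, source, flank = 50L) {
  stopifnot(flank >= 1L)
  lookup <- setNames(source$seq, source$id)
  by_peak_id <- all(peaks$peak_id %in% source$id)
  by_chrom <- all(peaks$chrom %in% source$id)
  if (!by_peak_id && !by_chrom) {
    missing <- if (sum(peaks$chrom %in% source$id) >=
                   sum(peaks$peak_id %in% source$id)) {
      setdiff(peaks$chrom, source$id)
    } else setdiff(peaks$peak_id, source$id)
    abort(sprintf("sequence source lacks entries: %s",
                  paste(head(missing, 3L), collapse = ",")),
          class = "crnntfbs_lookup_error")
  }
  ids <- character(); seqs <- character(); dropped <- 0L
  for (i in seq_len(nrow(peaks))) {
    if (by_peak_id && !by_chrom) {
      contig <- lookup[[peaks$peak_id[i]]]
      summit <- peaks$summit_offset[i]
    } else {
      contig <- lookup[[peaks$chrom[i]]]
      summit <- peaks$start[i] + peaks$summit_offset[i]
    }
    s0 <- summit - flank                     # 0-based half-open [s0, s0+2*flank)
    if (s0 < 0L || s0 + 2L * flank > nchar(contig)) {
      dropped <- dropped + 1L
      next
    }
    ids <- c(ids, peaks$peak_id[i])
    seqs <- c(seqs, substr(contig, s0 + 1L, s0 + 2L * flank))
  }
  if (dropped > 0L) {
    warn(sprintf("%d peak window(s) overran their contig and were dropped",
                 dropped))
  }
  tibble(id = ids, seq = toupper(seqs), length = nchar(seqs))
}
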