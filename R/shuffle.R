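#' Dinucleotide-preserving shuffle of a DNA sequence
#'
#' Rearranges a sequence while preserving its exact multiset of overlapping
#' dinucleotides (and therefore its mononucleotide counts and GC content),
#' using the Altschul-Erickson Eulerian-walk construction: the shuffled
#' sequence is a uniformly drawn Eulerian path through the dinucleotide
#' transition multigraph, so its first and last bases always equal the
#' input's. This is the construction behind MEME's `fasta-shuffle-letters`
#' at k-mer order 2 and is the standard way to build non-binding control
#' sequences that a classifier cannot separate by composition alone.
#'
#' @param seq A DNA string over `{A,C,G,T}` of length >= 3 (records
#'   containing `N` must be filtered upstream).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A shuffled DNA string with identical dinucleotide counts.
#' @export
#' @examples
#' dinucleotide_shuffle("GGGCAAAACCGGTTTTGCGG", seed = 1)
dinucleotide_shuffle <- function(seq, seed = NULL) {
  seq <- assert_dna(seq, allow_n = FALSE)
  if (nchar(seq) < 3L) {
    abort("sequence must be at least 3 nt for a dinucleotide shuffle",
          class = "crnntfbs_input_error")
  }
  run <- function() dinuc_shuffle_impl(seq_chars(seq))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

dinuc_shuffle_impl <- function(chars) {
  L <- length(chars)
  first <- chars[1L]
  last <- chars[L]
  # outgoing edge targets per vertex
  edges <- split(chars[-1L], chars[-L])
  verts <- names(edges)
  if (length(verts) == 1L) return(paste(chars, collapse = ""))

  # choose a random "last edge" out of every vertex except the terminal one,
  # retrying until the chosen edges form paths that all reach the terminal
  # vertex (Altschul-Erickson connectivity condition)
  inner <- setdiff(verts, last)
  repeat {
    last_edge <- vapply(inner, function(v) {
      tg <- edges[[v]]
      tg[sample.int(length(tg), 1L)]
    }, character(1))
    ok <- TRUE
    for (v in inner) {
      cur <- v
      steps <- 0L
      while (cur != last) {
        if (!cur %in% inner || steps > length(verts)) { ok <- FALSE; break }
        cur <- last_edge[[cur]]
        steps <- steps + 1L
      }
      if (!ok) break
    }
    if (ok) break
  }

  # permute the remaining edges at each vertex; append the reserved last edge
  ordered <- lapply(verts, function(v) {
    tg <- edges[[v]]
    if (v %in% inner) {
      drop <- match(last_edge[[v]], tg)
      tg <- tg[-drop]
      c(if (length(tg) > 1L) tg[sample.int(length(tg))] else tg,
        last_edge[[v]])
    } else {
      if (length(tg) > 1L) tg[sample.int(length(tg))] else tg
    }
  })
  names(ordered) <- verts

  # walk the Eulerian path from the first base
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(L)
  out[1L] <- first
  cur <- first
  for (i in 2L:L) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Count overlapping dinucleotides of a sequence
#'
#' @param seq A DNA string over `{A,C,G,T}`.
#' @return A named integer vector over the 16 dinucleotides.
#' @export
dinucleotide_counts <- function(seq) {
  seq <- assert_dna(seq, allow_n = FALSE)
  lev <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  chars <- seq_chars(seq)
  if (length(chars) < 2L) return(setNames(rep(0L, 16L), sort(lev)))
  di <- paste0(chars[-length(chars)], chars[-1L])
  table(factor(di, levels = sort(lev)))
}

#' Build a balanced binding / non-binding dataset
#'
#' Creates one dinucleotide-preserving shuffle per positive read, labelled
#' `non_binding`, alongside the positives labelled `binding`. Each record's
#' shuffle uses an RNG stream derived by hashing its id together with the
#' top-level seed, so results do not depend on collection order.
#'
#' @param positives Sequence tibble (`id`, `seq`), all records the same
#'   length and N-free.
#' @param seed Integer seed for the shuffles.
#' @return A labelled dataset tibble with columns `id`, `seq`,
#'   `label` (factor `binding`/`non_binding`) and `source_id` (the positive
#'   each negative was derived from; equal to `id` for positives).
#' @export
build_balanced_dataset <- function(positives, seed = 1L) {
  if (nrow(positives) == 0L) {
    abort("no positive sequences supplied", class = "crnntfbs_input_error")
  }
  seqs <- assert_dna_vec(positives$seq, allow_n = FALSE,
                         what = "positive sequences")
  if (length(unique(nchar(seqs))) != 1L) {
    abort("all positive sequences must have the same length",
          class = "crnntfbs_input_error")
  }
  neg_seq <- vapply(seq_along(seqs), function(i) {
    dinucleotide_shuffle(seqs[i], seed = derive_seed(seed, positives$id[i]))
  }, character(1))
  bind_rows(
    tibble(id = positives$id, seq = seqs,
           label = factor("binding", levels = c("binding", "non_binding")),
           source_id = positives$id),
    tibble(id = paste0(positives$id, "_shuf"), seq = neg_seq,
           label = factor("non_binding", levels = c("binding", "non_binding")),
           source_id = positives$id)
  )
}

#' Split a labelled dataset into train / validation / test subsets
#'
#' Random, seeded partition in the given ratios (70/15/15 by default).
#' Subset sizes are `floor(N * ratio)` for validation and test with the
#' remainder assigned to training. When the dataset was built by
#' [build_balanced_dataset()], a positive and its derived shuffle are always
#' co-assigned to the same subset, preventing composition leakage between
#' training and evaluation; each subset then stays exactly balanced.
#' Otherwise the split is stratified by label.
#'
#' @param dataset Labelled dataset tibble (`id`, `seq`, `label`,
#'   optionally `source_id`).
#' @param ratios Numeric length-3 vector summing to 1.
#' @param seed Integer seed.
#' @return A named list of tibbles: `train`, `validation`, `test`.
#' @export
split_dataset <- function(dataset, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    abort("ratios must be three positive numbers summing to 1",
          class = "crnntfbs_input_error")
  }
  paired <- "source_id" %in% names(dataset) &&
    !anyNA(dataset$source_id) &&
    all(table(dataset$source_id) == 2L)
  units <- if (paired) unique(dataset$source_id) else seq_len(nrow(dataset))

  assign_units <- function(u) {
    P <- length(u)
    n_val <- floor(P * ratios[2L])
    n_test <- floor(P * ratios[3L])
    n_train <- P - n_val - n_test
    if (min(n_train, n_val, n_test) < 1L) {
      abort("dataset too small: a split subset would be empty",
            class = "crnntfbs_input_error")
    }
    perm <- u[sample.int(P)]
    list(train = perm[seq_len(n_train)],
         validation = perm[n_train + seq_len(n_val)],
         test = perm[n_train + n_val + seq_len(n_test)])
  }

  withr::with_seed(seed, {
    if (paired) {
      parts <- assign_units(units)
      lapply(parts, function(u) dataset[dataset$source_id %in% u, ])
    } else {
      by_label <- split(seq_len(nrow(dataset)), dataset$label)
      parts <- lapply(by_label, assign_units)
      out <- lapply(c("train", "validation", "test"), function(nm) {
        idx <- sort(unlist(lapply(parts, `[[`, nm), use.names = FALSE))
        dataset[idx, ]
      })
      setNames(out, c("train", "validation", "test"))
    }
  })
}
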