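#' Configuration of the synthetic-data generator
#'
#' Describes the statistical structure of every synthetic input the
#' pipeline consumes: fixed-length selection reads carrying a planted
#' motif versus i.i.d. background; 100-nt peak windows with a
#' summit-proximal site whose strength decays with peak rank (so the
#' enrichment score and binding signal co-vary, as in real ChIP-Seq); a
#' second non-canonical motif that is guaranteed CNNG-free on both strands
#' and scores below zero under a sharp canonical log-odds matrix; and
#' dissociation constants that decrease monotonically with site strength,
#' censored at a detection threshold.
#'
#' @param n_reads Number of reads to simulate.
#' @param read_length Read length (nt).
#' @param planted_fraction Fraction of reads receiving a motif instance.
#' @param canonical_consensus Canonical motif consensus.
#' @param motif_softness Per-position mismatch probability of planted sites.
#' @param noncanonical_consensus Non-canonical motif consensus; must
#'   contain no CNNG on either strand.
#' @param noncanonical_read_fraction Fraction of planted reads whose site
#'   is the non-canonical motif (the selection pool contains both kinds of
#'   binder, which is what lets a sequence model learn sites a PWM cannot).
#' @param gc_content Background GC fraction (`P(G) = P(C) = gc/2`).
#' @param n_peaks Number of positive peaks.
#' @param peak_length Peak window length (nt).
#' @param noncanonical_peak_fraction Fraction of peaks carrying the
#'   non-canonical site (planted at full strength) instead of the
#'   canonical one.
#' @param signal_decay Exponential rate linking peak rank to site
#'   strength; 0 makes all peaks equally strong.
#' @param peak_softness_max Per-position mismatch probability reached by
#'   the weakest canonical peak.
#' @param chip_noise_sd Log-normal sd of the ChIP enrichment score noise.
#' @param kd_min Dissociation constant of a full-strength site (uM).
#' @param kd_slope Exponential rate of Kd increase as strength drops.
#' @param kd_noise_sd Log-normal sd of the simulated Kd noise.
#' @param detection_threshold Kd above which a measurement is censored and
#'   reported as NBD (uM).
#' @param seed Master seed; every generator derives its own stream from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_reads = 10000L, read_length = 20L,
                         planted_fraction = 1,
                         canonical_consensus = "AAACCGGTTT",
                         motif_softness = 0.05,
                         noncanonical_consensus = "TTTTCCACTTTG",
                         noncanonical_read_fraction = 0.15,
                         gc_content = 0.5,
                         n_peaks = 500L, peak_length = 100L,
                         noncanonical_peak_fraction = 0.1,
                         signal_decay = 1, peak_softness_max = 0.4,
                         chip_noise_sd = 0.25,
                         kd_min = 0.1, kd_slope = 7.5, kd_noise_sd = 0.2,
                         detection_threshold = 9, seed = 1L) {
  cfg <- list(
    n_reads = as.integer(n_reads), read_length = as.integer(read_length),
    planted_fraction = planted_fraction,
    canonical_consensus = assert_dna(canonical_consensus, allow_n = FALSE),
    motif_softness = motif_softness,
    noncanonical_consensus = assert_dna(noncanonical_consensus,
                                        allow_n = FALSE),
    noncanonical_read_fraction = noncanonical_read_fraction,
    gc_content = gc_content,
    n_peaks = as.integer(n_peaks), peak_length = as.integer(peak_length),
    noncanonical_peak_fraction = noncanonical_peak_fraction,
    signal_decay = signal_decay, peak_softness_max = peak_softness_max,
    chip_noise_sd = chip_noise_sd,
    kd_min = kd_min, kd_slope = kd_slope, kd_noise_sd = kd_noise_sd,
    detection_threshold = detection_threshold, seed = as.integer(seed)
  )
  frac_fields <- c("planted_fraction", "noncanonical_read_fraction",
                   "gc_content", "noncanonical_peak_fraction")
  for (f in frac_fields) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(sprintf("%s must be in [0,1]", f))
  }
  if (cfg$motif_softness < 0 || cfg$motif_softness >= 0.75) {
    abort("motif_softness must be in [0, 0.75)")
  }
  if (cfg$detection_threshold <= 0) abort("detection_threshold must be > 0")
  if (iupac_contains(cfg$noncanonical_consensus, "CNNG",
                     both_strands = TRUE)) {
    abort("noncanonical_consensus must be CNNG-free on both strands")
  }
  structure(cfg, class = "synth_config")
}

#' Build a position frequency matrix from a consensus and a softness
#'
#' Each column gives the consensus base a probability of `1 - softness`,
#' splitting the remaining softness equally among the other three bases;
#' counts are scaled to 100 per column. This is the fixture PWM standing in
#' for a near-consensus database motif.
#'
#' @param consensus DNA consensus string.
#' @param softness Per-position mismatch probability in `[0, 0.75)`.
#' @param motif_id Id recorded on the matrix.
#' @return A `pfm` object of width `nchar(consensus)`.
#' @export
#' @examples
#' pwm_from_consensus("AAACCGGTTT", 0.05)
pwm_from_consensus <- function(consensus, softness = 0.05,
                               motif_id = "synthetic_consensus") {
  consensus <- assert_dna(consensus, allow_n = FALSE)
  if (softness < 0 || softness >= 0.75) {
    abort("softness must be in [0, 0.75)")
  }
  w <- nchar(consensus)
  counts <- matrix(100 * softness / 3, nrow = 4L, ncol = w,
                   dimnames = list(DNA_BASES, NULL))
  idx <- match(seq_chars(consensus), DNA_BASES)
  counts[cbind(idx, seq_len(w))] <- 100 * (1 - softness)
  new_pfm(counts, motif_id)
}

# i.i.d. background sequences at the configured GC content
random_background <- function(n, len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE, prob = p),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

# sample one motif instance: each position mutates away from the consensus
# with probability `softness`, uniformly over the other three bases
sample_motif_instance <- function(consensus, softness) {
  chars <- seq_chars(consensus)
  mut <- runif(length(chars)) < softness
  if (any(mut)) {
    chars[mut] <- vapply(chars[mut], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

match_fraction <- function(instance, consensus) {
  mean(seq_chars(instance) == seq_chars(consensus))
}

#' Simulate selection reads with planted motifs
#'
#' Background bases are i.i.d. at the configured GC content. An exact
#' `round(n_reads * planted_fraction)` of the reads receive one motif
#' instance at a uniform random valid offset; within the planted reads an
#' exact `noncanonical_read_fraction` carry the non-canonical motif, the
#' rest the canonical one. Bit-reproducible from the config seed.
#'
#' @param cfg A [synth_config()].
#' @return List with `reads` (sequence tibble) and `truth` (tibble with
#'   `id`, `has_motif`, `motif_kind`, `motif_offset` (0-based),
#'   `true_strength` = fraction of instance positions matching the
#'   consensus).
#' @export
simulate_reads <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_reads
  if (n < 1L) abort("n_reads must be >= 1", class = "crnntfbs_input_error")
  for (cons in c(cfg$canonical_consensus, cfg$noncanonical_consensus)) {
    if (cfg$read_length < nchar(cons)) {
      abort("read_length shorter than a motif consensus",
            class = "crnntfbs_config_error")
    }
  }
  withr::with_seed(derive_seed(cfg$seed, "reads"), {
    ids <- sprintf("read_%05d", seq_len(n))
    seqs <- random_background(n, cfg$read_length, cfg$gc_content)
    n_plant <- round(n * cfg$planted_fraction)
    planted <- sort(sample.int(n, n_plant))
    n_nc <- round(n_plant * cfg$noncanonical_read_fraction)
    nc <- if (n_nc > 0L) sort(sample(planted, n_nc)) else integer()
    kind <- rep("none", n)
    kind[planted] <- "canonical"
    kind[nc] <- "noncanonical"
    offset <- rep(NA_integer_, n)
    strength <- rep(NA_real_, n)
    for (i in planted) {
      cons <- if (kind[i] == "canonical") cfg$canonical_consensus else
        cfg$noncanonical_consensus
      w <- nchar(cons)
      inst <- sample_motif_instance(cons, cfg$motif_softness)
      off <- sample.int(cfg$read_length - w + 1L, 1L) - 1L
      substr(seqs[i], off + 1L, off + w) <- inst
      offset[i] <- off
      strength[i] <- match_fraction(inst, cons)
    }
    list(
      reads = tibble(id = ids, seq = seqs, length = nchar(seqs)),
      truth = tibble(id = ids, has_motif = kind != "none",
                     motif_kind = kind, motif_offset = offset,
                     true_strength = strength)
    )
  })
}

#' Simulate ChIP-Seq peaks with decaying planted signal
#'
#' Generates `n_peaks` positive peak windows, each carrying one motif
#' instance whose centre lies within 10 nt of the peak summit. Site
#' strength decays exponentially with peak rank at `signal_decay` (the
#' per-position mismatch probability interpolates from `motif_softness` up
#' to `peak_softness_max`), and the ChIP enrichment score is a noisy
#' increasing function of strength, so sorting by score recovers the
#' strength gradient. An exact `noncanonical_peak_fraction` of peaks carry
#' the non-canonical motif instead, planted at full strength; their
#' model-window around the site is resampled until CNNG-free on both
#' strands, so the non-canonical phenomenon is present by construction.
#' q-values are a deterministic function of the score with all positives
#' passing `q < 1e-5`. A matched decoy set (dinucleotide shuffles of the
#' positive windows, no planted motif) is emitted as the negative dataset.
#'
#' @param cfg A [synth_config()].
#' @return List with `peaks` and `decoys` (peak tibbles as from
#'   [read_narrowpeak()]), `peak_seqs` and `decoy_seqs` (sequence tibbles),
#'   and `truth`.
#' @export
simulate_peaks <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_peaks
  if (n < 1L) abort("n_peaks must be >= 1", class = "crnntfbs_input_error")
  w_max <- max(nchar(cfg$canonical_consensus),
               nchar(cfg$noncanonical_consensus))
  if (cfg$peak_length < w_max + 20L) {
    abort("peak_length must be at least motif width + 20",
          class = "crnntfbs_config_error")
  }
  withr::with_seed(derive_seed(cfg$seed, "peaks"), {
    ids <- sprintf("peak_%04d", seq_len(n))
    rank_strength <- if (n == 1L) 1 else
      exp(-cfg$signal_decay * (seq_len(n) - 1L) / (n - 1L))
    n_nc <- round(n * cfg$noncanonical_peak_fraction)
    nc_idx <- if (n_nc > 0L) sort(sample.int(n, n_nc)) else integer()
    kind <- rep("canonical", n)
    kind[nc_idx] <- "noncanonical"
    summit <- cfg$peak_length %/% 2L

    seqs <- character(n)
    offset <- integer(n)
    strength <- numeric(n)
    for (i in seq_len(n)) {
      cons <- if (kind[i] == "canonical") cfg$canonical_consensus else
        cfg$noncanonical_consensus
      w <- nchar(cons)
      # canonical sites weaken with rank; non-canonical sites are planted
      # as the exact consensus (a single strongly bound sequence)
      soft <- if (kind[i] == "canonical") {
        cfg$motif_softness + (cfg$peak_softness_max - cfg$motif_softness) *
          (1 - rank_strength[i])
      } else 0
      repeat {
        s <- random_background(1L, cfg$peak_length, cfg$gc_content)
        inst <- sample_motif_instance(cons, soft)
        shift <- sample.int(21L, 1L) - 11L         # site centre in summit +/- 10
        off <- summit - w %/% 2L + shift
        off <- max(0L, min(cfg$peak_length - w, off))
        substr(s, off + 1L, off + w) <- inst
        if (kind[i] == "canonical") break
        # non-canonical sites must be CNNG-free across the site plus 8-nt
        # flanks, so every scan window containing the site is CNNG-free
        region <- substr(s, max(1L, off - 7L),
                         min(cfg$peak_length, off + w + 8L))
        if (!iupac_contains(region, "CNNG", both_strands = TRUE)) break
      }
      seqs[i] <- s
      offset[i] <- off
      strength[i] <- if (kind[i] == "canonical") {
        rank_strength[i] * match_fraction(inst, cons)
      } else match_fraction(inst, cons)
    }

    chip_score <- 10 * rank_strength * exp(rnorm(n, 0, cfg$chip_noise_sd))
    chip_score[nc_idx] <- 10 * exp(rnorm(length(nc_idx), 0,
                                         cfg$chip_noise_sd))
    gap <- cfg$peak_length + 20L
    peaks <- tibble(
      peak_id = ids, chrom = "chrSim",
      start = (seq_len(n) - 1L) * gap,
      end = (seq_len(n) - 1L) * gap + cfg$peak_length,
      summit_offset = summit,
      chip_score = chip_score,
      qvalue_mlog10 = 5 + chip_score
    )
    decoy_ids <- sprintf("decoy_%04d", seq_len(n))
    # decoys carry no motif by contract: reshuffle any whose rearrangement
    # happens to reassemble either consensus on either strand
    has_site <- function(s) {
      grepl(cfg$canonical_consensus, s, fixed = TRUE) ||
        grepl(cfg$noncanonical_consensus, s, fixed = TRUE) ||
        grepl(cfg$canonical_consensus, reverse_complement(s), fixed = TRUE) ||
        grepl(cfg$noncanonical_consensus, reverse_complement(s), fixed = TRUE)
    }
    decoy_seqs <- vapply(seqs, function(s) {
      for (try in 1:50) {
        d <- dinuc_shuffle_wrap(s)
        if (!has_site(d)) return(d)
      }
      d
    }, character(1), USE.NAMES = FALSE)
    decoys <- tibble(
      peak_id = decoy_ids, chrom = "chrDecoy",
      start = (seq_len(n) - 1L) * gap,
      end = (seq_len(n) - 1L) * gap + cfg$peak_length,
      summit_offset = summit,
      chip_score = 5 * exp(rnorm(n, 0, cfg$chip_noise_sd)),
      qvalue_mlog10 = 21
    )
    list(
      peaks = peaks, decoys = decoys,
      peak_seqs = tibble(id = ids, seq = seqs, length = nchar(seqs)),
      decoy_seqs = tibble(id = decoy_ids, seq = decoy_seqs,
                          length = nchar(decoy_seqs)),
      truth = bind_rows(
        tibble(id = ids, has_motif = TRUE, motif_kind = kind,
               motif_offset = offset, true_strength = strength),
        tibble(id = decoy_ids, has_motif = FALSE, motif_kind = "none",
               motif_offset = NA_integer_, true_strength = NA_real_)
      )
    )
  })
}

# shuffle using the current RNG stream (inside a with_seed block)
dinuc_shuffle_wrap <- function(s) dinuc_shuffle_impl(seq_chars(s))

#' Simulate a dissociation constant from a true site strength
#'
#' `Kd = kd_min * exp(kd_slope * (1 - strength))`, multiplied by log-normal
#' noise; values above the detection threshold are censored (NBD).
#' Monotone decreasing in strength when noise is off. Uses the current RNG
#' stream.
#'
#' @param strength True site strength in `[0,1]` (vectorised).
#' @param cfg A [synth_config()].
#' @param noise Apply log-normal measurement noise.
#' @return Tibble with `true_strength`, `kd` (`NA` when censored) and
#'   `censored`.
#' @export
simulate_kd <- function(strength, cfg, noise = TRUE) {
  stopifnot(all(strength >= 0 & strength <= 1))
  kd <- cfg$kd_min * exp(cfg$kd_slope * (1 - strength))
  if (noise) kd <- kd * exp(rnorm(length(kd), 0, cfg$kd_noise_sd))
  censored <- kd > cfg$detection_threshold
  tibble(true_strength = strength,
         kd = ifelse(censored, NA_real_, kd),
         censored = censored)
}

#' Simulate a ligand panel with measured and censored affinities
#'
#' Builds fixed-length ligand sequences whose planted canonical site
#' carries an exact number of mismatches per ligand (strength `s` gives
#' `round((1 - s) * width)` mismatches), emulating a titration panel that
#' spans strong binders down to non-binders, then simulates a Kd for each.
#' The default strength grid yields measured Kds for the strong ligands
#' and censored (NBD) records for the weak ones.
#'
#' @param cfg A [synth_config()].
#' @param strengths Strength grid, one ligand per value.
#' @return Affinity tibble: `ligand_id`, `seq`, `true_strength`, `kd`,
#'   `censored`.
#' @export
simulate_affinity_panel <- function(cfg,
                                    strengths = c(1, 0.9, 0.8, 0.7, 0.6,
                                                  0.5, 0.2, 0.1, 0)) {
  stopifnot(inherits(cfg, "synth_config"))
  cons <- cfg$canonical_consensus
  w <- nchar(cons)
  withr::with_seed(derive_seed(cfg$seed, "affinity"), {
    seqs <- vapply(strengths, function(s) {
      chars <- seq_chars(cons)
      n_mut <- round((1 - s) * w)
      if (n_mut > 0L) {
        pos <- sample.int(w, n_mut)
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, character(1), USE.NAMES = FALSE)
      }
      inst <- paste(chars, collapse = "")
      flank <- cfg$read_length - w
      left <- flank %/% 2L
      bg <- random_background(1L, cfg$read_length, cfg$gc_content)
      substr(bg, left + 1L, left + w) <- inst
      bg
    }, character(1))
    meas <- simulate_kd(strengths, cfg)
    tibble(ligand_id = sprintf("ligand_%02d", seq_along(strengths)),
           seq = seqs, true_strength = strengths,
           kd = meas$kd, censored = meas$censored)
  })
}

#' Write a peak tibble as an ENCODE narrowPeak file
#'
#' @param peaks Peak tibble (`peak_id`, `chrom`, `start`, `end`,
#'   `summit_offset`, `chip_score`, `qvalue_mlog10`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$peak_id, score = 0L, strand = ".",
    signalValue = peaks$chip_score, pValue = -1,
    qValue = peaks$qvalue_mlog10, peak = peaks$summit_offset
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
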