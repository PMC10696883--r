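---
title: "Methods: a convolutional-recurrent classifier for TF binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a convolutional-recurrent classifier for TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Position weight matrices score each base independently, so any binding mode
that depends on interactions between positions — or on a motif the matrix
was never built from — is invisible to them. This package trains a sequence
classifier that makes no such independence assumption and then uses the
*disagreement* between the two scorers as a discovery signal: windows the
network calls binding with very high confidence (score > 0.99) while the
log-odds matrix scores them below background (< 0 bits) are candidate
non-canonical binding sites.

The classifier maps a fixed-length DNA window (20 nt by default) to a
binding probability:

1. **one-hot encoding** — an L×4 matrix with columns A, C, G, T; unknown
   bases (`N`) become all-zero rows rather than 0.25-filled rows, so row
   sums stay exactly 0/1 and the network can learn to ignore them (the
   training pipeline rejects reads containing `N` anyway);
2. an optional **1-D convolution** (32 kernels of width 8, ReLU), **max
   pooling** (window 2) and dropout (0.25) — the motif-detector stage;
3. a **bidirectional LSTM** (32 units per direction; a GRU is available via
   `rnn_cell = "gru"`) whose final hidden states summarise the window in
   both reading directions;
4. a **dense ReLU layer** (64 units, dropout 0.5) under a per-unit max-norm
   constraint (3.0) on incoming weights;
5. a single **logistic output unit**, so scores live in [0, 1] and 0.5 is
   the binding/non-binding threshold.

Training minimises binary cross-entropy with Adam (learning rate 1e-3,
batch 256), stops early when the validation loss has not improved for 5
epochs, and restores the best-epoch weights. The early-stopping monitor is
the validation *loss*, not the AUC: with a few dozen batches per epoch the
loss is the smoother of the two signals. The whole network — forward pass,
backpropagation through time, Adam, dropout, max-norm projection — is
implemented in vectorised base R and verified in the test suite against a
central-difference numerical-gradient oracle (relative error below 1e-5 for
LSTM, GRU, convolutional and dense paths).

These hyperparameter defaults are explicit stand-ins chosen from the common
practice for small CNN+RNN sequence classifiers; `grid_search()` spans the
axes that matter (with/without convolution, kernel length, dense dropout,
uni- vs bidirectional recurrence) and selects by validation ROC-AUC with
ties broken toward fewer parameters, and `consistency_check()` retrains the
chosen configuration across independent splits to guard against a lucky
one.

## Negatives, splits, and leakage

Non-binding controls are **dinucleotide-preserving shuffles** of the
binding reads, built by the Altschul–Erickson Eulerian-walk construction:
the shuffled read has *exactly* the same multiset of overlapping 2-mers
(hence mononucleotide counts and GC content) and the same first and last
base, and is drawn uniformly from the set of valid rearrangements. The test
suite checks both the exact count preservation on random 20-mers and, on a
short fixture, that the sampler's support equals the brute-force enumerated
set of valid arrangements. The guarantee matters because it removes every
composition shortcut: a classifier that separates the classes must be
reading positional structure, not base content.

Datasets are split 70/15/15. A read and its shuffle are always co-assigned
to the same subset. This is a deliberate design choice on a question the
construction leaves open: assigning them independently would let the model
see near-duplicates of test composition during training, inflating held-out
estimates. With co-assignment, the label-permutation control in the test
suite sits at chance (AUC ≈ 0.5), which is the observable consequence of
no leakage.

Per-record shuffle streams are derived by hashing the record id together
with the top-level seed (FNV-1a reduced below 2^31), so regenerating a
collection in a different order yields identical negatives.

## PWM comparator

The classical arm converts a position frequency matrix to log2-odds against
a background (uniform by default; FIMO's default is a 0-order model from
the scanned sequences, but uniform is reproducible without reference to the
input and is recorded in the output). The pseudocount default is 0.1,
FIMO's own. Scores are in bits and 0 marks the below-background boundary
used by the discovery filter. PWM scanning defaults to both strands; the
neural scanner defaults to the forward strand (it was trained on
single-stranded reads) with a both-strand option. Both policies are
explicit arguments rather than hidden behaviour.

## Scanning and discovery

Peaks are reduced to 100-nt summit-centred windows; windows that would
overrun their contig are dropped, not clipped, because the model requires
fixed-length input and clipped windows would be scored on different amounts
of sequence. The sliding window moves at stride 1 and reports the best
20-mer; ties go to the smallest offset so results are deterministic.
Percentiles use midranks, computed within each dataset (positives against
positives, decoys against decoys would be meaningless — each result set is
its own reference).

The discovery filter applies *strict* inequalities (`> 0.99`, `< 0`),
matching the convention that the thresholds themselves are excluded.
Saturation mutagenesis enumerates all 3L single-nucleotide variants,
reports positions 1-based (the convention of wet-lab variant tables), and
records each variant's score delta against the parent.

## What the synthetic generator emulates — and what it does not

`synth_config()` encodes the study conditions the package is exercised
under:

* **reads**: 20-nt sequences, i.i.d. background at GC 0.5, a planted motif
  sampled from a consensus (`AAACCGGTTT`) with per-position mismatch
  probability (*softness*) 0.05 at a uniform offset. A fraction (0.15) of
  planted reads instead carry a **non-canonical motif** (`TTTTCCACTTTG`,
  verified CNNG-free on both strands at construction). This mixture is the
  generator's emulation of the core premise that the selection pool itself
  contains non-canonical binders a PWM cannot represent — without it no
  classifier trained on the reads could recognise such sites in peaks, and
  the discovery experiment would be vacuous by construction.
* **peaks**: 100-nt windows whose canonical site strength decays
  exponentially with peak rank (`signal_decay` = 1, per-position mismatch
  probability interpolating 0.05 → 0.4), with the ChIP enrichment score a
  log-normally noisy increasing function of strength — so sorting by score
  recovers the strength gradient, which is what the binned-AUC protocol
  measures. Non-canonical peaks (fraction 0.1) carry the exact
  non-canonical consensus, emulating a single strongly bound non-canonical
  sequence rather than a motif ensemble; the site plus 8-nt flanks is
  resampled until CNNG-free so that every scan window over the site shows
  the phenomenon. Decoy peaks are dinucleotide shuffles of the positive
  windows, reshuffled if a rearrangement happens to reassemble either
  consensus — decoys are motif-free by contract, as a negative ChIP set
  purged of overlapping sites would be.
* **affinities**: `Kd = kd_min · exp(kd_slope · (1 − strength))` with
  log-normal noise (sd 0.2), censored above a 9 µM detection threshold and
  reported as NBD. Defaults (`kd_min` 0.1 µM, `kd_slope` 7.5) place a
  full-strength site near 0.1 µM, mid-strength sites in the low-µM range
  and weak sites beyond the threshold — the structure of a titration panel
  with 6 measured and 3 censored ligands. The affinity analysis follows the
  censoring rules exactly: Pearson on measured pairs only, Spearman on
  midranked data with censored values imputed at 10 µM.

The generator does **not** emulate: selection-round enrichment dynamics,
sequencing error, read pileup shape, chromatin context, genomic repeat
structure, or inter-site interference within a peak. Passing tests
therefore show that the pipeline's logic and training machinery recover
planted structure under clean conditions; they do not certify performance
on real HT-SELEX or ChIP-Seq libraries, where label noise and covariate
shift are substantially worse.

## Numerical choices

* ROC-AUC is the exact Mann–Whitney statistic with midrank ties — no curve
  interpolation; curves are for plotting only. PR-AUC integrates the
  threshold sweep trapezoidally and equals class prevalence for an
  uninformative scorer.
* Binned AUC draws negatives without replacement within a repeat,
  independently across repeats; the per-repeat matrix is retained so the
  summary is auditable.
* Degenerate inputs fail loudly: zero-variance Pearson, fewer than three
  measured Kd pairs, empty score lists, windows containing `N` (scored
  `-Inf` by the PWM, rejected by the neural scorer), q-value thresholds
  outside (0, 1].
* All randomness flows from explicit integer seeds below 2^31; training is
  bit-reproducible for a fixed configuration, and predictions are
  batch-size invariant because every per-sample computation is independent.
* Model persistence is plain text (JSON config + full-precision JSON
  parameters + TSV history) with a format version checked at load.

## Problem sizes

The bundled checks run at desk scale, chosen so the full suite and the
reproduction script each complete comfortably on one CPU: ~14,300 balanced
records (≈10,000 training / ≈2,100 validation / ≈2,100 test) for the main
training runs, 500 positive peaks plus 500 decoys for scanning and
discovery, a 9-ligand affinity panel, and 1,000 reads for the shuffle
exactness check. Unit tests use smaller instances (hundreds of reads) with
a proportionally smaller network.

## Known limitations

* The recurrent layer processes the pooled convolutional features (6 time
  steps at the defaults), so "long-range" structure within a 20-mer is
  modest by construction; longer windows are supported but untested beyond
  100 nt peaks.
* Scores are calibrated only implicitly through cross-entropy; the 0.99
  discovery threshold is a convention, not a calibrated error rate.
* The PWM arm implements raw log-odds scoring (the quantity the discovery
  filter needs); p-value computation over the score distribution is out of
  scope.
* Training is CPU-bound R; at the default sizes a full run takes minutes,
  and the implementation is not intended for genome-scale scans or
  multi-million-read libraries.
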