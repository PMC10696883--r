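#' ROC curve and AUC from positive / negative score lists
#'
#' The AUC is computed exactly as the Mann-Whitney pair statistic with
#' midrank handling of ties: the probability that a random positive
#' outscores a random negative, counting ties as one half. The curve points
#' come from a threshold sweep over the pooled scores and are used for
#' plotting only.
#'
#' @param pos_scores,neg_scores Numeric score vectors (both non-empty).
#' @return An object of class `roc_result`: `auc`, `curve` (tibble with
#'   `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8), c(0.1, 0.2))$auc
roc_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    abort("both score lists must be non-empty",
          class = "crnntfbs_input_error")
  }
  np <- length(pos_scores); nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg_scores >= t), numeric(1))
  curve <- tibble(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  structure(list(auc = auc, curve = curve, n_pos = np, n_neg = nn),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration over the threshold sweep. A scorer with no
#' information attains the class prevalence `n_pos / (n_pos + n_neg)`.
#'
#' @inheritParams roc_auc
#' @return PR-AUC as a single number.
#' @export
pr_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    abort("both score lists must be non-empty",
          class = "crnntfbs_input_error")
  }
  np <- length(pos_scores)
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  recall <- vapply(thr, function(t) sum(pos_scores >= t) / np, numeric(1))
  prec <- vapply(thr, function(t) {
    tp <- sum(pos_scores >= t); fp <- sum(neg_scores >= t)
    tp / (tp + fp)
  }, numeric(1))
  recall <- c(0, recall)
  prec <- c(prec[1L], prec)
  sum(diff(recall) * (head(prec, -1L) + tail(prec, -1L)) / 2)
}

#' Binned, resampled-negative AUC across ChIP-Seq signal strength
#'
#' Sorts the positive peaks by decreasing ChIP-Seq score, partitions them
#' into consecutive bins of `bin_size` (the last bin may be smaller), and
#' for every bin repeatedly computes the ROC-AUC of the bin's scores
#' against `n_neg` negatives drawn uniformly without replacement —
#' `repeats` independent draws per bin — so that the choice of negative
#' sequences does not drive the comparison.
#'
#' @param pos_results Tibble with columns `score` and `chip_score`.
#' @param neg_results Tibble with a `score` column, at least `n_neg` rows.
#' @param bin_size Peaks per bin.
#' @param n_neg Negatives drawn per repeat.
#' @param repeats Number of negative redraws per bin.
#' @param seed Integer seed.
#' @return An object of class `binned_auc_result`: `bins` (tibble with
#'   `bin`, `n_pos`, `mean_chip_score`, `mean_auc`, `sd_auc`), the
#'   per-repeat AUC matrix `auc_matrix` (bins x repeats), `repeats`,
#'   `n_neg_per_repeat`.
#' @export
binned_auc <- function(pos_results, neg_results, bin_size = 500L,
                       n_neg = 500L, repeats = 1000L, seed = 1L) {
  if (nrow(neg_results) < n_neg) {
    abort(sprintf("need at least %d negatives, got %d", n_neg,
                  nrow(neg_results)), class = "crnntfbs_input_error")
  }
  pos <- arrange(pos_results, desc(.data$chip_score))
  n <- nrow(pos)
  n_bins <- ceiling(n / bin_size)
  bin_of <- rep(seq_len(n_bins), each = bin_size)[seq_len(n)]
  neg_scores <- neg_results$score
  auc_mat <- matrix(NA_real_, n_bins, repeats)
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      draw <- neg_scores[sample.int(length(neg_scores), n_neg)]
      for (b in seq_len(n_bins)) {
        auc_mat[b, r] <- roc_auc(pos$score[bin_of == b], draw)$auc
      }
    }
  })
  bins <- tibble(
    bin = seq_len(n_bins),
    n_pos = as.integer(tabulate(bin_of, n_bins)),
    mean_chip_score = vapply(seq_len(n_bins), function(b)
      mean(pos$chip_score[bin_of == b]), numeric(1)),
    mean_auc = rowMeans(auc_mat),
    sd_auc = apply(auc_mat, 1L, sd)
  )
  structure(list(bins = bins, auc_matrix = auc_mat, repeats = repeats,
                 n_neg_per_repeat = n_neg),
            class = "binned_auc_result")
}

#' @export
print.binned_auc_result <- function(x, ...) {
  cat(sprintf("<binned_auc_result> %d bins, %d repeats of %d negatives\n",
              nrow(x$bins), x$repeats, x$n_neg_per_repeat))
  print(x$bins)
  invisible(x)
}

#' Summarise score distributions per dataset and flag named sequences
#'
#' @param results Tibble with columns `dataset`, `peak_id` and `score`
#'   (stack several scan results with a `dataset` label to compare them).
#' @param flag_ids Optional ids to report individually with their score and
#'   within-dataset percentile; missing ids produce a warning.
#' @return A list with `summary` (per-dataset quartiles, mean, n) and
#'   `flagged` (tibble of the requested ids).
#' @export
score_distribution_summary <- function(results, flag_ids = NULL) {
  stopifnot(all(c("dataset", "score") %in% names(results)))
  summary <- results |>
    group_by(.data$dataset) |>
    summarise(
      n = n(), min = min(.data$score),
      q25 = unname(quantile(.data$score, 0.25)),
      median = unname(quantile(.data$score, 0.5)),
      q75 = unname(quantile(.data$score, 0.75)), max = max(.data$score),
      mean = mean(.data$score), .groups = "drop"
    )
  flagged <- NULL
  if (!is.null(flag_ids)) {
    missing <- setdiff(flag_ids, results$peak_id)
    if (length(missing) > 0L) {
      warn(sprintf("flagged id(s) absent from results: %s",
                   paste(missing, collapse = ",")))
    }
    flagged <- results |>
      group_by(.data$dataset) |>
      mutate(percentile = 100 * rank(.data$score, ties.method = "average") / n()) |>
      ungroup() |>
      filter(.data$peak_id %in% flag_ids)
  }
  list(summary = summary, flagged = flagged)
}

#' Correlate predicted binding scores with measured dissociation constants
#'
#' Follows the censoring rules of the affinity analysis: Pearson (on raw
#' values) uses only ligands with a measured Kd, while Spearman (on ranks)
#' uses all ligands with censored "no binding detected" records imputed at
#' `censored_value` (10 uM by default, just above the 9 uM detection
#' threshold). Strong binders have low Kd and high score, so the signed
#' coefficients are negative; the absolute magnitudes are reported
#' alongside.
#'
#' @param scores Named numeric vector (names = ligand ids) or a tibble with
#'   `ligand_id` and `score`.
#' @param affinities Affinity tibble with `ligand_id`, `kd` (numeric, NA
#'   when censored) and `censored` (logical); see [read_affinity_table()].
#' @param censored_value Imputed Kd for censored records (uM).
#' @return One-row tibble: `pearson_r`, `r_squared`, `spearman_rho`,
#'   `abs_pearson_r`, `abs_spearman_rho`, `n_used_pearson`,
#'   `n_used_spearman`.
#' @export
affinity_correlation <- function(scores, affinities, censored_value = 10) {
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$ligand_id)
  }
  missing <- setdiff(affinities$ligand_id, names(scores))
  if (length(missing) > 0L) {
    abort(sprintf("no score for ligand(s): %s",
                  paste(missing, collapse = ",")),
          class = "crnntfbs_input_error")
  }
  s <- unname(scores[affinities$ligand_id])
  cens <- affinities$censored
  kd_meas <- affinities$kd[!cens]
  s_meas <- s[!cens]
  if (length(kd_meas) < 3L) {
    abort("fewer than 3 uncensored Kd measurements: Pearson undefined",
          class = "crnntfbs_insufficient_data")
  }
  if (sd(kd_meas) == 0 || sd(s_meas) == 0) {
    abort("zero variance in scores or Kd: Pearson undefined",
          class = "crnntfbs_degenerate_error")
  }
  pearson <- cor(s_meas, kd_meas, method = "pearson")
  kd_all <- affinities$kd
  kd_all[cens] <- censored_value
  spearman <- if (length(kd_all) >= 3L) {
    cor(s, kd_all, method = "spearman")
  } else NA_real_
  tibble(
    pearson_r = pearson, r_squared = pearson^2, spearman_rho = spearman,
    abs_pearson_r = abs(pearson), abs_spearman_rho = abs(spearman),
    n_used_pearson = length(kd_meas), n_used_spearman = length(kd_all)
  )
}

#' Read a ligand affinity table
#'
#' Expects a TSV with columns `ligand_id`, `sequence` and `kd_uM`, where a
#' literal `NBD` ("no binding detected") marks a censored measurement;
#' optional thermodynamic columns (`dH`, `minus_TdS`, `dG`, kcal/mol) are
#' carried through untouched. A machine-readable mirror of the published
#' GRHL1 isothermal-titration-calorimetry panel ships with the package:
#' `system.file("extdata", "grhl1_itc_affinities.tsv", package = "crnntfbs")`.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `ligand_id`, `seq`, `kd` (numeric, `NA` when
#'   censored), `censored` (logical) and any extra columns.
#' @export
read_affinity_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("ligand_id", "sequence", "kd_uM") %in% names(df)))
  kd_raw <- as.character(df$kd_uM)
  censored <- toupper(trimws(kd_raw)) == "NBD"
  kd <- suppressWarnings(as.numeric(kd_raw))
  if (any(!censored & is.na(kd))) {
    abort("kd_uM must be numeric or 'NBD'", class = "crnntfbs_parse_error")
  }
  if (any(kd <= 0, na.rm = TRUE)) {
    abort("measured Kd must be positive", class = "crnntfbs_validation_error")
  }
  out <- tibble(ligand_id = df$ligand_id,
                seq = assert_dna_vec(df$sequence),
                kd = kd, censored = censored)
  extra <- setdiff(names(df), c("ligand_id", "sequence", "kd_uM"))
  if (length(extra) > 0L) out <- dplyr::bind_cols(out, df[extra])
  out
}
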