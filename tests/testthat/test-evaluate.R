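test_that("ROC-AUC equals the Mann-Whitney pair statistic", {
  expect_equal(roc_auc(c(0.9, 0.8), c(0.1, 0.2))$auc, 1.0)
  expect_equal(roc_auc(c(0.5, 0.5), c(0.5, 0.5))$auc, 0.5)
  withr::local_seed(91)
  for (i in 1:20) {
    pos <- runif(20); neg <- runif(20)
    if (i %% 3 == 0) pos <- round(pos, 1)   # force ties
    if (i %% 3 == 0) neg <- round(neg, 1)
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(roc_auc(pos, neg)$auc, mean(pairs), tolerance = 1e-12)
  }
  expect_error(roc_auc(numeric(), 1), class = "crnntfbs_input_error")
})

test_that("ROC-AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(92)
  pos <- rnorm(50, 1); neg <- rnorm(60)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 50), rep(0, 60)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(pos, neg)$auc, ref, tolerance = 1e-12)
})

test_that("ROC-AUC invariances: monotone transforms and class swap", {
  withr::local_seed(93)
  pos <- runif(30); neg <- runif(25)
  a <- roc_auc(pos, neg)$auc
  expect_equal(roc_auc(exp(3 * pos), exp(3 * neg))$auc, a)
  expect_equal(roc_auc(neg, pos)$auc, 1 - a, tolerance = 1e-12)
  curve <- roc_auc(pos, neg)$curve
  expect_equal(curve[1, ], tibble::tibble(fpr = 0, tpr = 0))
  expect_equal(unlist(curve[nrow(curve), ]), c(fpr = 1, tpr = 1))
})

test_that("PR-AUC hits its closed-form anchors and a brute-force oracle", {
  expect_equal(pr_auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  # an uninformative scorer attains the class prevalence
  expect_equal(pr_auc(rep(0.4, 30), rep(0.4, 70)), 0.3)

  # independent enumeration oracle on a small instance
  withr::local_seed(94)
  pos <- runif(8); neg <- runif(12)
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  rec <- c(0, vapply(thr, function(t) mean(pos >= t), numeric(1)))
  prc <- vapply(thr, function(t) {
    sum(pos >= t) / (sum(pos >= t) + sum(neg >= t))
  }, numeric(1))
  prc <- c(prc[1], prc)
  oracle <- sum(diff(rec) * (prc[-length(prc)] + prc[-1]) / 2)
  expect_equal(pr_auc(pos, neg), oracle, tolerance = 1e-9)
})

test_that("binned AUC partitions by decreasing ChIP score", {
  withr::local_seed(95)
  pos <- tibble::tibble(peak_id = sprintf("p%d", 1:23),
                        score = runif(23), chip_score = runif(23, 1, 10))
  neg <- tibble::tibble(peak_id = sprintf("n%d", 1:40), score = runif(40))
  res <- binned_auc(pos, neg, bin_size = 10L, n_neg = 15L, repeats = 4L,
                    seed = 2)
  expect_equal(res$bins$n_pos, c(10L, 10L, 3L))
  expect_true(all(diff(res$bins$mean_chip_score) < 0))
  expect_equal(dim(res$auc_matrix), c(3L, 4L))
  expect_equal(res$bins$mean_auc, rowMeans(res$auc_matrix))
  rerun <- binned_auc(pos, neg, bin_size = 10L, n_neg = 15L, repeats = 4L,
                      seed = 2)
  expect_equal(res$bins, rerun$bins)
  expect_error(binned_auc(pos, neg, n_neg = 500L),
               class = "crnntfbs_input_error")
})

test_that("resampled binned AUC converges to the full-pool AUC", {
  withr::local_seed(96)
  pos <- tibble::tibble(peak_id = sprintf("p%d", 1:30),
                        score = rnorm(30, 1), chip_score = 1)
  neg <- tibble::tibble(peak_id = sprintf("n%d", 1:50), score = rnorm(50))
  exact <- roc_auc(pos$score, neg$score)$auc
  res <- binned_auc(pos, neg, bin_size = 30L, n_neg = 20L, repeats = 2000L,
                    seed = 3)
  se <- res$bins$sd_auc[1] / sqrt(res$repeats)
  expect_lt(abs(res$bins$mean_auc[1] - exact), 3 * se + 1e-3)
})

test_that("binned AUC declines when signal decays with ChIP score", {
  withr::local_seed(97)
  # strongest bin separates perfectly, weakest not at all
  chip <- seq(100, 1, length.out = 60)
  strength <- chip / 100
  pos <- tibble::tibble(peak_id = sprintf("p%d", 1:60),
                        score = strength + rnorm(60, 0, 0.1),
                        chip_score = chip)
  neg <- tibble::tibble(peak_id = sprintf("n%d", 1:80),
                        score = rnorm(80, 0, 0.1))
  res <- binned_auc(pos, neg, bin_size = 20L, n_neg = 40L, repeats = 50L,
                    seed = 4)
  expect_true(all(diff(res$bins$mean_auc) <= 0.05))
  expect_gt(res$bins$mean_auc[1], res$bins$mean_auc[3])
})

test_that("score summaries report quartiles per dataset and flag ids", {
  res <- tibble::tibble(dataset = rep(c("g", "m"), each = 4),
                        peak_id = sprintf("p%d", 1:8),
                        score = c(0.1, 0.2, 0.3, 0.4, rep(0.5, 4)))
  s <- score_distribution_summary(res)
  g <- s$summary[s$summary$dataset == "g", ]
  expect_equal(c(g$q25, g$median, g$q75), c(0.175, 0.25, 0.325))
  m <- s$summary[s$summary$dataset == "m", ]
  expect_equal(c(m$q25, m$median, m$q75), c(0.5, 0.5, 0.5))

  flagged <- score_distribution_summary(res, flag_ids = "p4")$flagged
  expect_equal(flagged$percentile, 100)
  expect_warning(score_distribution_summary(res, flag_ids = "absent"),
                 "absent")
})

test_that("affinity correlation applies the censoring rules", {
  # perfect monotone inverse relation, no censoring
  aff <- tibble::tibble(ligand_id = sprintf("l%d", 1:6),
                        kd = c(0.1, 0.3, 1, 2, 5, 8),
                        censored = FALSE)
  scores <- tibble::tibble(ligand_id = aff$ligand_id,
                           score = c(0.99, 0.9, 0.7, 0.5, 0.3, 0.1))
  res <- affinity_correlation(scores, aff)
  expect_equal(res$spearman_rho, -1)
  expect_equal(res$r_squared, res$pearson_r^2)

  # hand-built 6 measured + 3 censored panel: Spearman on midranked data
  # with censored records imputed at 10; Pearson on the 6 measured only
  aff9 <- tibble::tibble(
    ligand_id = sprintf("l%d", 1:9),
    kd = c(0.11, 3.4, 1.54, 4.35, 0.18, 0.21, NA, NA, NA),
    censored = c(rep(FALSE, 6), rep(TRUE, 3))
  )
  sc9 <- tibble::tibble(ligand_id = aff9$ligand_id,
                        score = c(0.99, 0.62, 0.81, 0.55, 0.98, 0.97,
                                  0.10, 0.32, 0.05))
  res9 <- affinity_correlation(sc9, aff9, censored_value = 10)
  kd_imp <- ifelse(aff9$censored, 10, aff9$kd)
  oracle_rho <- cor(rank(sc9$score), rank(kd_imp), method = "pearson")
  expect_equal(res9$spearman_rho, oracle_rho, tolerance = 1e-12)
  expect_equal(res9$pearson_r,
               cor(sc9$score[1:6], aff9$kd[1:6]), tolerance = 1e-12)
  expect_equal(res9$n_used_pearson, 6L)
  expect_equal(res9$n_used_spearman, 9L)

  # degenerate cases surface as explicit errors
  expect_error(
    affinity_correlation(sc9, dplyr::mutate(aff9, kd = 1, censored = FALSE)),
    class = "crnntfbs_degenerate_error")
  expect_error(
    affinity_correlation(sc9[1:2, ], aff9[1:2, ]),
    class = "crnntfbs_insufficient_data")
  expect_error(
    affinity_correlation(sc9[1:8, ], aff9),
    class = "crnntfbs_input_error")
})

test_that("the shipped ITC panel mirror parses with its censoring flags", {
  aff <- read_affinity_table(itc_fixture_path())
  expect_equal(nrow(aff), 9L)
  expect_equal(sum(aff$censored), 3L)
  expect_equal(aff$kd[aff$ligand_id == "Pos_Ctrl"], 0.11)
  expect_equal(aff$seq[aff$ligand_id == "Novel"], "AGGTTTTTCCACTTTGGGGC")
  expect_true(all(is.na(aff$kd[aff$censored])))
  expect_equal(aff$dG[aff$ligand_id == "Novel_V2"], -41.0)
})
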