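# central-difference gradient check: the independent oracle for the
# hand-written backpropagation
numeric_grad_worst <- function(cfg, n = 5L, n_checks = 12L, eps = 1e-5) {
  ns <- asNamespace("crnntfbs")
  withr::local_seed(123)
  seqs <- random_dna(n, cfg$input_length)
  y <- rep(c(1, 0), length.out = n)
  X <- ns$encode_batch(seqs)
  params <- withr::with_seed(1, ns$init_params(cfg))
  fwd <- ns$net_forward(params, cfg, X, training = FALSE)
  grads <- ns$net_backward(params, cfg, X, y, fwd)
  loss_at <- function(p) {
    ns$bce_loss(ns$net_forward(p, cfg, X, training = FALSE)$prob, y)
  }
  flat <- ns$flatten_params(params)
  gflat <- ns$flatten_params(grads)
  worst <- 0
  for (k in seq_len(n_checks)) {
    key <- sample(names(flat), 1)
    j <- sample(length(flat[[key]]$values), 1)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    bump <- function(p, d) {
      if (length(parts) == 1) p[[parts]][j] <- p[[parts]][j] + d
      else p[[parts[1]]][[parts[2]]][j] <- p[[parts[1]]][[parts[2]]][j] + d
      p
    }
    num <- (loss_at(bump(params, eps)) - loss_at(bump(params, -eps))) /
      (2 * eps)
    ana <- gflat[[key]]$values[j]
    worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
  }
  worst
}

test_that("analytic gradients match numerical differentiation", {
  archs <- list(
    crnn_config(input_length = 12L, conv_kernels = 5L, kernel_len = 3L,
                pool_size = 2L, conv_dropout = 0, rnn_units = 4L,
                dense_units = 6L, dense_dropout = 0, seed = 3L),
    crnn_config(use_conv = FALSE, input_length = 8L, bidirectional = FALSE,
                rnn_units = 5L, dense_units = 4L, dense_dropout = 0,
                conv_dropout = 0, seed = 4L),
    crnn_config(rnn_cell = "gru", input_length = 12L, conv_kernels = 4L,
                kernel_len = 4L, pool_size = 2L, conv_dropout = 0,
                rnn_units = 4L, dense_units = 5L, dense_dropout = 0,
                seed = 5L)
  )
  for (cfg in archs) expect_lt(numeric_grad_worst(cfg), 1e-5)
})

test_that("configuration invariants are enforced before training", {
  expect_error(crnn_config(dense_dropout = 1.5),
               class = "crnntfbs_config_error")
  expect_error(crnn_config(kernel_len = 30L, input_length = 20L),
               class = "crnntfbs_config_error")
  expect_error(crnn_config(max_norm = -1), class = "crnntfbs_config_error")
})

test_that("model builds are deterministic and bounded in [0,1]", {
  withr::local_seed(71)
  cfg <- tiny_config()
  probe <- random_dna(32, 20)
  a <- predict(build_model(cfg), probe)
  b <- predict(build_model(cfg), probe)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  # the no-conv, unidirectional variant builds and predicts too
  m <- build_model(tiny_config(use_conv = FALSE, bidirectional = FALSE))
  expect_true(all(predict(m, probe) >= 0))
})

test_that("prediction is a pure, order-preserving, batch-invariant map", {
  withr::local_seed(72)
  m <- tiny_trained_model()
  s <- random_dna(1, 20)
  batch <- c(s, random_dna(999, 20), s)
  p <- predict(m, batch)
  expect_equal(p[1], p[1000 + 1L])                     # duplicates agree
  expect_equal(predict(m, s), p[1], tolerance = 1e-6)  # batch of one agrees
  expect_error(predict(m, tibble::tibble(id = "bad", seq = "ACGT")),
               class = "crnntfbs_input_error", regexp = "bad")
})

test_that("training learns a planted motif and is seed-reproducible", {
  m <- tiny_trained_model()
  expect_gt(m$validation_auc, 0.9)
  expect_s3_class(m$history, "data.frame")
  expect_true(all(c("train_loss", "val_loss", "val_auc") %in%
                    names(m$history)))
  parts <- tiny_split()
  rerun <- train(build_model(tiny_config()), parts$train, parts$validation)
  expect_equal(rerun$validation_auc, m$validation_auc, tolerance = 1e-6)

  # a trained model separates motif-bearing reads from their shuffles
  p <- predict(m, parts$test)
  expect_gt(median(p[parts$test$label == "binding"]),
            median(p[parts$test$label == "non_binding"]))
})

test_that("label permutation destroys the signal (leakage control)", {
  parts <- tiny_split()
  perm <- parts
  withr::with_seed(1, {
    for (nm in names(perm)) {
      perm[[nm]]$label <- sample(perm[[nm]]$label)
    }
  })
  m <- train(build_model(tiny_config(max_epochs = 4L)), perm$train,
             perm$validation)
  te <- perm$test
  p <- predict(m, te)
  auc <- roc_auc(p[te$label == "binding"], p[te$label == "non_binding"])$auc
  # wide band: small test set, chance-level expectation
  expect_gt(auc, 0.3)
  expect_lt(auc, 0.7)
})

test_that("grid search validates everything first and ranks by AUC", {
  parts <- tiny_split()
  bad <- tiny_config()
  bad$dense_dropout <- 1.4                 # corrupt after construction
  expect_error(grid_search(list(tiny_config(), bad), parts$train,
                           parts$validation),
               class = "crnntfbs_config_error")

  single <- grid_search(list(tiny_config(max_epochs = 2L)), parts$train,
                        parts$validation)
  expect_equal(nrow(single$table), 1L)
  expect_equal(single$best_config, single$table$config[[1]])

  grid <- list(tiny_config(max_epochs = 3L),
               tiny_config(max_epochs = 3L, use_conv = FALSE,
                           bidirectional = FALSE, rnn_units = 4L))
  gs <- grid_search(grid, parts$train, parts$validation)
  expect_equal(nrow(gs$table), 2L)
  expect_equal(gs$best_model$validation_auc, max(gs$table$validation_auc))
})

test_that("repeated-split consistency checks are deterministic summaries", {
  withr::local_seed(73)
  cfg <- synth_config(n_reads = 120L, seed = 55L)
  ds <- build_balanced_dataset(simulate_reads(cfg)$reads, seed = 5)
  mini <- tiny_config(max_epochs = 2L, batch_size = 32L)
  a <- consistency_check(mini, ds, repeats = 2L, base_seed = 10L)
  b <- consistency_check(mini, ds, repeats = 2L, base_seed = 10L)
  expect_equal(a$summary, b$summary)
  expect_equal(a$summary$mean_auc, mean(a$runs$test_auc), tolerance = 1e-12)
  expect_equal(nrow(a$runs), 2L)
  expect_error(consistency_check(mini, ds, repeats = 1L),
               class = "crnntfbs_input_error")
})

test_that("saved models reload with identical config and predictions", {
  withr::local_seed(74)
  m <- tiny_trained_model()
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(unclass(m2$config), unclass(m$config))
  probe <- random_dna(100, 20)
  expect_lt(max(abs(predict(m2, probe) - predict(m, probe))), 1e-6)

  # truncation is an explicit incompatibility, not a silent misload
  pf <- file.path(dir, "params.json")
  writeLines(substr(readLines(pf, warn = FALSE)[1], 1, 200), pf)
  expect_error(load_model(dir), class = "crnntfbs_incompatible_model")

  # version mismatches are refused
  dir2 <- withr::local_tempdir()
  save_model(m, dir2)
  cj <- file.path(dir2, "config.json")
  meta <- jsonlite::read_json(cj)
  meta$format_version <- 999L
  jsonlite::write_json(meta, cj, auto_unbox = TRUE)
  expect_error(load_model(dir2), class = "crnntfbs_incompatible_model")
})

test_that("tidiers expose history and a one-row model summary", {
  m <- tiny_trained_model()
  h <- tidy(m)
  expect_equal(names(h), c("epoch", "train_loss", "val_loss", "val_auc"))
  g <- glance(m)
  expect_equal(nrow(g), 1L)
  expect_equal(g$validation_auc, m$validation_auc)
  expect_true(g$n_params > 0)
})
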