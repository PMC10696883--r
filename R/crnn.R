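#' Configuration for the convolutional-recurrent binding classifier
#'
#' Bundles every tunable hyperparameter of the network: an optional 1-D
#' convolution (ReLU, temporal max pooling, dropout) feeding a uni- or
#' bidirectional recurrent layer (LSTM by default), then a dense ReLU layer
#' with dropout and a per-unit max-norm weight constraint, and a single
#' logistic output unit so scores live in \[0,1\] with 0.5 as the binding
#' threshold. Training uses binary cross-entropy, Adam, and early stopping
#' on validation loss with best-weights restoration.
#'
#' @param use_conv Include the convolutional front end.
#' @param conv_kernels Number of convolution filters.
#' @param kernel_len Filter width in nucleotides.
#' @param pool_size Temporal max-pooling window.
#' @param conv_dropout Dropout fraction after pooling, in `[0,1)`.
#' @param rnn_units Hidden units per recurrent direction.
#' @param bidirectional Run the recurrence in both directions and
#'   concatenate the final hidden states.
#' @param rnn_cell `"lstm"` (default) or `"gru"`.
#' @param dense_units Units in the dense layer.
#' @param dense_dropout Dropout fraction after the dense layer.
#' @param max_norm Upper bound on the L2 norm of each dense unit's incoming
#'   weight vector.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs (validation loss).
#' @param input_length Fixed sequence length in nucleotides.
#' @param seed Integer seed pinning initialisation, batch order and dropout.
#' @return An object of class `crnn_config`.
#' @export
crnn_config <- function(use_conv = TRUE, conv_kernels = 32L, kernel_len = 8L,
                        pool_size = 2L, conv_dropout = 0.25,
                        rnn_units = 32L, bidirectional = TRUE,
                        rnn_cell = c("lstm", "gru"),
                        dense_units = 64L, dense_dropout = 0.5,
                        max_norm = 3.0, learning_rate = 1e-3,
                        batch_size = 256L, max_epochs = 100L, patience = 5L,
                        input_length = 20L, seed = 1L) {
  rnn_cell <- match.arg(rnn_cell)
  cfg <- list(
    use_conv = isTRUE(use_conv), conv_kernels = as.integer(conv_kernels),
    kernel_len = as.integer(kernel_len), pool_size = as.integer(pool_size),
    conv_dropout = conv_dropout, rnn_units = as.integer(rnn_units),
    bidirectional = isTRUE(bidirectional), rnn_cell = rnn_cell,
    dense_units = as.integer(dense_units), dense_dropout = dense_dropout,
    max_norm = max_norm, learning_rate = learning_rate,
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), input_length = as.integer(input_length),
    seed = as.integer(seed)
  )
  validate_crnn_config(cfg)
  structure(cfg, class = "crnn_config")
}

validate_crnn_config <- function(cfg) {
  bad <- character()
  chk <- function(cond, msg) if (!cond) bad <<- c(bad, msg)
  chk(cfg$conv_dropout >= 0 && cfg$conv_dropout < 1,
      "conv_dropout must be in [0,1)")
  chk(cfg$dense_dropout >= 0 && cfg$dense_dropout < 1,
      "dense_dropout must be in [0,1)")
  chk(cfg$max_norm > 0, "max_norm must be > 0")
  chk(cfg$learning_rate > 0, "learning_rate must be > 0")
  chk(cfg$rnn_units >= 1, "rnn_units must be >= 1")
  chk(cfg$input_length >= 1, "input_length must be >= 1")
  if (cfg$use_conv) {
    chk(cfg$kernel_len <= cfg$input_length,
        "kernel_len must not exceed input_length")
    chk(cfg$pool_size >= 1, "pool_size must be >= 1")
    chk((cfg$input_length - cfg$kernel_len + 1L) %/% cfg$pool_size >= 1L,
        "pooled sequence would be empty: shrink kernel_len or pool_size")
  }
  if (length(bad) > 0L) {
    abort(paste0("invalid model configuration:\n", paste("-", bad, collapse = "\n")),
          class = "crnntfbs_config_error")
  }
  invisible(cfg)
}

#' Build an (untrained) convolutional-recurrent model
#'
#' Initialises all parameters deterministically from `config$seed`
#' (Glorot-uniform weights, zero biases, LSTM forget-gate bias 1) so that
#' two builds from the same configuration produce identical predictions.
#'
#' @param config A [crnn_config()].
#' @return An object of class `crnn_model` with elements `config`,
#'   `params`, `n_params`, `trained`, `history` and `validation_auc`.
#' @export
build_model <- function(config) {
  validate_crnn_config(config)
  params <- withr::with_seed(config$seed, init_params(config))
  structure(
    list(config = config, params = params, n_params = count_params(params),
         trained = FALSE, history = NULL, validation_auc = NA_real_),
    class = "crnn_model"
  )
}

#' @export
print.crnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<crnn_model> %s%s(%d units), input %d nt, %d parameters, %s\n",
    if (cfg$use_conv) sprintf("conv(%dx%d)+pool(%d) -> ", cfg$conv_kernels,
                              cfg$kernel_len, cfg$pool_size) else "",
    paste0(if (cfg$bidirectional) "bi-" else "", toupper(cfg$rnn_cell)),
    cfg$rnn_units, cfg$input_length, x$n_params,
    if (x$trained) sprintf("trained (val AUC %.4f)", x$validation_auc)
    else "untrained"
  ))
  invisible(x)
}

prepare_xy <- function(dataset, input_length, what) {
  if (nrow(dataset) == 0L) {
    abort(sprintf("%s set is empty", what), class = "crnntfbs_input_error")
  }
  seqs <- assert_dna_vec(dataset$seq, allow_n = FALSE,
                         what = sprintf("%s sequences", what))
  bad <- nchar(seqs) != input_length
  if (any(bad)) {
    abort(sprintf("%s sequences with wrong length (expected %d): %s",
                  what, input_length,
                  paste(head(dataset$id[bad], 5L), collapse = ",")),
          class = "crnntfbs_input_error")
  }
  list(X = encode_batch(seqs),
       y = as.numeric(dataset$label == "binding"))
}

#' Train the binding classifier
#'
#' Minimises binary cross-entropy with Adam on shuffled minibatches. After
#' each epoch the validation loss is computed; training stops when it has
#' not improved for `patience` epochs and the best-epoch parameters are
#' restored. The per-epoch history and the final validation ROC-AUC are
#' recorded on the returned model. Fully deterministic given
#' `config$seed`.
#'
#' @param model An untrained (or trained) `crnn_model`.
#' @param train_set,val_set Labelled dataset tibbles (`id`, `seq`, `label`)
#'   whose sequences all have length `config$input_length` and no `N`.
#' @param quiet Suppress per-epoch progress messages.
#' @return The trained `crnn_model`.
#' @export
train <- function(model, train_set, val_set, quiet = TRUE) {
  stopifnot(inherits(model, "crnn_model"))
  cfg <- model$config
  tr <- prepare_xy(train_set, cfg$input_length, "training")
  va <- prepare_xy(val_set, cfg$input_length, "validation")
  params <- model$params
  opt <- adam_init(params)
  n <- dim(tr$X)[1L]
  bs <- min(cfg$batch_size, n)

  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L
  hist <- list()

  withr::with_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      n_batches <- ceiling(n / bs)
      for (bi in seq_len(n_batches)) {
        idx <- perm[((bi - 1L) * bs + 1L):min(bi * bs, n)]
        Xb <- tr$X[idx, , , drop = FALSE]
        yb <- tr$y[idx]
        fwd <- net_forward(params, cfg, Xb, training = TRUE)
        loss <- bce_loss(fwd$prob, yb)
        if (!is.finite(loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d",
                        epoch), class = "crnntfbs_divergence_error")
        }
        ep_loss <- ep_loss + loss * length(idx)
        grads <- net_backward(params, cfg, Xb, yb, fwd)
        stepped <- adam_step(params, grads, opt, cfg$learning_rate)
        params <- stepped$params
        opt <- stepped$state
        params$Wd <- max_norm_project(params$Wd, cfg$max_norm)
        params$Wo <- max_norm_project(params$Wo, cfg$max_norm)
      }
      val_prob <- predict_prob(params, cfg, va$X)
      val_loss <- bce_loss(val_prob, va$y)
      val_auc <- roc_auc(val_prob[va$y == 1], val_prob[va$y == 0])$auc
      hist[[epoch]] <- tibble(epoch = epoch,
                              train_loss = ep_loss / n,
                              val_loss = val_loss, val_auc = val_auc)
      if (!quiet) {
        inform(sprintf("epoch %3d  train %.4f  val %.4f  val AUC %.4f",
                       epoch, ep_loss / n, val_loss, val_auc))
      }
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })

  model$params <- best_params
  model$trained <- TRUE
  model$history <- bind_rows(hist)
  model$best_epoch <- best_epoch
  va_prob <- predict_prob(best_params, cfg, va$X)
  model$validation_auc <- roc_auc(va_prob[va$y == 1], va_prob[va$y == 0])$auc
  model
}

# forward pass in inference mode, chunked so memory stays bounded;
# per-sample arithmetic is batch-independent, so chunking never changes scores
predict_prob <- function(params, cfg, X, chunk = 1024L) {
  n <- dim(X)[1L]
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e] <- net_forward(params, cfg, X[s:e, , , drop = FALSE],
                            training = FALSE)$prob
  }
  out
}

#' Predict binding scores for sequences
#'
#' @param object A trained `crnn_model`.
#' @param newdata A sequence tibble (`id`, `seq`), a labelled dataset, or a
#'   bare character vector of sequences.
#' @param ... Unused.
#' @return Numeric vector of scores in \[0,1\], one per sequence, in input
#'   order; scores above 0.5 denote a positive binding prediction.
#' @export
predict.crnn_model <- function(object, newdata, ...) {
  cfg <- object$config
  if (is.character(newdata)) {
    newdata <- tibble(id = paste0("seq", seq_along(newdata)), seq = newdata)
  }
  seqs <- assert_dna_vec(newdata$seq, allow_n = FALSE)
  bad <- nchar(seqs) != cfg$input_length
  if (any(bad)) {
    abort(sprintf("sequences with wrong length (expected %d nt): %s",
                  cfg$input_length,
                  paste(head(newdata$id[bad], 5L), collapse = ",")),
          class = "crnntfbs_input_error")
  }
  predict_prob(object$params, cfg, encode_batch(seqs))
}

#' Wrap a trained model as a window-scoring function
#'
#' Convenience for [scan_sequences()]: returns a function mapping a
#' character vector of fixed-length windows to scores.
#'
#' @param model A trained `crnn_model`.
#' @return `function(windows) -> numeric`.
#' @export
crnn_scorer <- function(model) {
  force(model)
  function(windows) predict(model, windows)
}

#' Grid search over model configurations
#'
#' Trains every configuration on a shared train/validation split and ranks
#' them by validation ROC-AUC; ties are broken by fewer parameters, then by
#' lower seed. All configurations are validated before any training starts.
#'
#' @param grid A list of [crnn_config()] objects.
#' @param train_set,val_set Labelled dataset tibbles.
#' @param quiet Suppress progress messages.
#' @return A list of class `crnn_grid_search`: `table` (one row per
#'   configuration with `config_id`, `n_params`, `seed`, `validation_auc`
#'   and a `config` list-column), `best_config`, and `models`.
#' @export
grid_search <- function(grid, train_set, val_set, quiet = TRUE) {
  if (length(grid) == 0L) {
    abort("empty configuration grid", class = "crnntfbs_input_error")
  }
  purrr::walk(grid, validate_crnn_config)
  models <- purrr::imap(grid, function(cfg, i) {
    if (!quiet) inform(sprintf("training configuration %d/%d", i, length(grid)))
    train(build_model(cfg), train_set, val_set, quiet = TRUE)
  })
  tab <- tibble(
    config_id = seq_along(grid),
    n_params = vapply(models, `[[`, integer(1), "n_params"),
    seed = vapply(grid, `[[`, integer(1), "seed"),
    validation_auc = vapply(models, `[[`, numeric(1), "validation_auc"),
    config = grid
  )
  ord <- order(-tab$validation_auc, tab$n_params, tab$seed)
  structure(list(table = tab, best_config = grid[[ord[1L]]],
                 best_model = models[[ord[1L]]], models = models),
            class = "crnn_grid_search")
}

#' @export
print.crnn_grid_search <- function(x, ...) {
  cat(sprintf("<crnn_grid_search> %d configurations\n", nrow(x$table)))
  print(arrange(select(x$table, -"config"), desc(.data$validation_auc)))
  invisible(x)
}

#' Repeated-split consistency check of one configuration
#'
#' Retrains the same configuration across `repeats` fresh
#' train/validation/test splits (seeded `base_seed + i`) and records the
#' held-out test ROC-AUC of each run, summarising mean, standard deviation
#' and range — the standard guard against a lucky split.
#'
#' @param config A [crnn_config()].
#' @param dataset A labelled dataset tibble (paired positives/negatives).
#' @param repeats Number of reruns (>= 2).
#' @param ratios Train/validation/test ratios.
#' @param base_seed Base seed; run `i` uses `base_seed + i`.
#' @param quiet Suppress progress messages.
#' @return A list of class `crnn_consistency`: `runs` (tibble with `run`,
#'   `seed`, `test_auc`) and `summary` (mean, sd, min, max).
#' @export
consistency_check <- function(config, dataset, repeats = 100L,
                              ratios = c(0.70, 0.15, 0.15), base_seed = 1L,
                              quiet = TRUE) {
  if (repeats < 2L) {
    abort("repeats must be >= 2", class = "crnntfbs_input_error")
  }
  aucs <- vapply(seq_len(repeats), function(i) {
    seed_i <- as.integer(base_seed + i)
    parts <- split_dataset(dataset, ratios, seed = seed_i)
    cfg <- config
    cfg$seed <- seed_i
    m <- train(build_model(cfg), parts$train, parts$validation)
    te <- prepare_xy(parts$test, cfg$input_length, "test")
    p <- predict_prob(m$params, cfg, te$X)
    a <- roc_auc(p[te$y == 1], p[te$y == 0])$auc
    if (!quiet) inform(sprintf("run %d/%d: test AUC %.4f", i, repeats, a))
    a
  }, numeric(1))
  structure(list(
    runs = tibble(run = seq_len(repeats),
                  seed = as.integer(base_seed + seq_len(repeats)),
                  test_auc = aucs),
    summary = tibble(mean_auc = mean(aucs), sd_auc = sd(aucs),
                     min_auc = min(aucs), max_auc = max(aucs),
                     repeats = repeats)
  ), class = "crnn_consistency")
}

#' @export
print.crnn_consistency <- function(x, ...) {
  cat(sprintf("<crnn_consistency> %d runs: mean AUC %.4f (sd %.4f, range %.4f-%.4f)\n",
              x$summary$repeats, x$summary$mean_auc, x$summary$sd_auc,
              x$summary$min_auc, x$summary$max_auc))
  invisible(x)
}

MODEL_FORMAT_VERSION <- 1L

#' Save a model to a directory
#'
#' Writes a human-readable `config.json` (with a format version), a
#' full-precision `params.json` parameter store and, when present, the
#' training history as `history.tsv`.
#'
#' @param model A `crnn_model`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "crnn_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format_version = MODEL_FORMAT_VERSION,
    package = "crnntfbs",
    config = unclass(model$config),
    n_params = model$n_params,
    trained = model$trained,
    validation_auc = model$validation_auc,
    best_epoch = model$best_epoch %||% NA_integer_
  )
  jsonlite::write_json(meta, file.path(path, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  flat <- flatten_params(model$params)
  jsonlite::write_json(flat, file.path(path, "params.json"), digits = NA)
  if (!is.null(model$history)) {
    readr::write_tsv(model$history, file.path(path, "history.tsv"),
                     progress = FALSE)
  }
  invisible(path)
}

flatten_params <- function(p, prefix = character()) {
  out <- list()
  for (nm in names(p)) {
    key <- paste(c(prefix, nm), collapse = ".")
    x <- p[[nm]]
    if (is.list(x)) {
      out <- c(out, flatten_params(x, c(prefix, nm)))
    } else {
      out[[key]] <- list(dim = dim(x) %||% length(x), values = as.numeric(x))
    }
  }
  out
}

unflatten_params <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    v <- flat[[key]]
    dims <- unlist(v$dim)
    vals <- unlist(v$values)
    x <- if (length(dims) == 2L) matrix(vals, dims[1L], dims[2L]) else vals
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) out[[parts]] <- x else out[[parts[1L]]][[parts[2L]]] <- x
  }
  out
}

#' Load a model saved by [save_model()]
#'
#' @param path Model directory.
#' @return A `crnn_model` whose predictions reproduce the saved model's.
#' @export
load_model <- function(path) {
  cfg_file <- file.path(path, "config.json")
  par_file <- file.path(path, "params.json")
  if (!file.exists(cfg_file) || !file.exists(par_file)) {
    abort("not a model directory (config.json / params.json missing)",
          class = "crnntfbs_incompatible_model")
  }
  meta <- tryCatch(jsonlite::read_json(cfg_file),
                   error = function(e) abort(
                     "unreadable model metadata", parent = e,
                     class = "crnntfbs_incompatible_model"))
  if (!identical(as.integer(meta$format_version), MODEL_FORMAT_VERSION)) {
    abort(sprintf("model format version %s is not supported (expected %d)",
                  meta$format_version %||% "<missing>", MODEL_FORMAT_VERSION),
          class = "crnntfbs_incompatible_model")
  }
  flat <- tryCatch(jsonlite::read_json(par_file),
                   error = function(e) abort(
                     "corrupt or truncated parameter file", parent = e,
                     class = "crnntfbs_incompatible_model"))
  cfg <- meta$config
  cfg[c("use_conv", "bidirectional")] <-
    lapply(cfg[c("use_conv", "bidirectional")], isTRUE)
  config <- do.call(crnn_config, cfg)
  params <- unflatten_params(flat)
  hist_file <- file.path(path, "history.tsv")
  history <- if (file.exists(hist_file)) {
    readr::read_tsv(hist_file, show_col_types = FALSE, progress = FALSE)
  }
  structure(
    list(config = config, params = params, n_params = count_params(params),
         trained = isTRUE(meta$trained), history = history,
         validation_auc = as.numeric(meta$validation_auc %||% NA),
         best_epoch = meta$best_epoch),
    class = "crnn_model"
  )
}
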