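#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a fitted model
#'
#' @param x A trained `crnn_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`, `val_auc`.
#' @export
tidy.crnn_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(epoch = integer(), train_loss = double(),
                  val_loss = double(), val_auc = double()))
  }
  as_tibble(x$history)
}

#' One-row summary of a fitted model
#'
#' @param x A `crnn_model`.
#' @param ... Unused.
#' @return Tibble with `n_params`, `trained`, `epochs_trained`,
#'   `best_epoch`, `validation_auc`.
#' @export
glance.crnn_model <- function(x, ...) {
  tibble(
    n_params = x$n_params,
    trained = x$trained,
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    validation_auc = x$validation_auc
  )
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
tidy.binned_auc_result <- function(x, ...) x$bins

#' @export
glance.binned_auc_result <- function(x, ...) {
  tibble(n_bins = nrow(x$bins), repeats = x$repeats,
         n_neg_per_repeat = x$n_neg_per_repeat,
         overall_mean_auc = mean(x$bins$mean_auc))
}

#' @export
tidy.crnn_grid_search <- function(x, ...) select(x$table, -"config")

#' @export
tidy.crnn_consistency <- function(x, ...) x$runs

#' @export
glance.crnn_consistency <- function(x, ...) x$summary
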