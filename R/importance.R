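#' Random-forest hyperparameter importance
#'
#' Regresses inner-validation accuracy on the hyperparameter values of a
#' search table with a random forest and reports the impurity-decrease
#' importance of each hyperparameter.  The categorical menu (activation) is
#' one-hot encoded for the forest and its per-level importances are summed
#' back into the parent hyperparameter; numeric menus stay numeric.  Rows
#' with missing accuracy (diverged runs) are dropped.
#'
#' @param search a `search_result` (or any data frame with the hyperparameter
#'   columns and an `accuracy` column).
#' @param n_trees number of trees (default 500).
#' @param seed integer seed; the report is bitwise reproducible given it.
#' @param min_rows minimum usable rows required (default 20).
#' @return an `importance_report` tibble: `hyperparameter`, `importance`
#'   (mean impurity decrease), `rank` (descending by importance), with
#'   attributes `n_trees`, `seed`, `n_rows`.
#' @export
rf_importance <- function(search, n_trees = 500, seed = 1, min_rows = 20) {
  hp <- names(cnn_hyper_grid())
  stopifnot(all(hp %in% names(search)), "accuracy" %in% names(search))
  tab <- search[!is.na(search$accuracy), c(hp, "accuracy")]
  if (nrow(tab) < min_rows) {
    stop(sprintf("need >= %d non-missing rows, have %d", min_rows, nrow(tab)),
         call. = FALSE)
  }
  if (sd(tab$accuracy) == 0) stop("all accuracies equal; degenerate target", call. = FALSE)
  # canonical row order makes the report invariant to input row order
  tab <- tab[do.call(order, as.list(tab)), ]
  act <- factor(tab$activation, levels = cnn_hyper_grid()$activation)
  onehot <- stats::model.matrix(~ act - 1)
  colnames(onehot) <- paste0("activation.", levels(act))
  Xnum <- as.matrix(tab[setdiff(hp, "activation")])
  X <- cbind(onehot, Xnum)
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = tab$accuracy, ntree = n_trees)
  imp <- randomForest::importance(rf)[, "IncNodePurity"]
  parent <- ifelse(startsWith(names(imp), "activation."), "activation", names(imp))
  agg <- tapply(imp, parent, sum)
  out <- tibble::tibble(hyperparameter = names(agg),
                        importance = as.numeric(agg)) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("importance_report", class(out))
  attr(out, "n_trees") <- n_trees
  attr(out, "seed") <- seed
  attr(out, "n_rows") <- nrow(tab)
  out
}

#' Permutation-null threshold for importance scores
#'
#' Refits the forest `n_perm` times on accuracy values permuted against the
#' hyperparameters and returns the chosen quantile of the maximum
#' per-hyperparameter importance under the null — a yardstick for judging
#' whether an observed importance is distinguishable from noise.
#'
#' @inheritParams rf_importance
#' @param n_perm number of permutations (default 20).
#' @param probs quantile of the null max-importance (default 0.95).
#' @return numeric threshold.
#' @export
rf_importance_null <- function(search, n_trees = 200, n_perm = 20,
                               probs = 0.95, seed = 1) {
  tab <- search[!is.na(search$accuracy), ]
  maxes <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + b)
    perm <- tab
    perm$accuracy <- sample(perm$accuracy)
    rep <- rf_importance(perm, n_trees = n_trees, seed = seed + b,
                         min_rows = min(20, nrow(tab)))
    maxes[b] <- max(rep$importance)
  }
  as.numeric(stats::quantile(maxes, probs))
}

#' @export
autoplot.importance_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$importance,
                               stats::reorder(.data$hyperparameter,
                                              .data$importance))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "importance (mean impurity decrease)", y = NULL) +
    ggplot2::theme_minimal()
}
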