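#' Random hyperparameter search for the CNN
#'
#' Samples `budget` hyperparameter points uniformly without replacement from
#' the full grid (see [cnn_hyper_grid()]); when `budget` equals the grid size
#' the search is exhaustive.  Each point is trained on a fixed inner 80/20
#' split of the training set and scored by the Pearson correlation between
#' its predictions and the inner-validation phenotypes.  Points are sampled,
#' and the inner split drawn, before any training, from seeds derived from
#' `seed` — so the sampled set does not depend on how points are evaluated,
#' and each point's accuracy does not depend on evaluation order (point `i`
#' trains with seed `seed + i`).
#'
#' Diverged runs (non-finite loss) score `NA` and are excluded from the
#' best-point selection; their count is reported.  Ties on accuracy are
#' broken by fewer parameters, then by earlier sampling.
#'
#' @param X encoded genotype matrix of the training set (see
#'   [encode_input()]).
#' @param y phenotypes aligned to `X` rows.
#' @param budget number of points to evaluate.
#' @param inner_frac fraction of the training set held out for inner
#'   validation (default 0.2).
#' @param epochs,batch training settings passed to [train_predict_cnn()].
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed.
#' @param grid the menu list (defaults to the full grid).
#' @return a `search_result` tibble: one row per point (all hyperparameter
#'   columns, `accuracy`, `epochs_used`, `n_params`, `diverged`, `order`),
#'   with attributes `best_point`, `best_accuracy`, `n_diverged`,
#'   `inner_split`.
#' @export
search_hyperparams <- function(X, y, budget = 20, inner_frac = 0.2,
                               epochs = 30, batch = 32, patience = 10,
                               seed = 1, grid = cnn_hyper_grid()) {
  stopifnot(budget >= 1, nrow(X) == length(y))
  gs <- grid_size(grid)
  if (budget > gs) stop("budget exceeds grid size", call. = FALSE)
  set.seed(seed)
  sampled <- sample.int(gs, budget)          # points first,
  n <- nrow(X)
  val_idx <- sort(sample.int(n, max(1, round(inner_frac * n))))  # then split
  tr_idx <- setdiff(seq_len(n), val_idx)
  points <- lapply(sampled, decode_point, grid = grid)
  rows <- vector("list", budget)
  for (i in seq_len(budget)) {
    pt <- points[[i]]
    arch <- build_cnn(pt, ncol(X), seed = seed + i)
    pred <- train_predict_cnn(arch, X[tr_idx, , drop = FALSE], y[tr_idx],
                              X[val_idx, , drop = FALSE],
                              epochs = epochs, batch = batch, seed = seed + i,
                              monitor = list(X = X[val_idx, , drop = FALSE],
                                             y = y[val_idx]),
                              patience = patience)
    acc <- if (attr(pred, "diverged") || sd(pred) == 0 || !all(is.finite(pred))) {
      NA_real_
    } else {
      cor(y[val_idx], as.vector(pred))
    }
    rows[[i]] <- tibble::tibble(
      !!!pt, accuracy = acc,
      epochs_used = attr(pred, "epochs_used"),
      n_params = arch$n_params,
      diverged = attr(pred, "diverged"),
      order = i
    )
  }
  tab <- dplyr::bind_rows(rows)
  if (all(is.na(tab$accuracy))) stop("all search points diverged", call. = FALSE)
  ranked <- tab |>
    dplyr::filter(!is.na(.data$accuracy)) |>
    dplyr::arrange(dplyr::desc(.data$accuracy), .data$n_params, .data$order)
  best_row <- ranked[1, ]
  out <- tab
  class(out) <- c("search_result", class(out))
  attr(out, "best_point") <- points[[best_row$order]]
  attr(out, "best_accuracy") <- best_row$accuracy
  attr(out, "n_diverged") <- sum(tab$diverged)
  attr(out, "inner_split") <- list(train = tr_idx, valid = val_idx)
  attr(out, "ranking") <- ranked$order
  attr(out, "points") <- points
  attr(out, "seed") <- seed
  out
}

#' Fit the best searched CNN and predict a validation panel
#'
#' Re-trains the winning point of a [search_hyperparams()] run (reusing the
#' seed under which it was scored, so its training trajectory is reproduced)
#' and predicts the supplied panel.  If the winner's predictions degenerate
#' (divergence or zero variance), the next-ranked point is tried, and so on.
#'
#' @param search a `search_result`.
#' @param X,y full training encodings / phenotypes used in the search.
#' @param X_new encoded panel to predict.
#' @inheritParams search_hyperparams
#' @return numeric predictions for `X_new`, with attribute `point_used`
#'   (the rank-order index of the point that produced them).
#' @export
predict_best_cnn <- function(search, X, y, X_new, epochs = 30, batch = 32,
                             patience = 10, seed = NULL) {
  split <- attr(search, "inner_split")
  points <- attr(search, "points")
  base_seed <- seed %||% attr(search, "seed")
  for (cand in attr(search, "ranking")) {
    pt <- points[[cand]]
    arch <- build_cnn(pt, ncol(X), seed = base_seed + cand)
    pred <- train_predict_cnn(arch, X[split$train, , drop = FALSE],
                              y[split$train],
                              X_new, epochs = epochs, batch = batch,
                              seed = base_seed + cand,
                              monitor = list(X = X[split$valid, , drop = FALSE],
                                             y = y[split$valid]),
                              patience = patience)
    if (!attr(pred, "diverged") && all(is.finite(pred)) && sd(pred) > 0) {
      attr(pred, "point_used") <- cand
      return(pred)
    }
  }
  stop("no searched configuration produced usable predictions", call. = FALSE)
}

#' @export
autoplot.search_result <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$accuracy))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$n_filters), .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$activation),
                         width = 0.15, alpha = 0.8) +
    ggplot2::labs(x = "convolution filters", y = "inner-validation accuracy") +
    ggplot2::theme_minimal()
}
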