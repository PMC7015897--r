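#' Train/validation split plans
#'
#' Two strategies mirror common breeding-program designs: `by_label` places
#' every individual whose label (e.g. trial code) is in `param` into the
#' validation set; `random_fraction` samples `param` of the ids into
#' validation.  Deterministic given `seed`; training and validation are
#' disjoint and jointly exhaustive.
#'
#' @param ids character vector of individual ids.
#' @param strategy `"random_fraction"` or `"by_label"`.
#' @param param validation fraction in (0, 1), or the label set to validate.
#' @param seed integer seed (used by `random_fraction`).
#' @param labels label per id (required for `by_label`).
#' @return a `split_plan`: list with `training`, `validation`, `strategy`,
#'   `param`, `seed`.
#' @export
split_data <- function(ids, strategy = c("random_fraction", "by_label"),
                       param = 0.3, seed = 1, labels = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "random_fraction") {
    if (param <= 0 || param >= 1) stop("fraction must be in (0, 1)", call. = FALSE)
    set.seed(seed)
    nv <- round(param * length(ids))
    if (nv == 0 || nv == length(ids)) stop("split leaves one side empty", call. = FALSE)
    validation <- sort(sample(ids, nv))
  } else {
    if (is.null(labels) || length(labels) != length(ids)) {
      stop("by_label requires one label per id", call. = FALSE)
    }
    validation <- ids[labels %in% param]
    if (length(validation) == 0 || length(validation) == length(ids)) {
      stop("split leaves one side empty", call. = FALSE)
    }
  }
  structure(list(training = setdiff(ids, validation), validation = validation,
                 strategy = strategy, param = param, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s: %d training / %d validation\n",
              x$strategy, length(x$training), length(x$validation)))
  invisible(x)
}

#' Predictive ability
#'
#' Pearson correlation between observed and predicted phenotypes in a
#' validation set.  Zero-variance input is an error (never a silent 0).
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
predictive_ability <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3) {
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  }
  if (anyNA(predicted) || anyNA(observed)) {
    stop("missing values in observed/predicted", call. = FALSE)
  }
  if (sd(observed) == 0 || sd(predicted) == 0) {
    stop("zero-variance input; predictive ability undefined", call. = FALSE)
  }
  cor(observed, predicted)
}

#' Simulation-study settings
#'
#' Bundles every knob of [run_simulation_study()].  Defaults are the reduced
#' desk scale (n = 600, p = 2000, diploid, five replicates per architecture,
#' 2000-cycle chains with 500 burn-in, CNN search budget 20); the full-size
#' chain (6000/1000) can be requested explicitly.
#'
#' @param n,p,ploidy panel dimensions and ploidy.
#' @param architectures subset of `c("additive", "epistatic", "mixed")`.
#' @param replicates replicates per architecture.
#' @param methods subset of `c("BRR", "BL", "BRR-GM", "RKHS", "CNN")`; the
#'   CNN is optional so the Bayesian-only study runs in minutes.
#' @param target_H2 broad-sense heritability of the simulated traits.
#' @param maf_range,ld_block_size passed to [simulate_genotypes()].
#' @param validation_fraction random validation fraction.
#' @param n_iter,burn_in Gibbs chain settings for all Bayesian fits.
#' @param rkhs_bandwidths grid from which the Gaussian-kernel bandwidth is
#'   chosen by inner-training validation.
#' @param cnn_budget,cnn_epochs,cnn_batch CNN search settings.
#' @param base_seed replicate `r` of architecture `a` uses seed
#'   `base_seed + r` (the same genotype panel is reused across
#'   architectures, as when architectures are simulated on one real panel).
#' @return a `study_config` list.
#' @export
study_config <- function(n = 600, p = 2000, ploidy = 2,
                         architectures = c("additive", "epistatic", "mixed"),
                         replicates = 5,
                         methods = c("BRR", "BRR-GM", "RKHS"),
                         target_H2 = 0.5, maf_range = c(0.05, 0.5),
                         ld_block_size = 10, validation_fraction = 0.3,
                         n_iter = 2000, burn_in = 500,
                         rkhs_bandwidths = c(0.1, 0.5, 1, 2.5),
                         cnn_budget = 20, cnn_epochs = 30, cnn_batch = 32,
                         base_seed = 101) {
  methods <- match.arg(methods, c("BRR", "BL", "BRR-GM", "RKHS", "CNN"),
                       several.ok = TRUE)
  architectures <- match.arg(architectures,
                             c("additive", "epistatic", "mixed"),
                             several.ok = TRUE)
  structure(as.list(environment()), class = "study_config")
}

# Fit one method on training phenotypes only and predict the validation ids.
# y_train is named by training id; validation phenotypes never enter.
predict_method <- function(method, genotypes, y_train, split, cfg,
                           seed = cfg$base_seed) {
  ids <- individual_ids(genotypes)
  tr <- match(split$training, ids)
  va <- match(split$validation, ids)
  y_train <- y_train[split$training]
  gcfg <- gibbs_config(n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                       seed = seed)
  if (method %in% c("BRR", "BL")) {
    Z <- additive_design(genotypes)
    fit <- if (method == "BRR") {
      fit_brr(Z[tr, , drop = FALSE], y_train, gcfg)
    } else {
      fit_bl(Z[tr, , drop = FALSE], y_train, gcfg)
    }
    return(predict(fit, Z[va, , drop = FALSE]))
  }
  if (method == "BRR-GM") {
    Om <- dosage_dummy_matrix(genotypes)
    fit <- fit_brr(Om[tr, , drop = FALSE], y_train, gcfg)
    fit$model <- "BRR-GM"
    return(predict(fit, Om[va, , drop = FALSE]))
  }
  if (method == "RKHS") {
    h <- choose_bandwidth(genotypes, y_train, tr, cfg, gcfg)
    K <- gaussian_kernel(genotypes, h = h)
    fit <- fit_rkhs(subset_kernel(K, tr, tr), y_train, gcfg)
    return(predict(fit, subset_kernel(K, va, tr)))
  }
  if (method == "CNN") {
    X <- encode_input(genotypes)
    search <- search_hyperparams(X[tr, , drop = FALSE], y_train,
                                 budget = cfg$cnn_budget,
                                 epochs = cfg$cnn_epochs,
                                 batch = cfg$cnn_batch, seed = seed)
    pred <- predict_best_cnn(search, X[tr, , drop = FALSE], y_train,
                             X[va, , drop = FALSE],
                             epochs = cfg$cnn_epochs, batch = cfg$cnn_batch,
                             seed = seed)
    return(stats::setNames(as.vector(pred), split$validation))
  }
  stop("unknown method: ", method, call. = FALSE)
}

subset_kernel <- function(K, i, j) {
  M <- unclass(K)[i, j, drop = FALSE]
  if (identical(i, j)) {
    return(kernel_matrix(M, attr(K, "kind"), attr(K, "denominator")))
  }
  M
}

# pick the Gaussian bandwidth by an inner 80/20 validation within training
choose_bandwidth <- function(genotypes, y_train, tr, cfg, gcfg) {
  hs <- cfg$rkhs_bandwidths
  if (length(hs) == 1) return(hs)
  set.seed(gcfg$seed)
  n_tr <- length(tr)
  inner_va <- sort(sample.int(n_tr, max(3, round(0.2 * n_tr))))
  inner_tr <- setdiff(seq_len(n_tr), inner_va)
  short <- gibbs_config(n_iter = max(600, cfg$n_iter %/% 2),
                        burn_in = max(150, cfg$burn_in %/% 2),
                        seed = gcfg$seed)
  pas <- vapply(hs, function(h) {
    K <- gaussian_kernel(genotypes[tr, seq_len(ncol(genotypes$dosages))], h = h)
    fit <- fit_rkhs(subset_kernel(K, inner_tr, inner_tr), y_train[inner_tr], short)
    pred <- predict(fit, subset_kernel(K, inner_va, inner_tr))
    tryCatch(predictive_ability(y_train[inner_va], pred),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(pas))) return(hs[1])
  hs[which.max(pas)]
}

#' Run the replicated simulation study
#'
#' End-to-end driver: for each architecture and replicate it simulates a
#' genotype panel and trait at the target heritability, splits the
#' individuals, estimates the additive/dominance/epistatic variance ratios
#' with the multi-kernel model on the combined data (a descriptive stage —
#' those estimates feed nothing downstream), fits every requested method on
#' training phenotypes only, and records validation predictive ability.
#' A failing method is recorded as `NA` for that cell and the study
#' continues.
#'
#' @param config a [study_config()].
#' @return a `study_result` tibble with columns `replicate`, `architecture`,
#'   `method`, `h2_a`, `h2_d`, `h2_e`, `pa`, plus the config in attribute
#'   `config`.
#' @export
run_simulation_study <- function(config = study_config()) {
  cfg <- config
  rows <- list()
  for (arch_kind in cfg$architectures) {
    for (r in seq_len(cfg$replicates)) {
      seed_r <- cfg$base_seed + r
      rep <- simulate_replicate(cfg$n, cfg$p, cfg$ploidy, arch_kind,
                                cfg$target_H2, cfg$maf_range,
                                cfg$ld_block_size, seed = seed_r)
      geno <- rep$genotypes
      y <- rep$trait$phenotypes
      ids <- individual_ids(geno)
      names(y) <- ids
      split <- split_data(ids, "random_fraction", cfg$validation_fraction,
                          seed = seed_r)
      A <- additive_kernel(geno)
      D <- if (cfg$ploidy == 2) dominance_kernel_diploid(geno)
           else dominance_kernel_tetraploid(geno)
      E <- epistasis_kernel(A)
      gcfg <- gibbs_config(n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                           seed = seed_r)
      mk <- fit_multikernel(list(a = A, d = D, e = E), y, gcfg)
      h2 <- stats::setNames(mk$decomposition$summary$mean,
                            mk$decomposition$summary$component)
      for (method in cfg$methods) {
        pa <- tryCatch({
          pred <- predict_method(method, geno, y[split$training], split, cfg,
                                 seed = seed_r)
          predictive_ability(y[split$validation], pred[split$validation])
        }, error = function(e) {
          warning(sprintf("replicate %d %s %s failed: %s",
                          r, arch_kind, method, conditionMessage(e)))
          NA_real_
        })
        rows[[length(rows) + 1]] <- tibble::tibble(
          replicate = r, architecture = arch_kind, method = method,
          h2_a = h2[["a"]], h2_d = h2[["d"]], h2_e = h2[["e"]], pa = pa
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("study_result", class(out))
  attr(out, "config") <- cfg
  out
}

#' @export
autoplot.study_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$method, .data$pa, colour = .data$method)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1) +
    ggplot2::facet_wrap(~architecture) +
    ggplot2::labs(x = NULL, y = "predictive ability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Summarize a study by architecture and method
#'
#' @param object a `study_result`.
#' @param ... unused.
#' @return tibble of mean/sd predictive ability and mean variance ratios.
#' @export
summary.study_result <- function(object, ...) {
  object |>
    dplyr::group_by(.data$architecture, .data$method) |>
    dplyr::summarise(
      mean_pa = mean(.data$pa, na.rm = TRUE),
      sd_pa = sd(.data$pa, na.rm = TRUE),
      mean_h2_a = mean(.data$h2_a), mean_h2_d = mean(.data$h2_d),
      mean_h2_e = mean(.data$h2_e),
      .groups = "drop"
    )
}
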