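#' Model configuration
#'
#' Bundles the regression settings used throughout the modelling stage.
#' Defaults follow common practice for this kind of trait-estimation work:
#' an eps-regression SVM with Gaussian (RBF) kernel, `C = 20`,
#' `gamma = 0.02` (a polynomial kernel is selectable); a random forest of
#' 100 CART trees; and a single-hidden-layer back-propagation network with
#' 10 sigmoid units. Stochastic learners are refit `n_repeats` times with
#' distinct seeds and their predictions averaged.
#'
#' @param svm_kernel `"radial"` (Gaussian, default) or `"polynomial"`.
#' @param svm_cost,svm_gamma SVM regularisation and kernel width.
#' @param rf_trees number of trees (default 100).
#' @param bpnn_size hidden units (default 10).
#' @param bpnn_maxit optimisation iteration cap (default 500).
#' @param bpnn_decay weight decay (default 1e-4).
#' @param n_repeats stochastic-refit count whose predictions are averaged
#'   (default 10).
#' @param split_seed seed controlling which member of each sorted block
#'   goes to validation, see [split_dataset()].
#' @param seed base seed for per-repeat model initialisation.
#' @return a `model_config` list.
#' @export
model_config <- function(svm_kernel = c("radial", "polynomial"),
                         svm_cost = 20, svm_gamma = 0.02,
                         rf_trees = 100,
                         bpnn_size = 10, bpnn_maxit = 500, bpnn_decay = 1e-4,
                         n_repeats = 10, split_seed = 1, seed = 42) {
  svm_kernel <- match.arg(svm_kernel)
  stopifnot(svm_cost > 0, svm_gamma > 0, rf_trees >= 1, n_repeats >= 1,
            bpnn_size >= 1)
  structure(
    list(svm_kernel = svm_kernel, svm_cost = svm_cost, svm_gamma = svm_gamma,
         rf_trees = as.integer(rf_trees), bpnn_size = as.integer(bpnn_size),
         bpnn_maxit = as.integer(bpnn_maxit), bpnn_decay = bpnn_decay,
         n_repeats = as.integer(n_repeats),
         split_seed = as.integer(split_seed), seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Deterministic target-stratified 2:1 split
#'
#' Sorts samples by the target and, within each consecutive block of three,
#' assigns one member to the validation set (the block position is selected
#' by `split_seed %% 3`; the default picks the middle member, so both
#' splits span the occupied trait range and the global extremes stay in the
#' modelling set). Leftover samples of an incomplete final block go to the
#' modelling set. With n = 60 this yields 40 modelling and 20 validation
#' samples.
#'
#' @param n number of samples (>= 6).
#' @param target numeric trait vector of length `n`.
#' @param split_seed integer seed; only `split_seed %% 3` matters.
#' @return list with integer index vectors `modeling` and `validation`.
#' @export
split_dataset <- function(n, target, split_seed = 1) {
  if (n < 6) stop("need at least 6 samples for a 2:1 split")
  if (length(target) != n) stop("target length must equal n")
  ord <- order(target, seq_len(n))
  pos <- (split_seed %% 3) + 1
  block <- (seq_len(n) - 1) %/% 3
  in_block <- (seq_len(n) - 1) %% 3 + 1
  complete <- block < (n %/% 3)
  val_sorted <- which(complete & in_block == pos)
  validation <- sort(ord[val_sorted])
  list(modeling = setdiff(seq_len(n), validation), validation = validation)
}

#' Fit one model with repeated-run averaging and predict both splits
#'
#' Features are z-scored using modelling-set statistics for the SVM and the
#' neural network (the network's target is also standardised and
#' back-transformed); the random forest sees raw features. Stochastic
#' learners (RF, BPNN) are refit `n_repeats` times under seeds
#' `seed + 1 .. seed + n_repeats` and the per-sample predictions averaged;
#' the SVM fit is deterministic so a single fit is used. Everything is
#' reproducible bit-for-bit under a fixed config.
#'
#' @param model `"svm"`, `"rf"` or `"bpnn"`.
#' @param x_model,y_model modelling-set feature matrix and target.
#' @param x_valid validation-set feature matrix.
#' @param config a [model_config()].
#' @return list with numeric vectors `pred_model` and `pred_valid`.
#' @export
fit_predict <- function(model = c("svm", "rf", "bpnn"),
                        x_model, y_model, x_valid, config = model_config()) {
  model <- match.arg(model)
  x_model <- as.matrix(x_model); x_valid <- as.matrix(x_valid)
  if (any(!is.finite(x_model)) || any(!is.finite(x_valid))) {
    stop("non-finite feature values")
  }
  if (any(!is.finite(y_model))) stop("non-finite target values")

  if (model %in% c("svm", "bpnn")) {
    mu <- colMeans(x_model)
    sdv <- apply(x_model, 2, stats::sd)
    sdv[sdv == 0] <- 1
    x_model <- sweep(sweep(x_model, 2, mu), 2, sdv, "/")
    x_valid <- sweep(sweep(x_valid, 2, mu), 2, sdv, "/")
  }

  one_fit <- function(rep_seed) {
    set.seed(rep_seed)
    switch(model,
      svm = {
        fit <- e1071::svm(x = x_model, y = y_model, type = "eps-regression",
                          kernel = config$svm_kernel, cost = config$svm_cost,
                          gamma = config$svm_gamma, scale = FALSE)
        list(m = as.numeric(stats::predict(fit, x_model)),
             v = as.numeric(stats::predict(fit, x_valid)))
      },
      rf = {
        fit <- randomForest::randomForest(x = x_model, y = y_model,
                                          ntree = config$rf_trees)
        list(m = as.numeric(stats::predict(fit, x_model)),
             v = as.numeric(stats::predict(fit, x_valid)))
      },
      bpnn = {
        ym <- mean(y_model); ys <- stats::sd(y_model)
        if (ys == 0) ys <- 1
        fit <- nnet::nnet(x = x_model, y = (y_model - ym) / ys,
                          size = config$bpnn_size, linout = TRUE,
                          maxit = config$bpnn_maxit,
                          decay = config$bpnn_decay, trace = FALSE)
        list(m = as.numeric(stats::predict(fit, x_model)) * ys + ym,
             v = as.numeric(stats::predict(fit, x_valid)) * ys + ym)
      })
  }

  n_rep <- if (model == "svm") 1L else config$n_repeats
  fits <- lapply(seq_len(n_rep), function(r) one_fit(config$seed + r))
  list(
    pred_model = rowMeans(vapply(fits, `[[`, numeric(nrow(x_model)), "m")),
    pred_valid = rowMeans(vapply(fits, `[[`, numeric(nrow(x_valid)), "v"))
  )
}

#' Regression accuracy metrics
#'
#' `r2` is the coefficient of determination `1 - SS_res / SS_tot`, `rmse`
#' the root mean squared error in trait units, and `mre` the mean relative
#' error `(100/n) * sum(|y - yhat| / y)` in percent (requires positive
#' observed values). A zero-variance `y_true` leaves `r2` as `NA`.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return list with `r2`, `rmse`, `mre`.
#' @export
evaluate <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (any(y_true <= 0)) stop("y_true must be positive for MRE")
  ss_res <- sum((y_true - y_pred)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  list(
    r2 = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
    rmse = sqrt(mean((y_true - y_pred)^2)),
    mre = 100 * mean(abs(y_true - y_pred) / y_true)
  )
}

#' Run the full trait x combination x model evaluation grid
#'
#' For every trait, feature combination and model, splits the samples 2:1
#' ([split_dataset()]), fits with repeated-run averaging ([fit_predict()])
#' and evaluates both splits ([evaluate()]). The result is a tidy table
#' with one row per (trait, combination, model, split).
#'
#' @param selection output of [select_features()] (per-trait combinations
#'   and feature matrices).
#' @param config a [model_config()].
#' @param models subset of `c("svm", "rf", "bpnn")` to run.
#' @param combinations subset of combination names to run (default all
#'   four).
#' @return data.frame with columns `trait`, `combination`, `model`,
#'   `split`, `n`, `r2`, `rmse`, `mre`.
#' @export
run_experiment <- function(selection, config = model_config(),
                           models = c("svm", "rf", "bpnn"),
                           combinations = paste0("combination_", 1:4)) {
  rows <- list()
  for (trait in names(selection$traits)) {
    tr <- selection$traits[[trait]]
    y <- tr$target
    sp <- split_dataset(length(y), y, config$split_seed)
    for (combo in combinations) {
      members <- tr$combinations[[combo]]$feature
      X <- as.matrix(tr$feature_matrix[, members, drop = FALSE])
      for (model in models) {
        pred <- fit_predict(model, X[sp$modeling, , drop = FALSE],
                            y[sp$modeling], X[sp$validation, , drop = FALSE],
                            config)
        for (split in c("modeling", "validation")) {
          idx <- sp[[split]]
          p <- if (split == "modeling") pred$pred_model else pred$pred_valid
          met <- evaluate(y[idx], p)
          rows[[length(rows) + 1L]] <- data.frame(
            trait = trait, combination = combo, model = model,
            split = split, n = length(idx),
            r2 = met$r2, rmse = met$rmse, mre = met$mre,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
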