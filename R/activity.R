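#' @title Class-specific activity models
#' @description Random-forest regression of binding activity (-log M, i.e.
#'   pKi/pKd/pIC50) from Avalon fingerprint descriptors. Models are trained
#'   and assessed by repeated nested cross-validation: hyperparameters are
#'   selected in an inner CV loop strictly inside each outer training fold,
#'   so outer-fold test estimates never leak into model selection.
#' @name activity-models
NULL

#' Avalon fingerprint descriptor vector
#'
#' @param smiles A single SMILES string.
#' @param n_bits Fingerprint length (default 512).
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
featurize_avalon <- function(smiles, n_bits = 512L) {
  avalon_matrix(smiles, n_bits = n_bits)[1, ]
}

#' Avalon fingerprint matrix for a batch of molecules
#' @param smiles Character vector of SMILES.
#' @param n_bits Fingerprint length.
#' @return Integer 0/1 matrix, one row per molecule.
#' @export
avalon_matrix <- function(smiles, n_bits = 512L) {
  stopifnot(length(smiles) >= 1L, n_bits >= 16L)
  smi_file <- write_smiles_tmp(smiles)
  on.exit(unlink(smi_file), add = TRUE)
  recs <- chemtool_run(c("fp", "--in", shQuote(smi_file),
                         "--algorithms", "avalon",
                         "--nbits", paste0("avalon:", as.integer(n_bits))))
  bad <- Filter(function(r) !isTRUE(r$ok), recs)
  if (length(bad)) stop("Avalon featurization failed for molecule ",
                        bad[[1]]$i + 1L, ": ", bad[[1]]$error)
  m <- matrix(0L, length(smiles), n_bits)
  for (r in recs) m[r$i + 1L, unlist(r$fps$avalon$on) + 1L] <- 1L
  m
}

#' Default hyperparameter grid for the activity forests
#'
#' Trees in \{100, 300, 500\} crossed with mtry in \{sqrt(p), p/3, p\}.
#' @param p Number of descriptors.
#' @return data.frame with columns `num_trees`, `mtry`.
#' @export
activity_grid <- function(p = 512L) {
  expand.grid(num_trees = c(100L, 300L, 500L),
              mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), p))),
              KEEP.OUT.ATTRS = FALSE)
}

.fit_forest <- function(x, y, num_trees, mtry, seed) {
  df <- data.frame(y = y, x)
  ranger::ranger(y ~ ., data = df, num.trees = num_trees,
                 mtry = min(mtry, ncol(x)), seed = seed, num.threads = 1,
                 respect.unordered.factors = FALSE)
}

.predict_forest <- function(fit, x) {
  stats::predict(fit, data = data.frame(x), num.threads = 1)$predictions
}

.make_folds <- function(n, k) {
  # balanced fold assignment of a pre-shuffled index vector
  split(seq_len(n), rep_len(seq_len(k), n))
}

#' Pearson R and RMSE of predictions against observations
#'
#' @param pred,obs Equal-length numeric vectors (length >= 2).
#' @return Object of class `model_performance`: `pearson_r`, `rmse`
#'   (and NA standard deviations; see [nested_cv_train()] for aggregated
#'   performance over folds/repeats). `pearson_r` is NA with a warning when
#'   either vector has zero variance.
#' @export
evaluate_predictions <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 2L)
  rmse <- sqrt(mean((pred - obs)^2))
  r <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    warning("zero variance: Pearson R undefined")
    NA_real_
  } else {
    stats::cor(pred, obs)
  }
  structure(list(pearson_r = r, rmse = rmse,
                 r_sd = NA_real_, rmse_sd = NA_real_),
            class = "model_performance")
}

#' @export
print.model_performance <- function(x, ...) {
  fmt <- function(v, s) if (is.na(s)) sprintf("%.3f", v) else
    sprintf("%.3f +/- %.3f", v, s)
  cat(sprintf("R = %s, RMSE = %s (-log M)\n",
              fmt(x$pearson_r, x$r_sd), fmt(x$rmse, x$rmse_sd)))
  invisible(x)
}

#' Train a class-specific activity forest by repeated nested CV
#'
#' For each repeat, rows are shuffled and split into `outer_k` folds; inside
#' each outer training fold an `inner_k`-fold CV selects the grid point with
#' the lowest mean inner RMSE, a forest with that setting is fit on the full
#' outer training fold and evaluated on the held-out outer fold. Reported
#' performance is the mean and SD of outer-fold Pearson R and RMSE across
#' all folds and repeats; folds whose test labels have zero variance are
#' recorded as missing and excluded with a warning. The final model is refit
#' on all rows with the most frequently selected hyperparameters.
#'
#' @param data An `activity_dataset` (see [generate_activity_dataset()]) or
#'   a list with `features` (numeric matrix), `activity`, `class_label`.
#' @param outer_k,inner_k Fold counts (defaults 5 and 3).
#' @param grid Hyperparameter grid, default [activity_grid()].
#' @param repeats Number of nested-CV repeats (default 10).
#' @param seed Integer seed; repeat r uses `seed + r - 1`.
#' @return List with `model` (class `activity_model`), `performance`
#'   (class `model_performance` with SDs over folds/repeats), and `details`
#'   (one row per outer fold: repeat, fold, selected grid row).
#' @export
nested_cv_train <- function(data, outer_k = 5L, inner_k = 3L,
                            grid = NULL, repeats = 10L, seed = 1L) {
  x <- data$features
  y <- data$activity
  stopifnot(is.matrix(x), length(y) == nrow(x), nrow(x) >= outer_k)
  if (length(unique(y)) < 2L) stop("need >= 2 distinct activity values")
  if (is.null(grid)) grid <- activity_grid(ncol(x))
  stopifnot(nrow(grid) >= 1L)
  colnames(x) <- sprintf("b%04d", seq_len(ncol(x)))

  fold_r <- c(); fold_rmse <- c(); chosen <- integer(0)
  details <- list()
  dropped <- 0L
  for (rep_i in seq_len(repeats)) {
    set.seed(seed + rep_i - 1L)
    perm <- sample.int(nrow(x))
    outer_folds <- .make_folds(nrow(x), outer_k)
    for (fold_i in seq_along(outer_folds)) {
      of <- outer_folds[[fold_i]]
      test_idx <- perm[of]
      train_idx <- setdiff(perm, test_idx)
      # inner loop: select grid point on the outer-training rows only
      inner_folds <- .make_folds(length(train_idx), inner_k)
      inner_rmse <- vapply(seq_len(nrow(grid)), function(g) {
        errs <- vapply(inner_folds, function(inf) {
          val <- train_idx[inf]
          trn <- setdiff(train_idx, val)
          fit <- .fit_forest(x[trn, , drop = FALSE], y[trn],
                             grid$num_trees[g], grid$mtry[g],
                             seed = seed + rep_i)
          sqrt(mean((.predict_forest(fit, x[val, , drop = FALSE]) - y[val])^2))
        }, numeric(1))
        mean(errs)
      }, numeric(1))
      best <- which.min(inner_rmse)
      chosen <- c(chosen, best)
      details[[length(details) + 1L]] <- data.frame(
        repeat_i = rep_i, fold = fold_i, chosen_grid_row = best)
      fit <- .fit_forest(x[train_idx, , drop = FALSE], y[train_idx],
                         grid$num_trees[best], grid$mtry[best],
                         seed = seed + rep_i)
      pred <- .predict_forest(fit, x[test_idx, , drop = FALSE])
      fold_rmse <- c(fold_rmse, sqrt(mean((pred - y[test_idx])^2)))
      if (stats::sd(y[test_idx]) == 0 || stats::sd(pred) == 0) {
        dropped <- dropped + 1L
        fold_r <- c(fold_r, NA_real_)
      } else {
        fold_r <- c(fold_r, stats::cor(pred, y[test_idx]))
      }
    }
  }
  if (dropped > 0L) {
    warning(dropped, " outer fold(s) had zero-variance labels or predictions; ",
            "excluded from the R average")
  }
  final_idx <- as.integer(names(which.max(table(chosen))))
  final_fit <- .fit_forest(x, y, grid$num_trees[final_idx],
                           grid$mtry[final_idx], seed = seed)
  performance <- structure(list(
    pearson_r = mean(fold_r, na.rm = TRUE),
    rmse = mean(fold_rmse),
    r_sd = stats::sd(fold_r, na.rm = TRUE),
    rmse_sd = stats::sd(fold_rmse)), class = "model_performance")
  model <- structure(list(
    class_label = data$class_label,
    fit = final_fit,
    hyperparameters = grid[final_idx, , drop = FALSE],
    n_bits = ncol(x),
    training = list(seed = seed, outer_k = outer_k, inner_k = inner_k,
                    repeats = repeats, grid = grid, n = nrow(x))),
    class = "activity_model")
  list(model = model, performance = performance,
       details = do.call(rbind, details))
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("<activity_model [%s]: %d trees, mtry %d, %d descriptors>\n",
              x$class_label, x$hyperparameters$num_trees,
              x$hyperparameters$mtry, x$n_bits))
  invisible(x)
}

#' Predict binding activity (-log M) for molecules
#'
#' @param model An `activity_model` from [nested_cv_train()].
#' @param smiles Character vector of SMILES, or a precomputed 0/1 Avalon
#'   matrix with `model$n_bits` columns.
#' @return Numeric vector of predicted activities.
#' @export
predict_activity <- function(model, smiles) {
  stopifnot(inherits(model, "activity_model"))
  feats <- if (is.matrix(smiles)) smiles else
    avalon_matrix(smiles, n_bits = model$n_bits)
  if (ncol(feats) != model$n_bits) {
    stop("descriptor length mismatch: model expects ", model$n_bits, " bits")
  }
  colnames(feats) <- sprintf("b%04d", seq_len(ncol(feats)))
  out <- .predict_forest(model$fit, feats)
  if (!all(is.finite(out))) stop("non-finite activity prediction")
  out
}

#' Train one activity model per target class of a library
#'
#' Convenience wrapper: groups library entries by class, trains a nested-CV
#' forest per class on the co-crystal ligands' Avalon descriptors and
#' activities. Classes with too few entries or fewer than two distinct
#' activities are skipped with a warning.
#'
#' @param lib A `target_library`.
#' @param min_n Minimum entries per class (default 4).
#' @param n_bits Avalon length.
#' @param ... Passed to [nested_cv_train()] (e.g. `repeats`, `seed`).
#' @return Named list of `activity_model` objects (names = class labels).
#' @export
train_class_models <- function(lib, min_n = 4L, n_bits = 512L, ...) {
  cls <- vapply(lib$entries, function(e) e$target_class, character(1))
  out <- list()
  for (cl in unique(cls)) {
    entries <- lib$entries[cls == cl]
    act <- vapply(entries, function(e) e$activity, numeric(1))
    keep <- is.finite(act)
    if (sum(keep) < min_n || length(unique(act[keep])) < 2L) {
      warning("skipping class '", cl, "': insufficient activity data")
      next
    }
    smi <- vapply(entries[keep], function(e) e$cocrystal_smiles, character(1))
    ds <- list(features = avalon_matrix(smi, n_bits = n_bits),
               activity = act[keep], class_label = cl)
    out[[cl]] <- nested_cv_train(ds, ...)$model
  }
  out
}
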