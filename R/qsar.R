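# Per-target pIC50 regression on fingerprints, model evaluation, and
# applicability-domain filtering by residual percentile.

#' Convert IC50 (nM) to pIC50 and back
#'
#' `pIC50 = -log10(IC50 * 1e-9)`: the negative base-10 logarithm of the
#' molar IC50, so 1000 nM maps to 6 and 1 nM to 9. Strictly decreasing in
#' IC50. `pic50_to_ic50()` is the exact inverse, `10^(9 - pIC50)` nM.
#'
#' @param ic50_nm Positive IC50 values in nanomolar.
#' @param pic50 pIC50 values.
#' @return Numeric vector.
#' @examples
#' ic50_to_pic50(1000)  # 6
#' pic50_to_ic50(7.5)   # ~31.6 nM
#' @export
ic50_to_pic50 <- function(ic50_nm) {
  if (!is.numeric(ic50_nm) || length(ic50_nm) == 0L) {
    stop_domain("`ic50_nm` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(ic50_nm)) || any(ic50_nm <= 0)) {
    stop_domain("`ic50_nm` must be finite and strictly positive.")
  }
  -log10(ic50_nm * 1e-9)
}

#' @rdname ic50_to_pic50
#' @export
pic50_to_ic50 <- function(pic50) {
  if (!is.numeric(pic50) || any(!is.finite(pic50))) {
    stop_domain("`pic50` must be finite numeric.")
  }
  10^(9 - pic50)
}

#' Split records into training and test partitions
#'
#' Random disjoint partition covering all rows; the training size is
#' `round(n * train_fraction)`. Reproducible under a fixed seed.
#'
#' @param df Data frame of records.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(df, train_fraction = 0.8, seed = 1L) {
  check_number(train_fraction, "train_fraction", lower = 1e-12, upper = 1 - 1e-12)
  n <- nrow(df)
  if (is.null(n) || n < 2L) stop_domain("Need at least 2 records to split.")
  n_train <- round(n * train_fraction)
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- withr_seed(seed, sample.int(n, n_train))
  list(train = as_tibble(df[sort(idx), , drop = FALSE]),
       test = as_tibble(df[setdiff(seq_len(n), idx), , drop = FALSE]))
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Regression metrics
#'
#' Mean squared error, coefficient of determination, mean absolute error
#' and root mean squared error; `rmse == sqrt(mse)` by construction.
#'
#' @param truth,pred Numeric vectors of equal positive length.
#' @return One-row tibble with columns `mse`, `r2`, `mae`, `rmse`.
#' @export
regression_metrics <- function(truth, pred) {
  if (length(truth) == 0L || length(truth) != length(pred)) {
    stop_domain("`truth` and `pred` must be non-empty and of equal length.")
  }
  res <- truth - pred
  mse <- mean(res^2)
  ss_tot <- sum((truth - mean(truth))^2)
  tibble(
    mse = mse,
    r2 = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
    mae = mean(abs(res)),
    rmse = sqrt(mse)
  )
}

#' Train a per-target pIC50 random-forest regressor
#'
#' Fits a random-forest regression of pIC50 on circular fingerprint bits
#' for a single protein target, with k-fold cross-validation metrics
#' retained on the model. Constant-valued bits are dropped from the
#' feature matrix before fitting. The fit is deterministic under a fixed
#' seed (single-threaded forest).
#'
#' @param train Activity tibble with `id`, `canonical_smiles`, `target`,
#'   `pic50` columns (see [read_compound_table()]).
#' @param n_bits,radius Fingerprint parameters (see
#'   [compute_fingerprints()]).
#' @param num_trees Number of trees. Default 500.
#' @param k_folds Cross-validation folds. Default 5; must not exceed the
#'   number of training records. `0` skips cross-validation.
#' @param seed Integer seed.
#' @param fingerprints Optional precomputed fingerprint matrix (rows
#'   aligned with `train`); computed from `canonical_smiles` if omitted.
#' @return Object of class `qsar_model`: the fitted forest plus feature
#'   parameters, kept bit indices, per-fold CV metrics, training metrics,
#'   and the seed. Test metrics and the residual cutoff are attached later
#'   by [evaluate_model()] / [filter_applicability()].
#' @seealso [predict.qsar_model()], [glance.qsar_model()]
#' @export
train_qsar <- function(train, n_bits = 2048L, radius = 2L, num_trees = 500L,
                       k_folds = 5L, seed = 1L, fingerprints = NULL) {
  check_columns(train, c("target", "pic50"), "training table")
  targets <- unique(train$target)
  if (length(targets) != 1L) {
    stop_domain(sprintf(
      "Training records must share one target; got: %s. Fit one model per target.",
      paste(targets, collapse = ", ")
    ))
  }
  if (nrow(train) < k_folds) {
    stop_domain(sprintf("Need at least k_folds = %d records, got %d.", k_folds, nrow(train)))
  }
  if (any(!is.finite(train$pic50))) stop_domain("Non-finite pIC50 in training data.")
  if (is.null(fingerprints)) {
    fingerprints <- compute_fingerprints(train, n_bits = n_bits, radius = radius)
  }
  keep_bits <- which(apply(fingerprints, 2, function(x) length(unique(x)) > 1L))
  if (length(keep_bits) == 0L) keep_bits <- 1L  # degenerate: constant features
  x <- fingerprints[, keep_bits, drop = FALSE]
  colnames(x) <- paste0("b", keep_bits)
  dat <- as.data.frame(x)
  dat$.pic50 <- train$pic50

  fit_rf <- function(d, s) {
    ranger::ranger(
      dependent.variable.name = ".pic50", data = d,
      num.trees = num_trees, seed = s, num.threads = 1L,
      # regression convention (p/3 candidate features per split)
      mtry = max(1L, floor((ncol(d) - 1L) / 3)),
      respect.unordered.factors = "ignore"
    )
  }

  cv <- NULL
  if (k_folds >= 2L && nrow(dat) >= 2L * k_folds) {
    folds <- withr_seed(seed, sample(rep(seq_len(k_folds), length.out = nrow(dat))))
    cv <- purrr::map_dfr(seq_len(k_folds), function(f) {
      fit <- fit_rf(dat[folds != f, , drop = FALSE], seed + f)
      pred <- predict(fit, dat[folds == f, , drop = FALSE], num.threads = 1L)$predictions
      mutate(regression_metrics(dat$.pic50[folds == f], pred), fold = f, .before = 1)
    })
  }

  forest <- fit_rf(dat, seed)
  train_pred <- predict(forest, dat, num.threads = 1L)$predictions
  structure(
    list(
      target = targets,
      forest = forest,
      feature_params = list(n_bits = as.integer(n_bits), radius = as.integer(radius)),
      keep_bits = keep_bits,
      n_train = nrow(dat),
      seed = as.integer(seed),
      cv_metrics = cv,
      train_metrics = regression_metrics(train$pic50, train_pred),
      test_metrics = NULL,
      residual_cutoff = NULL
    ),
    class = "qsar_model"
  )
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model> target: %s | %d training records | %d active bits (of %d, radius %d)\n",
              x$target, x$n_train, length(x$keep_bits),
              x$feature_params$n_bits, x$feature_params$radius))
  cat(sprintf("  train: R2 = %.3f, RMSE = %.3f\n",
              x$train_metrics$r2, x$train_metrics$rmse))
  if (!is.null(x$cv_metrics)) {
    cat(sprintf("  %d-fold CV: mean R2 = %.3f, mean RMSE = %.3f\n",
                nrow(x$cv_metrics), mean(x$cv_metrics$r2), mean(x$cv_metrics$rmse)))
  }
  if (!is.null(x$test_metrics)) {
    cat(sprintf("  test: R2 = %.3f, RMSE = %.3f\n", x$test_metrics$r2, x$test_metrics$rmse))
  }
  if (!is.null(x$residual_cutoff)) {
    cat(sprintf("  applicability residual cutoff: %.4f\n", x$residual_cutoff))
  }
  invisible(x)
}

# Featurize a compound table with a model's fingerprint parameters and
# return the model's feature columns.
model_features <- function(model, df, fingerprints = NULL) {
  if (is.null(fingerprints)) {
    fingerprints <- compute_fingerprints(
      df, n_bits = model$feature_params$n_bits, radius = model$feature_params$radius
    )
  }
  x <- fingerprints[, model$keep_bits, drop = FALSE]
  colnames(x) <- paste0("b", model$keep_bits)
  as.data.frame(x)
}

#' Predict pIC50 for new compounds
#'
#' @param object A [train_qsar()] model.
#' @param newdata Compound tibble with `id` and `canonical_smiles`.
#' @param fingerprints Optional precomputed fingerprint matrix.
#' @param ... Unused.
#' @return Numeric vector of predicted pIC50, named by compound id.
#' @export
predict.qsar_model <- function(object, newdata, fingerprints = NULL, ...) {
  feats <- model_features(object, newdata, fingerprints)
  setNames(
    predict(object$forest, feats, num.threads = 1L)$predictions,
    as.character(newdata$id)
  )
}

#' Evaluate a fitted model on labelled data
#'
#' @param model A [train_qsar()] model.
#' @param data Activity tibble with `canonical_smiles` and `pic50`.
#' @param fingerprints Optional precomputed fingerprint matrix.
#' @return The model with `$test_metrics` set (one-row metrics tibble).
#' @export
evaluate_model <- function(model, data, fingerprints = NULL) {
  if (is.null(nrow(data)) || nrow(data) == 0L) stop_domain("Evaluation data is empty.")
  pred <- predict(model, data, fingerprints = fingerprints)
  model$test_metrics <- regression_metrics(data$pic50, pred)
  model
}

#' Residual-percentile applicability cutoff
#'
#' The q-quantile (default 95th percentile) of absolute residuals under
#' linear interpolation between order statistics; records whose absolute
#' residual exceeds the cutoff fall outside the model's applicability
#' domain.
#'
#' @param residuals Non-negative absolute residuals.
#' @param q Quantile level in (0, 1). Default 0.95.
#' @return The cutoff value.
#' @export
residual_cutoff <- function(residuals, q = 0.95) {
  if (length(residuals) == 0L || !is.numeric(residuals)) {
    stop_domain("`residuals` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(residuals)) || any(residuals < 0)) {
    stop_domain("`residuals` must be finite, non-negative absolute residuals.")
  }
  check_number(q, "q", lower = 1e-12, upper = 1 - 1e-12)
  unname(quantile(residuals, probs = q, type = 7))
}

#' Two-stage applicability-domain filter
#'
#' Stage 1 keeps records whose observed pIC50 is at least `pic50_min`
#' (default 5.0, the conventional 100 uM activity floor). Stage 2 computes
#' absolute residuals |observed - predicted| under `model`, sets the
#' cutoff at the `q`-quantile of those residuals, and drops records above
#' it. The returned attributes record counts per stage.
#'
#' @param df Activity tibble with `canonical_smiles` and `pic50`.
#' @param model A [train_qsar()] model.
#' @param q Residual quantile level in (0, 1). Default 0.95.
#' @param pic50_min Activity floor applied before residual filtering.
#' @param fingerprints Optional precomputed fingerprint matrix aligned
#'   with `df`.
#' @return Tibble of retained records with `predicted_pic50` and
#'   `abs_residual` columns appended; attributes `report` (one-row tibble:
#'   n_input, n_after_pic50, n_retained, cutoff) and `model` (the model
#'   with `$residual_cutoff` set).
#' @export
filter_applicability <- function(df, model, q = 0.95, pic50_min = 5,
                                 fingerprints = NULL) {
  check_number(q, "q", lower = 1e-12, upper = 1 - 1e-12)
  check_columns(df, "pic50", "activity table")
  n_input <- nrow(df)
  if (!is.null(fingerprints)) fingerprints <- fingerprints[df$pic50 >= pic50_min, , drop = FALSE]
  stage1 <- df[df$pic50 >= pic50_min, , drop = FALSE]
  pred <- predict(model, stage1, fingerprints = fingerprints)
  stage1$predicted_pic50 <- unname(pred)
  stage1$abs_residual <- abs(stage1$pic50 - stage1$predicted_pic50)
  cutoff <- residual_cutoff(stage1$abs_residual, q)
  out <- stage1[stage1$abs_residual <= cutoff, , drop = FALSE]
  model$residual_cutoff <- cutoff
  attr(out, "report") <- tibble(
    n_input = n_input, n_after_pic50 = nrow(stage1),
    n_retained = nrow(out), cutoff = cutoff
  )
  attr(out, "model") <- model
  out
}

#' PCA projection of a fingerprint matrix
#'
#' Centered principal-component projection used to visualise the chemical
#' space of a ligand set and its applicability domain.
#'
#' @param fingerprints Numeric matrix (rows = compounds).
#' @param n_components Number of components. Default 2.
#' @return Tibble with `id` and `PC1..PCk` coordinate columns; attribute
#'   `explained_variance` holds the per-component variance fractions
#'   (non-increasing, summing to at most 1).
#' @export
pca_projection <- function(fingerprints, n_components = 2L) {
  if (nrow(fingerprints) < max(2L, n_components)) {
    stop_domain("Need at least as many rows as components (and >= 2).")
  }
  pc <- prcomp(fingerprints, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  coords <- mutate(coords,
    id = rownames(fingerprints) %||% as.character(seq_len(nrow(fingerprints))),
    .before = 1
  )
  ev <- pc$sdev^2
  attr(coords, "explained_variance") <- (ev / sum(ev))[seq_len(k)]
  coords
}
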