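# broom-style accessors for fitted QSAR models.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a QSAR model's cross-validation folds
#'
#' One row per cross-validation fold with its held-out metrics.
#'
#' @param x A [train_qsar()] model.
#' @param ... Unused.
#' @return Tibble with `fold`, `mse`, `r2`, `mae`, `rmse` (empty when CV
#'   was skipped for lack of data).
#' @export
tidy.qsar_model <- function(x, ...) {
  if (is.null(x$cv_metrics)) {
    return(tibble(fold = integer(0), mse = numeric(0), r2 = numeric(0),
                  mae = numeric(0), rmse = numeric(0)))
  }
  x$cv_metrics
}

#' One-row summary of a QSAR model
#'
#' @param x A [train_qsar()] model.
#' @param ... Unused.
#' @return One-row tibble: target, training size, fingerprint parameters,
#'   train metrics, test metrics (NA until [evaluate_model()] is called)
#'   and the residual cutoff (NA until [filter_applicability()]).
#' @export
glance.qsar_model <- function(x, ...) {
  tm <- x$test_metrics
  tibble(
    target = x$target,
    n_train = x$n_train,
    n_bits = x$feature_params$n_bits,
    radius = x$feature_params$radius,
    train_r2 = x$train_metrics$r2,
    train_rmse = x$train_metrics$rmse,
    test_mse = if (is.null(tm)) NA_real_ else tm$mse,
    test_r2 = if (is.null(tm)) NA_real_ else tm$r2,
    test_mae = if (is.null(tm)) NA_real_ else tm$mae,
    test_rmse = if (is.null(tm)) NA_real_ else tm$rmse,
    residual_cutoff = x$residual_cutoff %||% NA_real_,
    seed = x$seed
  )
}
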