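# ggplot2 visual summaries for the main result types.

#' Predicted-vs-observed scatter for a QSAR model
#'
#' @param model A [train_qsar()] model.
#' @param data Labelled activity tibble (`canonical_smiles`, `pic50`).
#' @param set Label for the panel subtitle (e.g. "test").
#' @return A ggplot object.
#' @export
plot_model_fit <- function(model, data, set = "test") {
  pred <- predict(model, data)
  df <- tibble(observed = data$pic50, predicted = unname(pred))
  m <- regression_metrics(df$observed, df$predicted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "red") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      title = sprintf("%s pIC50: predicted vs observed", model$target),
      subtitle = sprintf("%s set: R2 = %.3f, RMSE = %.3f", set, m$r2, m$rmse),
      x = "observed pIC50", y = "predicted pIC50"
    )
}

#' Elbow and silhouette curves for cluster-count selection
#'
#' @param selection A [choose_k()] result.
#' @return A ggplot object (SSE and silhouette vs k, free scales).
#' @export
plot_cluster_selection <- function(selection) {
  stopifnot(inherits(selection, "cluster_selection"))
  long <- tidyr::pivot_longer(selection$table, c("sse", "silhouette"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = selection$chosen_k, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      title = sprintf("Cluster-count selection (chosen k = %d, elbow k = %d)",
                      selection$chosen_k, selection$elbow_k),
      x = "number of clusters k", y = NULL
    )
}

#' @rdname plot_cluster_selection
#' @param object,... Autoplot arguments.
#' @export
autoplot.cluster_selection <- function(object, ...) plot_cluster_selection(object)

#' PCA scatter of a fingerprint space
#'
#' @param projection A [pca_projection()] tibble.
#' @param colour Optional vector (aligned with rows) for point colour.
#' @return A ggplot object with variance fractions on the axes.
#' @export
plot_pca <- function(projection, colour = NULL) {
  ev <- attr(projection, "explained_variance")
  df <- projection
  if (!is.null(colour)) df$colour <- colour
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2])
    )
  if (is.null(colour)) gg + ggplot2::geom_point(alpha = 0.6)
  else gg + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), alpha = 0.8) +
    ggplot2::labs(colour = NULL)
}

#' Descriptor-vs-potency SAR scatter, coloured by cluster
#'
#' @param assignments A [cluster_kmeans()] tibble.
#' @param profile Tibble with `id`, descriptors and a pIC50 column.
#' @param pic50_col Name of the pIC50 column. Default `"predicted_pic50"`.
#' @return A ggplot object faceted by descriptor.
#' @export
plot_sar <- function(assignments, profile, pic50_col = "predicted_pic50") {
  dat <- inner_join(
    mutate(assignments, id = as.character(.data$id)),
    mutate(as_tibble(profile), id = as.character(.data$id)),
    by = "id"
  ) |>
    tidyr::pivot_longer(all_of(descriptor_cols),
                        names_to = "descriptor", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$value, y = .data[[pic50_col]],
    colour = factor(.data$cluster)
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~descriptor, scales = "free_x") +
    ggplot2::labs(x = "descriptor value", y = "pIC50", colour = "cluster")
}

#' BBB criterion pass/fail tile plot
#'
#' @param bbb A [bbb_score()] tibble.
#' @return A ggplot object (compound x criterion tiles).
#' @export
plot_bbb <- function(bbb) {
  long <- bbb |>
    select("id", ends_with("_ok"), "score_percent") |>
    tidyr::pivot_longer(ends_with("_ok"), names_to = "criterion", values_to = "pass") |>
    mutate(criterion = sub("_ok$", "", .data$criterion))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$criterion,
    y = stats::reorder(.data$id, .data$score_percent),
    fill = .data$pass
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = "criterion", y = NULL, fill = "pass")
}
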