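# Candidate potency prediction, cluster-count selection, k-means
# clustering, and SAR / activity-tier summaries.

#' Predict candidate potency with a fitted QSAR model
#'
#' Applies a per-target fingerprint regressor to candidate compounds.
#' Candidates that cannot be featurized (no parseable structure) are
#' skipped with a warning rather than failing the batch.
#'
#' @param model A [train_qsar()] model (ideally trained on the
#'   applicability-filtered ligand set).
#' @param candidates Compound tibble (`id`, `canonical_smiles`).
#' @return Input tibble with a `predicted_pic50` column appended (skipped
#'   rows dropped; attribute `n_skipped` reports how many).
#' @export
predict_potency <- function(model, candidates) {
  check_columns(candidates, c("id", "canonical_smiles"), "candidate table")
  ok <- !is.na(candidates$canonical_smiles)
  if (any(!ok)) {
    warn(sprintf("Skipping %d candidate(s) without a parseable structure.", sum(!ok)))
  }
  out <- as_tibble(candidates[ok, , drop = FALSE])
  out$predicted_pic50 <- unname(predict(model, out))
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Classify pIC50 into potency tiers
#'
#' Low potency: pIC50 <= 5; medium: 5 < pIC50 <= 7; high: pIC50 > 7.
#' The three classes partition the real line; both boundary values fall in
#' the lower class (5 is low, 7 is medium).
#'
#' @param pic50 Finite numeric vector.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
classify_activity <- function(pic50) {
  if (!is.numeric(pic50) || any(!is.finite(pic50))) {
    stop_domain("`pic50` must be finite numeric.")
  }
  cut(pic50, breaks = c(-Inf, 5, 7, Inf), labels = c("low", "medium", "high"),
      right = TRUE)
}

#' Choose the number of k-means clusters
#'
#' Runs k-means over a range of cluster counts and reports, per k, the
#' within-cluster sum of squares (SSE, for the elbow heuristic) and the
#' mean silhouette width. The chosen k maximises the silhouette; the
#' elbow k (largest second difference of SSE) is reported alongside. When
#' even the best silhouette is weak (< `min_silhouette`) the result is
#' flagged as having no clear cluster structure.
#'
#' @param features Numeric matrix (rows = compounds).
#' @param k_range Candidate cluster counts, each in \[2, n-1\]. Default 2:10.
#' @param seed Integer seed.
#' @param n_start Random restarts per k. Default 10.
#' @param min_silhouette Weak-structure flag threshold. Default 0.25.
#' @return Object of class `cluster_selection`: list with `chosen_k`,
#'   `elbow_k`, `no_structure` flag, and a per-k `table` (k, sse,
#'   silhouette).
#' @export
choose_k <- function(features, k_range = 2:10, seed = 1L, n_start = 10L,
                     min_silhouette = 0.25) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    stop_domain(sprintf("`k_range` must lie within [2, %d] for %d rows.", n - 1L, n))
  }
  k_range <- sort(unique(as.integer(k_range)))
  d <- stats::dist(features)
  tab <- purrr::map_dfr(k_range, function(k) {
    km <- withr_seed(seed + k, kmeans(features, centers = k, nstart = n_start, iter.max = 50L))
    sil <- cluster::silhouette(km$cluster, d)
    tibble(k = k, sse = km$tot.withinss, silhouette = mean(sil[, "sil_width"]))
  })
  elbow_k <- if (nrow(tab) >= 3L) {
    d2 <- diff(diff(tab$sse))  # second difference; elbow = sharpest bend
    tab$k[which.max(d2) + 1L]
  } else {
    tab$k[1L]
  }
  best <- which.max(tab$silhouette)
  structure(
    list(
      chosen_k = tab$k[best],
      elbow_k = elbow_k,
      no_structure = tab$silhouette[best] < min_silhouette,
      table = tab
    ),
    class = "cluster_selection"
  )
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("<cluster_selection> chosen k = %d (max silhouette), elbow k = %d\n",
              x$chosen_k, x$elbow_k))
  if (x$no_structure) cat("  note: weak silhouette at every k -- no clear cluster structure\n")
  print(x$table)
  invisible(x)
}

#' K-means cluster assignments
#'
#' Lloyd-type k-means (`stats::kmeans`) with random restarts; labels are
#' stable under a fixed seed.
#'
#' @param features Numeric matrix with compound ids as rownames.
#' @param k Number of clusters (>= 2, < rows).
#' @param seed Integer seed.
#' @param n_start Random restarts. Default 10.
#' @return Tibble with `id`, `cluster` (integer in 1..k) and `distance`
#'   (Euclidean distance to the assigned centroid); attribute `sse` holds
#'   the total within-cluster sum of squares, `centers` the centroid
#'   matrix.
#' @export
cluster_kmeans <- function(features, k, seed = 1L, n_start = 10L) {
  features <- as.matrix(features)
  if (k < 2L || k >= nrow(features)) stop_domain("`k` must be in [2, n-1].")
  km <- withr_seed(seed, kmeans(features, centers = k, nstart = n_start, iter.max = 50L))
  dist_to_centroid <- sqrt(rowSums((features - km$centers[km$cluster, , drop = FALSE])^2))
  out <- tibble(
    id = rownames(features) %||% as.character(seq_len(nrow(features))),
    cluster = as.integer(km$cluster),
    distance = dist_to_centroid
  )
  attr(out, "sse") <- km$tot.withinss
  attr(out, "centers") <- km$centers
  out
}

#' Per-cluster SAR summary and fingerprint-bit frequencies
#'
#' Summarises each cluster's physicochemical descriptors and potency
#' (mean, median, SD of MolWt, LogP, HBD, HBA, TPSA, pIC50) and tabulates
#' how often each fingerprint bit is set per cluster (the data behind a
#' cluster-by-bit heatmap). Bit-frequency rows sum to cluster sizes and
#' columns sum to the global bit counts.
#'
#' @param assignments Tibble from [cluster_kmeans()] (`id`, `cluster`).
#' @param profile Tibble with `id`, the descriptor columns of
#'   [compute_descriptors()], and a pIC50 column.
#' @param fingerprints Optional fingerprint matrix (rownames = ids) for
#'   the bit-frequency matrix.
#' @param pic50_col Name of the pIC50 column in `profile`. Default
#'   `"predicted_pic50"`.
#' @return List with `summary` (long tibble: cluster, n, variable, mean,
#'   median, sd) and `bit_freq` (cluster x bit count matrix, or NULL).
#' @export
sar_summary <- function(assignments, profile, fingerprints = NULL,
                        pic50_col = "predicted_pic50") {
  check_columns(assignments, c("id", "cluster"), "assignments")
  check_columns(profile, c("id", descriptor_cols, pic50_col), "profile")
  if (!all(profile$id %in% assignments$id)) {
    stop_domain("Every profiled compound needs a cluster assignment.")
  }
  dat <- inner_join(
    mutate(assignments, id = as.character(.data$id)),
    mutate(as_tibble(profile), id = as.character(.data$id)),
    by = "id"
  )
  vars <- c(descriptor_cols, pic50_col)
  summary <- dat |>
    tidyr::pivot_longer(all_of(vars), names_to = "variable", values_to = "value") |>
    group_by(.data$cluster, .data$variable) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      median = median(.data$value),
      sd = sd(.data$value),
      .groups = "drop"
    )
  bit_freq <- NULL
  if (!is.null(fingerprints)) {
    fp <- fingerprints[dat$id, , drop = FALSE]
    bit_freq <- rowsum(fp, group = dat$cluster)
    colnames(bit_freq) <- paste0("bit", seq_len(ncol(bit_freq)))
  }
  list(summary = summary, bit_freq = bit_freq)
}
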