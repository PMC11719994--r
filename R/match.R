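# Similarity-based matching of candidate natural compounds to known
# active ligands: cosine similarity over fingerprints with a fixed
# decision threshold (strictly greater than 0.5 by default).

#' Cosine similarity between two fingerprint vectors
#'
#' `dot(a, b) / (|a| |b|)`. Symmetric, 1 for identical vectors, and in
#' \[0, 1\] for non-negative (binary) vectors.
#'
#' @param a,b Numeric vectors of equal length; neither may be all-zero.
#' @return Similarity in \[0, 1\].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop_domain("Fingerprint lengths differ.")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_domain("Cosine similarity is undefined for an all-zero vector.")
  sum(a * b) / (na * nb)
}

# Dense candidate x active cosine matrix via one cross-product.
cosine_matrix <- function(cand_fp, active_fp) {
  if (ncol(cand_fp) != ncol(active_fp)) stop_domain("Fingerprint lengths differ.")
  cn <- sqrt(rowSums(cand_fp^2)); an <- sqrt(rowSums(active_fp^2))
  if (any(cn == 0) || any(an == 0)) {
    stop_domain("Cosine similarity is undefined for an all-zero fingerprint.")
  }
  (cand_fp %*% t(active_fp)) / outer(cn, an)
}

#' Match candidates to known actives by cosine similarity
#'
#' For every (candidate, target) pair, takes the maximum cosine similarity
#' between the candidate's fingerprint and the fingerprints of that
#' target's active ligands. A pair is a hit when its best similarity is
#' strictly greater than `threshold` (default 0.5). Results are sorted by
#' similarity descending, ties broken by candidate id for a stable order.
#'
#' @param candidates Compound tibble (`id`, `canonical_smiles`).
#' @param actives Active-ligand tibble (`id`, `canonical_smiles`,
#'   `target`); every queried target must have at least one active.
#' @param threshold Decision threshold; hits require similarity strictly
#'   above it. Default 0.5.
#' @param n_bits,radius Fingerprint parameters.
#' @param candidate_fp,active_fp Optional precomputed fingerprint matrices
#'   (rows aligned with the respective tibbles).
#' @return Tibble with columns `id`, `target`, `best_similarity`,
#'   `matched_ligand`, `is_hit`.
#' @export
predict_candidates <- function(candidates, actives, threshold = 0.5,
                               n_bits = 2048L, radius = 2L,
                               candidate_fp = NULL, active_fp = NULL) {
  check_columns(candidates, c("id", "canonical_smiles"), "candidate table")
  check_columns(actives, c("id", "canonical_smiles", "target"), "active table")
  if (nrow(actives) == 0L) stop_domain("Active set is empty.")
  check_number(threshold, "threshold", lower = 0, upper = 1)
  if (is.null(candidate_fp)) {
    candidate_fp <- compute_fingerprints(candidates, n_bits = n_bits, radius = radius)
  }
  if (is.null(active_fp)) {
    active_fp <- compute_fingerprints(actives, n_bits = n_bits, radius = radius)
  }
  by_target <- split(seq_len(nrow(actives)), actives$target)
  empty <- names(by_target)[lengths(by_target) == 0L]
  if (length(empty) > 0L) {
    stop_domain(sprintf("No active ligands for target(s): %s", paste(empty, collapse = ", ")))
  }
  res <- purrr::map_dfr(names(by_target), function(tg) {
    idx <- by_target[[tg]]
    sims <- cosine_matrix(candidate_fp, active_fp[idx, , drop = FALSE])
    best <- max.col(sims, ties.method = "first")
    tibble(
      id = as.character(candidates$id),
      target = tg,
      best_similarity = sims[cbind(seq_len(nrow(sims)), best)],
      matched_ligand = as.character(actives$id[idx][best])
    )
  })
  res$is_hit <- res$best_similarity > threshold
  arrange(res, desc(.data$best_similarity), .data$id)
}

#' Recall of a hit list against truth labels
#'
#' TP / (TP + FN): the fraction of truly active candidates recovered as
#' hits.
#'
#' @param results Match tibble from [predict_candidates()] (needs `id`,
#'   `target`, `is_hit`).
#' @param truth Tibble with `id`, `target` and logical/0-1 `label`
#'   columns; every result row must have a label.
#' @return Recall in \[0, 1\].
#' @export
recall_score <- function(results, truth) {
  check_columns(results, c("id", "target", "is_hit"), "results")
  check_columns(truth, c("id", "target", "label"), "truth")
  joined <- inner_join(results, truth, by = c("id", "target"))
  if (nrow(joined) < nrow(results)) {
    stop_domain("Every result must have a truth label.")
  }
  pos <- joined$label %in% c(1, TRUE)
  if (!any(pos)) stop_domain("Recall is undefined with no positive truth labels.")
  sum(joined$is_hit[pos]) / sum(pos)
}
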