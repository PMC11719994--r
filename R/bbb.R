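# Rule-based blood-brain-barrier permeability scoring: five inclusive
# physicochemical criteria, 20 percentage points each.

#' BBB criterion bounds
#'
#' The five CNS-permeability criteria, all bounds inclusive:
#' molecular weight <= 400 Da; -0.5 <= LogP <= 5; hydrogen-bond donors
#' <= 3; hydrogen-bond acceptors <= 7; TPSA <= 90 square Angstroms.
#'
#' @return Named list of bounds.
#' @export
bbb_criteria <- function() {
  list(mw_max = 400, logp_min = -0.5, logp_max = 5, hbd_max = 3,
       hba_max = 7, tpsa_max = 90)
}

#' Score blood-brain-barrier permeability
#'
#' Evaluates the five physicochemical criteria of [bbb_criteria()] per
#' compound and reports the score as `20 * (criteria passed)` percent
#' (so always one of 0, 20, 40, 60, 80, 100). A perfect score requires
#' all five criteria.
#'
#' @param df Either a compound tibble already carrying the descriptor
#'   columns `mol_wt`, `log_p`, `h_donors`, `h_acceptors`, `tpsa` (see
#'   [compute_descriptors()]), or one with `canonical_smiles` (or
#'   `id` + `smiles`) from which descriptors are computed first.
#' @param criteria Bounds list, defaults to [bbb_criteria()].
#' @return Tibble with the descriptor columns, five pass flags (`mw_ok`,
#'   `logp_ok`, `hbd_ok`, `hba_ok`, `tpsa_ok`), `score_fraction` and
#'   `score_percent`.
#' @examples
#' \dontrun{
#' bbb_score(flavonoid_panel())  # coumarin scores 100, quercetin 60
#' }
#' @export
bbb_score <- function(df, criteria = bbb_criteria()) {
  if (!all(descriptor_cols %in% names(df))) {
    df <- compute_descriptors(df)
  }
  missing <- descriptor_cols[!vapply(descriptor_cols, function(cl) {
    cl %in% names(df) && all(is.finite(df[[cl]]))
  }, logical(1))]
  if (length(missing) > 0L) {
    stop_domain(sprintf("Missing or non-finite descriptor(s): %s",
                        paste(missing, collapse = ", ")))
  }
  out <- as_tibble(df)
  out$mw_ok <- out$mol_wt <= criteria$mw_max
  out$logp_ok <- out$log_p >= criteria$logp_min & out$log_p <= criteria$logp_max
  out$hbd_ok <- out$h_donors <= criteria$hbd_max
  out$hba_ok <- out$h_acceptors <= criteria$hba_max
  out$tpsa_ok <- out$tpsa <= criteria$tpsa_max
  passes <- out$mw_ok + out$logp_ok + out$hbd_ok + out$hba_ok + out$tpsa_ok
  out$score_fraction <- passes / 5
  out$score_percent <- 20 * passes
  out
}
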