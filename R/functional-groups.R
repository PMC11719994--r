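# Functional-group detection by SMARTS pattern matching (OpenBabel).
# Exclusion rules: a carboxyl carbon is not also counted as ketone or
# aldehyde (those patterns require carbon neighbours on the carbonyl
# carbon), and an ester/lactone oxygen is not counted as ether.

#' Functional-group SMARTS library
#'
#' The default group library used by [detect_functional_groups()]:
#' ether (dialkyl/aryl oxygen, excluding ester and lactone oxygens),
#' ketone (carbonyl flanked by two carbons, aromatic ring carbonyls
#' included), aldehyde, carboxyl (acid or carboxylate), and aromatic
#' (any aromatic atom). Extend or override by passing your own tibble of
#' `group` / `smarts` columns; a group matches when any of its patterns
#' matches.
#'
#' @return Tibble with columns `group` and `smarts`.
#' @export
fg_library <- function() {
  tibble::tribble(
    ~group,     ~smarts,
    # element-generic [#8] so aromatic ring oxygens count too
    "ether",    "[#8X2;!$([#8X2][#6X3]=[#8X1])]([#6])[#6]",
    "ketone",   "[#6X3](=[#8X1])([#6])[#6]",
    "aldehyde", "[#6X3H1](=[#8X1])[#6]",
    "carboxyl", "[#6X3](=[#8X1])[#8X2H1]",
    "carboxyl", "[#6X3](=[#8X1])[#8X1-]",
    "aromatic", "a"
  )
}

#' Detect functional groups in compounds
#'
#' Matches every pattern of the group library against every molecule and
#' reports which groups are present.
#'
#' @param df Compound tibble (`id`, `canonical_smiles`) or character
#'   vector of canonical SMILES.
#' @param groups Group library tibble (`group`, `smarts`); default
#'   [fg_library()].
#' @return Long tibble with columns `id`, `group`, `n_matches`, `present`.
#' @export
detect_functional_groups <- function(df, groups = fg_library()) {
  if (is.character(df)) df <- tibble(id = df, canonical_smiles = df)
  check_columns(df, c("id", "canonical_smiles"), "compound table")
  check_columns(groups, c("group", "smarts"), "group library")
  counts <- purrr::map(groups$smarts, function(p) smarts_count(df$canonical_smiles, p))
  long <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    tibble(
      id = as.character(df$id),
      group = groups$group[i],
      n_matches = counts[[i]]
    )
  })
  long |>
    group_by(.data$id, .data$group) |>
    summarise(n_matches = sum(.data$n_matches), .groups = "drop") |>
    mutate(present = .data$n_matches > 0L) |>
    arrange(match(.data$id, as.character(df$id)), match(.data$group, unique(groups$group)))
}

#' Functional-group sets per compound
#'
#' Convenience wrapper over [detect_functional_groups()] collapsing the
#' long table to one row per compound with a list-column of present
#' groups.
#'
#' @inheritParams detect_functional_groups
#' @return Tibble with `id` and `groups` (list of character vectors).
#' @export
functional_group_sets <- function(df, groups = fg_library()) {
  long <- detect_functional_groups(df, groups)
  present <- long |>
    filter(.data$present) |>
    group_by(.data$id) |>
    summarise(groups = list(sort(unique(.data$group))), .groups = "drop")
  tibble(id = as.character(if (is.character(df)) df else df$id)) |>
    left_join(present, by = "id") |>
    mutate(groups = purrr::map(.data$groups, function(g) g %||% character(0)))
}
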