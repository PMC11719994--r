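# Food-source aggregation: compound <-> source maps, top-source ranking,
# and exact Venn region counts.

#' Build a source map
#'
#' A `source_map` pairs a forward mapping (source name -> set of compound
#' ids) with its inverse (compound id -> set of sources); the two are kept
#' mutually consistent. Source names are normalised (case-folded,
#' trimmed) before matching, since real food-source tables are dirty.
#'
#' @param df Either a compound tibble with a `sources` list-column (see
#'   [parse_compounds()]) or a long two-column table with `id` and
#'   `source`.
#' @return Object of class `source_map`: list with `by_source` and
#'   `by_compound` (both named lists of character vectors).
#' @export
source_map <- function(df) {
  if (all(c("id", "source") %in% names(df)) && !"sources" %in% names(df)) {
    long <- tibble(id = as.character(df$id), source = tolower(trimws(df$source)))
  } else {
    check_columns(df, c("id", "sources"), "compound table")
    long <- tibble(id = as.character(df$id), source = df$sources) |>
      tidyr::unnest_longer("source", values_to = "source") |>
      mutate(source = tolower(trimws(.data$source)))
  }
  long <- distinct(filter(long, nzchar(.data$source)))
  structure(
    list(
      by_source = lapply(split(long$id, long$source), function(x) sort(unique(x))),
      by_compound = lapply(split(long$source, long$id), function(x) sort(unique(x)))
    ),
    class = "source_map"
  )
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("<source_map> %d sources, %d compounds\n",
              length(x$by_source), length(x$by_compound)))
  invisible(x)
}

#' Top food sources by compound count
#'
#' Sources ranked by how many (predicted-hit) compounds they contribute,
#' descending, ties broken alphabetically.
#'
#' @param map A [source_map()].
#' @param n Number of sources to return; `Inf` for all.
#' @param min_count Drop sources below this count (bar-chart cutoff).
#'   Default 0.
#' @return Tibble with `source` and `n_compounds`, ranked.
#' @export
top_sources <- function(map, n = 10, min_count = 0) {
  stopifnot(inherits(map, "source_map"))
  if (length(map$by_source) == 0L) stop_domain("Source map is empty.")
  if (!is.numeric(n) || length(n) != 1L || n <= 0) stop_domain("`n` must be positive.")
  tab <- tibble(
    source = names(map$by_source),
    n_compounds = unname(lengths(map$by_source))
  ) |>
    filter(.data$n_compounds >= min_count) |>
    arrange(desc(.data$n_compounds), .data$source)
  head(tab, n)
}

#' Exact Venn region counts for selected sources
#'
#' Computes all `2^k - 1` disjoint region counts for `k` selected sources
#' by exact set algebra: each compound in the union is assigned to exactly
#' one region according to which of the selected sources contain it, so
#' the region counts sum to the size of the union.
#'
#' @param map A [source_map()].
#' @param sources 2 to 6 source names present in the map.
#' @return Tibble with one row per non-empty membership pattern:
#'   `region` (source names joined by `&`), `bitmask` (bit i set = i-th
#'   selected source contains the compound), `count`, and `compounds`
#'   (list-column of ids).
#' @export
venn_intersections <- function(map, sources) {
  stopifnot(inherits(map, "source_map"))
  sources <- tolower(trimws(sources))
  if (length(sources) < 2L || length(sources) > 6L) {
    stop_domain("Provide between 2 and 6 source names.")
  }
  unknown <- setdiff(sources, names(map$by_source))
  if (length(unknown) > 0L) {
    stop_domain(sprintf("Unknown source(s): %s", paste(unknown, collapse = ", ")))
  }
  sets <- map$by_source[sources]
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe))
  bitmask <- as.integer(membership %*% 2^(seq_along(sources) - 1L))
  k <- length(sources)
  purrr::map_dfr(seq_len(2^k - 1L), function(m) {
    in_region <- bitmask == m
    bits <- bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L
    tibble(
      region = paste(sources[bits], collapse = " & "),
      bitmask = m,
      count = sum(in_region),
      compounds = list(universe[in_region])
    )
  })
}
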