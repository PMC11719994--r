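# Structure parsing, canonicalisation, descriptors and compound-table I/O.
# All heavy lifting is delegated to OpenBabel via ChemmineR/ChemmineOB;
# this file owns error handling, vectorisation and the tabular surface.

ob_convert <- function(from, to, source, opts = NULL) {
  if (is.null(opts)) {
    ChemmineOB::convertFormat(from, to, source)
  } else {
    ChemmineOB::convertFormat(from, to, source,
      options = data.frame(names = opts, args = "", stringsAsFactors = FALSE)
    )
  }
}

# OpenBabel molecule references for a vector of (canonical) SMILES.
ob_mols <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
}

# Unique-match counts of a SMARTS pattern over (canonical) SMILES.
smarts_count <- function(smiles, pattern) {
  as.integer(ChemmineOB::smartsSearch_OB(ob_mols(smiles), pattern, uniqueMatches = TRUE))
}

# Canonicalize one batch of SMILES through OpenBabel. The converter aborts
# the whole batch at the first invalid entry, so on a short read we split
# the batch and recurse; invalid entries come back NA.
canonicalize_batch <- function(smiles, strip_salts) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  opts <- if (strip_salts) "r" else NULL
  out <- suppressWarnings(ob_convert("SMI", "CAN", paste(smiles, collapse = "\n"), opts))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- sub("[ \t].*$", "", lines)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) <= n]
  lines <- lines[seq_len(min(length(lines), n))]
  lines[!nzchar(trimws(lines))] <- NA_character_
  if (length(lines) == n && !anyNA(lines)) return(lines)
  if (n == 1L) return(NA_character_)
  mid <- n %/% 2L
  c(
    canonicalize_batch(smiles[seq_len(mid)], strip_salts),
    canonicalize_batch(smiles[(mid + 1L):n], strip_salts)
  )
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form so that any two valid
#' encodings of the same structure map to the same string. Canonicalisation
#' is idempotent: applying it to its own output returns the same string.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strip_salts Keep only the largest contiguous fragment before
#'   canonicalising (drops counter-ions in salt forms). Default `TRUE`.
#' @return Character vector of canonical SMILES; `NA` for unparseable input.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("C1=CC=CC=C1", "c1ccccc1"))  # identical output
#' }
#' @export
canonicalize_smiles <- function(smiles, strip_salts = TRUE) {
  if (!is.character(smiles)) stop_domain("`smiles` must be a character vector.")
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (any(ok)) out[ok] <- canonicalize_batch(smiles[ok], strip_salts)
  out
}

#' Parse a compound table and attach canonical SMILES
#'
#' Takes a data frame with at least `id` and `smiles` columns, canonicalises
#' every structure, drops rows whose SMILES cannot be parsed (reporting how
#' many and which), and returns a tibble with a `canonical_smiles` column
#' appended. A delimiter-separated `sources` column, when present, is split
#' into a list-column of food-source names (case-folded and trimmed).
#'
#' @param df Data frame with columns `id`, `smiles` and optionally `name`,
#'   `sources`, `target`, `ic50_nm`.
#' @param strip_salts Passed to [canonicalize_smiles()].
#' @param source_delim Delimiter separating entries of the `sources` cell.
#' @return Tibble of parseable rows with `canonical_smiles` appended, and
#'   attribute `n_skipped` plus a `skipped` attribute tibble (id, row,
#'   smiles) for the rows that failed to parse.
#' @export
parse_compounds <- function(df, strip_salts = TRUE, source_delim = ";") {
  check_columns(df, c("id", "smiles"), "compound table")
  df <- as_tibble(df)
  df$canonical_smiles <- canonicalize_smiles(df$smiles, strip_salts)
  bad <- is.na(df$canonical_smiles)
  skipped <- tibble(
    id = as.character(df$id[bad]), row = which(bad), smiles = df$smiles[bad]
  )
  if (any(bad)) {
    warn(sprintf(
      "Skipped %d row%s with unparseable SMILES (rows: %s).",
      sum(bad), if (sum(bad) > 1L) "s" else "",
      paste(head(which(bad), 10L), collapse = ", ")
    ))
  }
  out <- df[!bad, , drop = FALSE]
  if ("sources" %in% names(out) && !is.list(out$sources)) {
    out$sources <- map(out$sources, function(s) {
      if (is.na(s) || !nzchar(trimws(s))) return(character(0))
      sort(unique(tolower(trimws(strsplit(s, source_delim, fixed = TRUE)[[1]]))))
    })
  }
  attr(out, "n_skipped") <- sum(bad)
  attr(out, "skipped") <- skipped
  out
}

#' Read a compound or activity table from CSV
#'
#' Thin wrapper around [readr::read_csv()] + [parse_compounds()]. For
#' `kind = "activities"` the columns `target` and `ic50_nm` are also
#' required and a derived `pic50` column is appended.
#'
#' @param path CSV file with a header row; must contain `id` and `smiles`.
#' @param kind `"candidates"` (default) or `"activities"`.
#' @inheritParams parse_compounds
#' @return Tibble of records (see [parse_compounds()]).
#' @export
read_compound_table <- function(path, kind = c("candidates", "activities"),
                                strip_salts = TRUE, source_delim = ";") {
  kind <- match.arg(kind)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) {
    warn(sprintf("'%s' contains no rows.", path))
  }
  check_columns(df, c("id", "smiles"), sprintf("'%s'", path))
  if (kind == "activities") {
    check_columns(df, c("target", "ic50_nm"), sprintf("'%s'", path))
  }
  out <- parse_compounds(df, strip_salts, source_delim)
  if (kind == "activities" && nrow(out) > 0L) out$pic50 <- ic50_to_pic50(out$ic50_nm)
  out
}

#' Write a compound table to CSV
#'
#' List-columns (`sources`) are collapsed back to delimiter-separated cells.
#'
#' @param df Compound tibble.
#' @param path Output CSV path.
#' @param source_delim Delimiter used to join `sources` entries.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(df, path, source_delim = ";") {
  if ("sources" %in% names(df) && is.list(df$sources)) {
    df$sources <- map_chr(df$sources, paste, collapse = source_delim)
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Compute physicochemical descriptors
#'
#' Appends the five descriptors used by BBB scoring and SAR profiling:
#' molecular weight (`mol_wt`, Da), octanol/water partition estimate
#' (`log_p`, OpenBabel atom-contribution model), hydrogen-bond donor and
#' acceptor counts (`h_donors`, `h_acceptors`; acceptors use the
#' Lipinski-style N/O acceptor definition), and topological polar surface
#' area (`tpsa`, Ertl fragment method, in square Angstroms). Extra OpenBabel
#' properties (molar refractivity `mol_mr`, fluorine count `n_f`) are
#' appended as well.
#'
#' @param df Compound tibble with a `canonical_smiles` column (see
#'   [parse_compounds()]), or a data frame with `id` + `smiles` which is
#'   parsed first.
#' @return Input tibble with descriptor columns appended.
#' @export
compute_descriptors <- function(df) {
  if (!"canonical_smiles" %in% names(df)) df <- parse_compounds(df)
  if (nrow(df) == 0L) {
    return(mutate(as_tibble(df),
      mol_wt = numeric(0), log_p = numeric(0), h_donors = integer(0),
      h_acceptors = integer(0), tpsa = numeric(0),
      mol_mr = numeric(0), n_f = integer(0)
    ))
  }
  p <- do.call(rbind, lapply(ob_mols(df$canonical_smiles), ChemmineOB::prop_OB))
  df$mol_wt <- as.numeric(p$MW)
  df$log_p <- as.numeric(p$logP)
  df$h_donors <- as.integer(p$HBD)
  df$h_acceptors <- as.integer(p$HBA2)
  df$tpsa <- as.numeric(p$TPSA)
  df$mol_mr <- as.numeric(p$MR)
  df$n_f <- as.integer(p$nF)
  df
}

descriptor_cols <- c("mol_wt", "log_p", "h_donors", "h_acceptors", "tpsa")
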