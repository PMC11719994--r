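# Internal helpers shared across modules.

# Structured error constructors. Every user-facing failure goes through one
# of these so callers can branch on class rather than on message text.
stop_parse <- function(msg, smiles = NULL, row = NULL) {
  abort(msg, class = "ncscreen_parse_error", smiles = smiles, row = row)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "ncscreen_config_error", ...)
}

stop_domain <- function(msg, ...) {
  abort(msg, class = "ncscreen_domain_error", ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_domain(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    stop_domain(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_config(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1L) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Deterministic 31-bit integer mixing hash over a numeric vector.
# Plain modular arithmetic in doubles: exact for values < 2^53, so the
# result is bit-identical across platforms and runs.
hash_mix <- function(vals) {
  h <- 17
  for (v in vals) h <- (h * 31 + v) %% 2147483647
  h
}
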