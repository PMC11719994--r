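# Independent oracles: deliberately naive implementations used to check
# the package's code paths.

# Linear-interpolation quantile on the sorted sample:
# h = (n - 1) q + 1, value = x[floor(h)] + (h - floor(h)) (x[ceil(h)] - x[floor(h)])
oracle_quantile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Exhaustive double-loop similarity scan (the brute-force matcher).
oracle_match <- function(cand_fp, active_fp, threshold) {
  out <- NULL
  for (i in seq_len(nrow(cand_fp))) {
    best <- -Inf; best_j <- NA_integer_
    for (j in seq_len(nrow(active_fp))) {
      s <- oracle_cosine(cand_fp[i, ], active_fp[j, ])
      if (s > best) { best <- s; best_j <- j }
    }
    out <- rbind(out, data.frame(cand = i, best_similarity = best,
                                 matched = best_j, is_hit = best > threshold))
  }
  out
}

# Brute-force Venn region counts by scanning every compound of the union.
oracle_venn <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  k <- length(sets)
  counts <- integer(2^k - 1)
  for (cid in universe) {
    mask <- sum(2^(which(vapply(sets, function(s) cid %in% s, logical(1))) - 1))
    counts[mask] <- counts[mask] + 1L
  }
  counts
}
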