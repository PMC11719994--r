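# Circular (Morgan-style) fingerprints computed on the OpenBabel-derived
# molecular graph. No installed R toolkit exposes circular fingerprints,
# so the neighbourhood-hashing step is implemented here; SMILES -> graph
# goes through OpenBabel (explicit-hydrogen SDF) and ChemmineR's SDF parser.

ATOMIC_NUMBERS <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53, Se = 34, As = 33, Na = 11, K = 19, Li = 3,
  Mg = 12, Ca = 20, Zn = 30, Fe = 26
)

# Parse canonical SMILES into heavy-atom graphs. Returns a list (one per
# molecule) of: element (chr), hcount (int), edges (2-col matrix of heavy
# atom indices), order (bond orders). Hydrogens are made explicit by the
# converter, counted per heavy atom, then dropped from the graph.
mol_graphs <- function(canonical_smiles) {
  stopifnot(is.character(canonical_smiles), length(canonical_smiles) > 0L)
  sdftxt <- ob_convert("SMI", "SDF", paste(canonical_smiles, collapse = "\n"), "h")
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdftxt, tf)
  sdfset <- ChemmineR::read.SDFset(tf)
  if (length(sdfset) != length(canonical_smiles)) {
    stop_parse(sprintf(
      "SDF conversion returned %d molecules for %d SMILES; canonicalize first.",
      length(sdfset), length(canonical_smiles)
    ))
  }
  lapply(ChemmineR::SDFset2SDF(sdfset), function(sdf) {
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    n_atoms <- length(elements)
    if (is.null(bb) || nrow(bb) == 0L) {
      edges <- matrix(integer(0), ncol = 2L)
      orders <- integer(0)
    } else {
      edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
      orders <- as.integer(bb[, 3])
    }
    heavy <- which(elements != "H")
    idx_map <- integer(n_atoms)
    idx_map[heavy] <- seq_along(heavy)
    hcount <- integer(length(heavy))
    keep <- logical(nrow(edges))
    for (b in seq_len(nrow(edges))) {
      a1 <- edges[b, 1]; a2 <- edges[b, 2]
      h1 <- elements[a1] == "H"; h2 <- elements[a2] == "H"
      if (h1 && !h2) hcount[idx_map[a2]] <- hcount[idx_map[a2]] + 1L
      if (h2 && !h1) hcount[idx_map[a1]] <- hcount[idx_map[a1]] + 1L
      keep[b] <- !h1 && !h2
    }
    list(
      element = elements[heavy],
      hcount = hcount,
      edges = matrix(idx_map[edges[keep, , drop = FALSE]], ncol = 2L),
      order = orders[keep]
    )
  })
}

# Atoms that survive iterative pruning of degree-1 vertices lie on a cycle.
ring_membership <- function(n_atoms, edges) {
  in_ring <- rep(FALSE, n_atoms)
  if (n_atoms == 0L || nrow(edges) == 0L) return(in_ring)
  alive <- rep(TRUE, n_atoms)
  edge_alive <- rep(TRUE, nrow(edges))
  repeat {
    deg <- tabulate(c(edges[edge_alive, 1], edges[edge_alive, 2]), n_atoms)
    leaves <- which(alive & deg <= 1L)
    if (length(leaves) == 0L) break
    alive[leaves] <- FALSE
    edge_alive <- edge_alive & !(edges[, 1] %in% leaves | edges[, 2] %in% leaves)
  }
  in_ring[alive & tabulate(c(edges[edge_alive, 1], edges[edge_alive, 2]), n_atoms) > 0L] <- TRUE
  in_ring
}

# Hashed circular-environment features for one molecular graph: the classic
# iterative neighbourhood refinement. Each atom environment at each radius
# contributes one integer feature; features are folded modulo n_bits.
morgan_bits <- function(graph, n_bits, radius) {
  n <- length(graph$element)
  if (n == 0L) return(integer(0))
  anum <- unname(ATOMIC_NUMBERS[graph$element])
  anum[is.na(anum)] <- 0
  deg <- tabulate(c(graph$edges[, 1], graph$edges[, 2]), n)
  ring <- as.integer(ring_membership(n, graph$edges))
  inv <- vapply(seq_len(n), function(i) {
    hash_mix(c(anum[i], deg[i], graph$hcount[i], ring[i]))
  }, numeric(1))
  nbrs <- vector("list", n)
  for (b in seq_len(nrow(graph$edges))) {
    i <- graph$edges[b, 1]; j <- graph$edges[b, 2]; o <- graph$order[b]
    nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
    nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
  }
  features <- inv
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      inv <- vapply(seq_len(n), function(i) {
        nb <- nbrs[[i]]
        if (is.null(nb)) return(hash_mix(c(r, inv[i])))
        pairs <- cbind(nb[, 2], inv[nb[, 1]])
        ord <- order(pairs[, 1], pairs[, 2])
        hash_mix(c(r, inv[i], t(pairs[ord, , drop = FALSE])))
      }, numeric(1))
      features <- c(features, inv)
    }
  }
  sort(unique(as.integer(features %% n_bits) + 1L))
}

#' Compute circular fingerprints for a compound table
#'
#' Hashed circular (Morgan-style) fingerprints: every atom's substructure
#' environment up to `radius` bonds is hashed to an integer and folded into
#' a fixed-length binary vector. Identical canonical structures give
#' bit-identical fingerprints; the hash is plain integer arithmetic, so
#' results are reproducible across platforms and runs.
#'
#' Atom environments are distinguished by element, heavy-atom degree,
#' attached hydrogen count, ring membership, and bond orders along the
#' expanding neighbourhood (the standard circular-fingerprint invariants).
#'
#' @param df Compound tibble with `id` and `canonical_smiles` columns
#'   (see [parse_compounds()]), or a character vector of canonical SMILES.
#' @param n_bits Fingerprint length (>= 64). Default 2048.
#' @param radius Maximum environment radius in bonds (>= 0). Default 2.
#' @return Integer 0/1 matrix, one row per compound (rownames = ids), with
#'   attributes `n_bits` and `radius`.
#' @export
compute_fingerprints <- function(df, n_bits = 2048L, radius = 2L) {
  check_number(n_bits, "n_bits", lower = 64)
  check_number(radius, "radius", lower = 0)
  n_bits <- as.integer(n_bits); radius <- as.integer(radius)
  if (is.character(df)) df <- tibble(id = df, canonical_smiles = df)
  check_columns(df, c("id", "canonical_smiles"), "fingerprint input")
  graphs <- mol_graphs(df$canonical_smiles)
  fp <- matrix(0L, nrow = nrow(df), ncol = n_bits,
               dimnames = list(as.character(df$id), NULL))
  for (i in seq_along(graphs)) {
    fp[i, morgan_bits(graphs[[i]], n_bits, radius)] <- 1L
  }
  attr(fp, "n_bits") <- n_bits
  attr(fp, "radius") <- radius
  fp
}
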