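# Maximum common substructure by McGregor-style backtracking: the search
# grows a connected atom mapping pair by pair (atoms compared by element,
# bonds by order or mere connectivity), with branch-and-bound pruning and
# a wall-clock deadline. Folded pairwise across molecule sets. The
# connected formulation sidesteps the dense modular-product clique search,
# which is intractable for fused-ring molecules.

bond_matrix <- function(g, bond_compare) {
  n <- length(g$element)
  m <- matrix(0L, n, n)
  for (e in seq_len(nrow(g$edges))) {
    o <- if (bond_compare == "any") 1L else g$order[e]
    m[g$edges[e, 1], g$edges[e, 2]] <- o
    m[g$edges[e, 2], g$edges[e, 1]] <- o
  }
  m
}

# Largest connected common induced subgraph mapping between two graphs.
# Returns list(map_a, map_b, exact): aligned atom index vectors.
mcgregor_mcs <- function(ga, gb, bond_compare, deadline) {
  ba <- bond_matrix(ga, bond_compare)
  bb <- bond_matrix(gb, bond_compare)
  na <- length(ga$element); nb <- length(gb$element)
  best_a <- integer(0); best_b <- integer(0)
  timed_out <- FALSE

  search <- function(map_a, map_b, dead_a) {
    if (timed_out || Sys.time() > deadline) {
      timed_out <<- TRUE
      return()
    }
    if (length(map_a) > length(best_a)) {
      best_a <<- map_a; best_b <<- map_b
    }
    avail_a <- setdiff(seq_len(na), c(map_a, dead_a))
    avail_b <- setdiff(seq_len(nb), map_b)
    if (length(map_a) + min(length(avail_a), length(avail_b)) <= length(best_a)) {
      return()
    }
    # frontier: unmapped atoms adjacent to the mapped core (any atom when
    # the mapping is empty, which keeps the search connected afterwards)
    frontier <- if (length(map_a) == 0L) {
      avail_a
    } else {
      avail_a[colSums(ba[map_a, avail_a, drop = FALSE] > 0L) > 0L]
    }
    if (length(frontier) == 0L) return()
    # branch atom: most bonds into the mapped core (densest first)
    i <- if (length(map_a) == 0L) {
      frontier[1L]
    } else {
      frontier[which.max(colSums(ba[map_a, frontier, drop = FALSE] > 0L))]
    }
    for (j in avail_b[gb$element[avail_b] == ga$element[i]]) {
      if (all(ba[i, map_a] == bb[j, map_b])) {
        search(c(map_a, i), c(map_b, j), dead_a)
        if (timed_out) return()
      }
    }
    # branch with atom i excluded from the whole subtree
    search(map_a, map_b, c(dead_a, i))
  }
  search(integer(0), integer(0), integer(0))
  list(map_a = best_a, map_b = best_b, exact = !timed_out)
}

# Mapped common subgraph of `ga` as a standalone graph structure.
mapped_subgraph <- function(ga, map_a) {
  sel <- ga$edges[, 1] %in% map_a & ga$edges[, 2] %in% map_a
  idx_map <- setNames(seq_along(map_a), map_a)
  list(
    element = ga$element[map_a],
    hcount = rep(0L, length(map_a)),
    edges = matrix(idx_map[as.character(ga$edges[sel, , drop = FALSE])], ncol = 2L),
    order = ga$order[sel]
  )
}

# Element/any-bond SMARTS for a connected subgraph.
graph_to_smarts <- function(g) {
  n <- length(g$element)
  if (n == 0L) return("")
  nbrs <- vector("list", n)
  for (e in seq_len(nrow(g$edges))) {
    i <- g$edges[e, 1]; j <- g$edges[e, 2]
    nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
  }
  atom_token <- function(i) sprintf("[#%d]", ATOMIC_NUMBERS[[g$element[i]]])
  visited <- rep(FALSE, n)
  ring_bonds <- list()   # ring-closure digits per back edge
  ring_digit <- 0L
  tree_edge <- matrix(FALSE, n, n)
  dfs <- function(i) {
    visited[i] <<- TRUE
    for (j in nbrs[[i]]) {
      if (!visited[j]) {
        tree_edge[i, j] <<- TRUE
        dfs(j)
      } else if (!tree_edge[j, i] && !tree_edge[i, j] && i < j) {
        ring_digit <<- ring_digit + 1L
        d <- if (ring_digit < 10L) as.character(ring_digit) else paste0("%", ring_digit)
        ring_bonds[[length(ring_bonds) + 1L]] <<- c(i, j, d)
      }
    }
  }
  dfs(1L)
  closure_of <- function(i) {
    out <- ""
    for (rb in ring_bonds) {
      if (as.integer(rb[1]) == i || as.integer(rb[2]) == i) out <- paste0(out, "~", rb[3])
    }
    out
  }
  emit <- function(i) {
    s <- paste0(atom_token(i), closure_of(i))
    children <- nbrs[[i]][tree_edge[i, nbrs[[i]]]]
    if (length(children) > 0L) {
      sub <- vapply(children, emit, character(1))
      last <- length(sub)
      if (last > 1L) {
        s <- paste0(s, paste0("(~", sub[-last], ")", collapse = ""))
      }
      s <- paste0(s, "~", sub[last])
    }
    s
  }
  emit(1L)
}

#' Maximum common substructure of a molecule set
#'
#' Finds the largest connected substructure (by atom count) shared by all
#' input molecules, comparing atoms by element and bonds by order
#' (`bond_compare = "order"`, default) or by mere connectivity
#' (`"any"`). The search folds pairwise: the running common subgraph is
#' matched against each further molecule in turn. Each pairwise search is
#' a branch-and-bound backtracking over connected atom mappings with a
#' wall-clock deadline; on timeout the best mapping found so far is used
#' and the result is marked inexact.
#'
#' @param df Compound tibble (`id`, `canonical_smiles`) or character
#'   vector of canonical SMILES; at least 2 molecules.
#' @param timeout_s Deadline per pairwise search, seconds. Default 10.
#' @param bond_compare `"order"` or `"any"`.
#' @return Object of class `mcs_result`: list with `smarts` (element and
#'   any-bond pattern, matching every input molecule), `n_atoms`,
#'   `n_bonds`, `exact` flag, and `found` (`FALSE` when no common
#'   substructure of at least one atom exists, in which case `smarts` is
#'   empty).
#' @export
find_mcs <- function(df, timeout_s = 10, bond_compare = c("order", "any")) {
  bond_compare <- match.arg(bond_compare)
  if (is.character(df)) df <- tibble(id = df, canonical_smiles = df)
  check_columns(df, "canonical_smiles", "molecule set")
  if (nrow(df) < 2L) stop_domain("Need at least 2 molecules for an MCS.")
  graphs <- mol_graphs(df$canonical_smiles)
  graphs <- graphs[order(vapply(graphs, function(g) length(g$element), integer(1)))]
  common <- graphs[[1L]]
  exact <- TRUE
  for (i in 2L:length(graphs)) {
    deadline <- Sys.time() + timeout_s
    m <- mcgregor_mcs(common, graphs[[i]], bond_compare, deadline)
    exact <- exact && m$exact
    if (length(m$map_a) == 0L) {
      common <- NULL
      break
    }
    common <- mapped_subgraph(common, m$map_a)
  }
  if (is.null(common) || length(common$element) == 0L) {
    return(structure(
      list(smarts = "", n_atoms = 0L, n_bonds = 0L, exact = exact, found = FALSE),
      class = "mcs_result"
    ))
  }
  structure(
    list(
      smarts = graph_to_smarts(common),
      n_atoms = length(common$element),
      n_bonds = nrow(common$edges),
      exact = exact,
      found = TRUE
    ),
    class = "mcs_result"
  )
}

#' @export
print.mcs_result <- function(x, ...) {
  if (!x$found) {
    cat("<mcs_result> no common substructure\n")
  } else {
    cat(sprintf("<mcs_result> %d atoms, %d bonds%s\n  %s\n",
                x$n_atoms, x$n_bonds, if (x$exact) "" else " (timeout: may be sub-maximal)",
                x$smarts))
  }
  invisible(x)
}

#' Does an MCS pattern match the given molecules?
#'
#' @param mcs An [find_mcs()] result.
#' @param smiles Character vector of canonical SMILES.
#' @return Logical vector.
#' @export
mcs_matches <- function(mcs, smiles) {
  if (!mcs$found) return(rep(FALSE, length(smiles)))
  smarts_count(smiles, mcs$smarts) > 0L
}
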