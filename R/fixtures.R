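# Seeded synthetic fixtures: chemically valid compound tables drawn from a
# scaffold-decoration grammar, activity tables with a planted linear
# bit -> pIC50 signal, separated Gaussian blobs for clustering, and source
# maps with planted counts. Everything is deterministic under `seed`.

# Scaffold templates. Slots ("{n}") are substitution positions; every
# substituent is a complete branch, so any combination yields valid SMILES.
fixture_scaffolds <- function() {
  list(
    list(template = "c1{1}c{2}c{3}c{4}c{5}c1", slots = c("ar", "ar", "ar", "ar", "ar")),
    list(template = "O=c1c{1}c{2}c2c{3}c{4}c{5}c{6}c2o1",
         slots = c("ar", "ar", "ar", "ar", "ar", "ar")),
    list(template = "O=c1c{1}c{2}oc2c{3}c{4}c{5}c{6}c12",
         slots = c("ar", "aryl", "ar", "ar", "ar", "ar")),
    list(template = "O=C1C{1}C{2}Oc2c{3}c{4}c{5}c{6}c21",
         slots = c("al", "aryl", "ar", "ar", "ar", "ar")),
    list(template = "C{1}CC{2}CC{3}O", slots = c("al", "al", "al"))
  )
}

fixture_substituents <- function() {
  list(
    ar = c("", "", "", "(O)", "(O)", "(OC)", "(C)", "(C=O)", "(C(=O)O)", "(CC)"),
    al = c("", "", "(O)", "(C)"),
    aryl = c("", "(-c3ccccc3)", "(-c3ccc(O)cc3)", "(-c3ccc(O)c(O)c3)", "(O)", "(C)")
  )
}

draw_smiles <- function(n) {
  scaffolds <- fixture_scaffolds()
  subs <- fixture_substituents()
  vapply(seq_len(n), function(i) {
    sc <- scaffolds[[sample.int(length(scaffolds), 1L)]]
    s <- sc$template
    for (j in seq_along(sc$slots)) {
      choice <- sample(subs[[sc$slots[j]]], 1L)
      s <- sub(sprintf("{%d}", j), choice, s, fixed = TRUE)
    }
    s
  }, character(1))
}

#' Generate a synthetic compound table
#'
#' Draws compounds by random decoration of a small scaffold library
#' (benzene, benzopyranone, chromone/flavone, flavanone, short chains)
#' with hydroxyl, methoxy, methyl, aldehyde, carboxyl and aryl
#' substituents. The grammar only composes complete branches, so every
#' draw is a valid, canonicalizable structure with genuine shared
#' substructure across compounds.
#'
#' @param n_compounds Number of compounds (>= 1).
#' @param seed Integer seed; same seed, same table.
#' @return Compound tibble (`id`, `name`, `smiles`, `canonical_smiles`)
#'   ready for every reader in the package.
#' @export
generate_compounds <- function(n_compounds, seed = 1L) {
  if (n_compounds < 1L) stop_domain("`n_compounds` must be >= 1.")
  smiles <- withr_seed(seed, draw_smiles(n_compounds))
  df <- tibble(
    id = sprintf("NC%05d", seq_len(n_compounds)),
    name = sprintf("synthetic-%05d", seq_len(n_compounds)),
    smiles = smiles
  )
  parse_compounds(df)
}

#' Generate a synthetic activity table with planted signal
#'
#' Plants a linear structure-activity relationship in fingerprint space:
#' per target, `pIC50 = base + sum(weights over planted bits present) +
#' N(0, noise_sd)`, then `ic50_nm = 10^(9 - pIC50)`. Planted bits are
#' chosen among bits with intermediate prevalence (20-80%) so the signal
#' is identifiable; weights are drawn uniformly from
#' `[-weight_max, -weight_min] U [weight_min, weight_max]` and then
#' rescaled so the realized signal standard deviation equals `signal_sd`,
#' making the fixture's signal-to-noise ratio (`signal_sd / noise_sd`)
#' explicit rather than a draw-dependent accident.
#'
#' @param compounds Compound tibble from [generate_compounds()] (or any
#'   table with `id`, `canonical_smiles`).
#' @param targets Character vector of target names. Default `"TARGET1"`.
#' @param n_signal_bits Number of planted bits per target. Default 8.
#' @param weight_min,weight_max Absolute weight range in pIC50 units
#'   (before rescaling).
#' @param signal_sd Realized standard deviation of the planted signal in
#'   pIC50 units. Default 1 (a realistic potency spread for a ligand set
#'   spanning a few log units of IC50). Set to `NA` to keep raw weights.
#' @param base Baseline pIC50. Default 6.
#' @param noise_sd Gaussian noise SD in pIC50 units. Default 0.3.
#' @param n_bits,radius Fingerprint parameters.
#' @param seed Integer seed.
#' @return Activity tibble (`id`, `smiles`, `canonical_smiles`, `target`,
#'   `ic50_nm`, `pic50`), one row per compound x target; attribute
#'   `planted` is a list per target with `bits` and `weights`, attribute
#'   `fingerprints` the compound fingerprint matrix.
#' @export
generate_activities <- function(compounds, targets = "TARGET1",
                                n_signal_bits = 8L, weight_min = 0.3,
                                weight_max = 0.8, signal_sd = 1,
                                base = 6, noise_sd = 0.3,
                                n_bits = 2048L, radius = 2L, seed = 1L) {
  if (noise_sd < 0) stop_domain("`noise_sd` must be non-negative.")
  fp <- compute_fingerprints(compounds, n_bits = n_bits, radius = radius)
  prevalence <- colMeans(fp)
  eligible <- which(prevalence >= 0.2 & prevalence <= 0.8)
  if (length(eligible) < n_signal_bits) {
    eligible <- order(abs(prevalence - 0.5))[seq_len(max(n_signal_bits, 2L))]
  }
  # keep the planted design identifiable: bits must be linearly
  # independent of each other and of the intercept on this compound set
  pick_independent <- function(cand, k) {
    chosen <- integer(0)
    basis <- matrix(1, nrow = nrow(fp), ncol = 1L)
    for (b in cand) {
      if (length(chosen) >= k) break
      trial <- cbind(basis, fp[, b])
      if (qr(trial)$rank > qr(basis)$rank) {
        chosen <- c(chosen, b)
        basis <- trial
      }
    }
    chosen
  }
  out <- withr_seed(seed, {
    purrr::map_dfr(seq_along(targets), function(t_idx) {
      bits <- sort(pick_independent(sample(eligible), n_signal_bits))
      if (length(bits) < n_signal_bits) {
        stop_domain("Compound set too degenerate to plant an identifiable signal.")
      }
      weights <- runif(n_signal_bits, weight_min, weight_max) *
        sample(c(-1, 1), n_signal_bits, replace = TRUE)
      signal <- as.numeric(fp[, bits, drop = FALSE] %*% weights)
      if (is.finite(signal_sd) && sd(signal) > 0) {
        weights <- weights * signal_sd / sd(signal)
        signal <- signal * signal_sd / sd(signal)
      }
      pic50 <- base + signal + rnorm(nrow(fp), 0, noise_sd)
      tibble(
        id = as.character(compounds$id),
        smiles = compounds$smiles,
        canonical_smiles = compounds$canonical_smiles,
        target = targets[t_idx],
        ic50_nm = 10^(9 - pic50),
        pic50 = pic50,
        .planted_bits = list(bits),
        .planted_weights = list(weights)
      )
    })
  })
  planted <- out |>
    group_by(.data$target) |>
    summarise(bits = .data$.planted_bits[1], weights = .data$.planted_weights[1])
  out <- select(out, -".planted_bits", -".planted_weights")
  attr(out, "planted") <- setNames(
    purrr::map(seq_len(nrow(planted)), function(i) {
      list(bits = planted$bits[[i]], weights = planted$weights[[i]])
    }),
    planted$target
  )
  attr(out, "fingerprints") <- fp
  out
}

#' Generate a separated Gaussian blob fixture for clustering
#'
#' Blob centres sit on distinct vertices of a scaled hypercube lattice, so
#' any two centres are at least `separation * noise_sd` apart.
#'
#' @param k_blobs Number of blobs (>= 1, at most `2^n_features`).
#' @param n_per_blob Points per blob. Default 30.
#' @param n_features Feature dimension. Default 5.
#' @param separation Centre separation in units of `noise_sd`. Default 10.
#' @param noise_sd Within-blob SD. Default 1.
#' @param seed Integer seed.
#' @return List with `features` (matrix, rownames = ids) and `labels`
#'   (integer vector of true blob assignments).
#' @export
generate_cluster_fixture <- function(k_blobs = 6L, n_per_blob = 30L,
                                     n_features = 5L, separation = 10,
                                     noise_sd = 1, seed = 1L) {
  if (k_blobs < 1L) stop_domain("`k_blobs` must be >= 1.")
  if (k_blobs > 2^n_features) {
    stop_domain("`k_blobs` must not exceed 2^n_features (lattice vertices).")
  }
  centers <- t(vapply(seq_len(k_blobs) - 1L, function(j) {
    as.integer(intToBits(j))[seq_len(n_features)] * separation * noise_sd
  }, numeric(n_features)))
  labels <- rep(seq_len(k_blobs), each = n_per_blob)
  features <- withr_seed(seed, {
    centers[labels, , drop = FALSE] +
      matrix(rnorm(length(labels) * n_features, 0, noise_sd),
             ncol = n_features)
  })
  rownames(features) <- sprintf("P%05d", seq_along(labels))
  list(features = features, labels = labels)
}

#' Generate a source map with planted counts and intersection
#'
#' Builds a compound/food-source map in which each named source has
#' exactly the requested compound count and all sources share exactly
#' `n_common` compounds (every other compound belongs to one source
#' only), so top-source ranking and the full Venn intersection are known
#' by construction.
#'
#' @param counts Named integer vector: source name -> compound count.
#' @param n_common Size of the planted all-source intersection; at most
#'   `min(counts)`.
#' @param seed Unused (construction is deterministic); kept for interface
#'   symmetry.
#' @return A [source_map()]; attribute `planted` holds `counts` and
#'   `common_ids`.
#' @export
generate_source_map <- function(counts = c("black walnut" = 40, "safflower" = 37,
                                           "fig" = 32, "pepper" = 32,
                                           "corn" = 31, "ginger" = 31),
                                n_common = 25L, seed = 1L) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop_domain("`counts` must be a named vector.")
  }
  if (n_common > min(counts)) stop_domain("`n_common` cannot exceed min(counts).")
  common <- sprintf("COMMON%03d", seq_len(n_common))
  long <- purrr::map_dfr(seq_along(counts), function(i) {
    n_unique <- counts[[i]] - n_common
    ids <- c(common, sprintf("ONLY_%s_%03d", gsub("\\W+", "_", names(counts)[i]),
                             seq_len(n_unique)))
    tibble(id = ids, source = names(counts)[i])
  })
  m <- source_map(long)
  attr(m, "planted") <- list(counts = counts, common_ids = common)
  m
}
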