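test_that("activity tiers follow the printed inequalities and partition the line", {
  expect_equal(as.character(classify_activity(5.0)), "low")
  expect_equal(as.character(classify_activity(6.2)), "medium")
  expect_equal(as.character(classify_activity(7.0)), "medium")
  expect_equal(as.character(classify_activity(7.3)), "high")

  set.seed(2)
  x <- c(runif(500, -2, 12), 5, 7, 4.999999, 5.000001, 6.999999, 7.000001)
  cls <- classify_activity(x)
  expect_false(anyNA(cls))  # exactly one class for every finite value
  expect_true(all(cls[x <= 5] == "low"))
  expect_true(all(cls[x > 5 & x <= 7] == "medium"))
  expect_true(all(cls[x > 7] == "high"))

  expect_error(classify_activity(NaN), class = "ncscreen_domain_error")
  expect_error(classify_activity(Inf), class = "ncscreen_domain_error")
})

test_that("silhouette-led k selection recovers planted blob counts", {
  fx6 <- generate_cluster_fixture(k_blobs = 6, n_per_blob = 25, seed = 31)
  sel6 <- choose_k(fx6$features, 2:10, seed = 31)
  expect_equal(sel6$chosen_k, 6L)
  expect_false(sel6$no_structure)
  expect_true(all(c("k", "sse", "silhouette") %in% names(sel6$table)))

  fx2 <- generate_cluster_fixture(k_blobs = 2, n_per_blob = 40, seed = 32)
  sel2 <- choose_k(fx2$features, 2:6, seed = 32)
  expect_equal(sel2$chosen_k, 2L)

  # one tight blob: weak silhouette everywhere -> flagged
  one <- generate_cluster_fixture(k_blobs = 1, n_per_blob = 80, seed = 33)
  sel1 <- choose_k(one$features, 2:5, seed = 33)
  expect_true(sel1$no_structure)

  expect_error(choose_k(fx2$features, 1:5), class = "ncscreen_domain_error")
  expect_error(choose_k(fx2$features[1:4, ], 2:10), class = "ncscreen_domain_error")
})

test_that("k-means assignments are seeded, exhaustive and recover planted labels", {
  # two separated pairs -> two pure clusters
  pts <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  rownames(pts) <- paste0("p", 1:4)
  asg <- cluster_kmeans(pts, 2, seed = 1)
  expect_equal(asg$cluster[1], asg$cluster[2])
  expect_equal(asg$cluster[3], asg$cluster[4])
  expect_false(asg$cluster[1] == asg$cluster[3])
  expect_equal(nrow(asg), 4L)

  fx <- generate_cluster_fixture(k_blobs = 3, n_per_blob = 30, seed = 41)
  a1 <- cluster_kmeans(fx$features, 3, seed = 7)
  a2 <- cluster_kmeans(fx$features, 3, seed = 7)
  expect_identical(a1$cluster, a2$cluster)
  expect_gte(mclust::adjustedRandIndex(a1$cluster, fx$labels), 0.9)

  expect_error(cluster_kmeans(pts, 4, seed = 1), class = "ncscreen_domain_error")
})

test_that("SAR summaries conserve counts and match hand-computed statistics", {
  prof <- tibble::tibble(
    id = sprintf("m%d", 1:6),
    mol_wt = c(100, 110, 120, 300, 310, 320),
    log_p = c(1, 1.5, 2, 4, 4.5, 5),
    h_donors = c(1, 1, 2, 5, 5, 6),
    h_acceptors = c(2, 2, 3, 8, 8, 9),
    tpsa = c(40, 45, 50, 140, 145, 150),
    predicted_pic50 = c(6, 6.2, 6.4, 7.5, 7.6, 7.7)
  )
  asg <- tibble::tibble(id = prof$id, cluster = c(1L, 1L, 1L, 2L, 2L, 2L))
  fp <- matrix(rbinom(6 * 16, 1, 0.5), nrow = 6,
               dimnames = list(prof$id, NULL))

  out <- sar_summary(asg, prof, fingerprints = fp)
  mw1 <- out$summary[out$summary$cluster == 1 & out$summary$variable == "mol_wt", ]
  expect_equal(mw1$mean, 110)
  expect_equal(mw1$median, 110)
  expect_equal(mw1$sd, sd(c(100, 110, 120)))
  expect_true(all(out$summary$n == 3L))

  # conservation: per-cluster counts bounded by cluster size, rows sum to
  # within-cluster popcount totals, columns to the global bit counts
  expect_true(all(out$bit_freq <= 3))
  expect_equal(unname(rowSums(out$bit_freq)),
               unname(rowsum(rowSums(fp), asg$cluster)[, 1]))
  expect_equal(unname(colSums(out$bit_freq)), unname(colSums(fp)))

  # single cluster reproduces global statistics
  g <- sar_summary(dplyr::mutate(asg, cluster = 1L), prof)
  mwg <- g$summary[g$summary$variable == "mol_wt", ]
  expect_equal(mwg$mean, mean(prof$mol_wt))

  expect_error(sar_summary(asg[1:3, ], prof), class = "ncscreen_domain_error")
})

test_that("predicted potency is deterministic and memorizes distinctive actives", {
  # training set: aromatic scaffolds at pIC50 6, plus a structurally
  # distinct aliphatic ligand repeated at pIC50 8 (noise-free)
  arom <- small_compounds()[1:30, ]
  special <- parse_compounds(tibble::tibble(
    id = sprintf("sp%02d", 1:8), smiles = rep("CCCCCCCCCC(=O)O", 8)
  ))
  train <- dplyr::bind_rows(
    dplyr::mutate(arom[, c("id", "canonical_smiles")], pic50 = 6),
    dplyr::mutate(special[, c("id", "canonical_smiles")], pic50 = 8)
  )
  train$target <- "T"
  m <- train_qsar(train, num_trees = 200L, k_folds = 0L, seed = 6)

  cand <- parse_compounds(tibble::tibble(id = "probe", smiles = "CCCCCCCCCC(=O)O"))
  out <- predict_potency(m, cand)
  expect_equal(out$predicted_pic50, 8, tolerance = 0.5)
  expect_identical(out$predicted_pic50, predict_potency(m, cand)$predicted_pic50)

  # unparseable candidates are skipped, not fatal
  cand2 <- tibble::tibble(id = c("probe", "bad"),
                          canonical_smiles = c(cand$canonical_smiles, NA))
  expect_warning(out2 <- predict_potency(m, cand2), "parseable")
  expect_equal(nrow(out2), 1L)
  expect_equal(attr(out2, "n_skipped"), 1L)
})
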