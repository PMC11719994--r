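test_that("cosine similarity matches hand arithmetic and is symmetric", {
  expect_equal(cosine_similarity(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(cosine_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)  # 1/(sqrt2*sqrt2)

  set.seed(8)
  for (i in 1:20) {
    a <- rbinom(32, 1, 0.4); b <- rbinom(32, 1, 0.4)
    if (sum(a) == 0 || sum(b) == 0) next
    expect_identical(cosine_similarity(a, b), cosine_similarity(b, a))
    expect_gte(cosine_similarity(a, b), 0)
    expect_lte(cosine_similarity(a, b), 1)
  }

  expect_error(cosine_similarity(c(0, 0), c(1, 0)), class = "ncscreen_domain_error")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 1)), class = "ncscreen_domain_error")
})

test_that("candidate matching agrees with the exhaustive pairwise oracle", {
  set.seed(21)
  n_bits <- 64
  cand_fp <- matrix(rbinom(100 * n_bits, 1, 0.3), nrow = 100)
  active_fp <- matrix(rbinom(100 * n_bits, 1, 0.3), nrow = 100)
  cand_fp[rowSums(cand_fp) == 0, 1] <- 1L
  active_fp[rowSums(active_fp) == 0, 1] <- 1L
  rownames(cand_fp) <- sprintf("c%03d", 1:100)
  rownames(active_fp) <- sprintf("a%03d", 1:100)

  candidates <- tibble::tibble(id = rownames(cand_fp), canonical_smiles = "X")
  actives <- tibble::tibble(id = rownames(active_fp), canonical_smiles = "X",
                            target = "T1")

  res <- predict_candidates(candidates, actives, threshold = 0.5,
                            candidate_fp = cand_fp, active_fp = active_fp)
  oracle <- oracle_match(cand_fp, active_fp, 0.5)

  res_ordered <- res[match(sprintf("c%03d", oracle$cand), res$id), ]
  expect_equal(res_ordered$best_similarity, oracle$best_similarity, tolerance = 1e-12)
  expect_equal(res_ordered$is_hit, oracle$is_hit)
  expect_equal(res_ordered$matched_ligand, sprintf("a%03d", oracle$matched))

  # raising the threshold can only shrink the hit set
  hits_at <- function(th) {
    r <- predict_candidates(candidates, actives, threshold = th,
                            candidate_fp = cand_fp, active_fp = active_fp)
    r$id[r$is_hit]
  }
  h <- lapply(c(0.3, 0.5, 0.7, 0.9), hits_at)
  for (i in 2:4) expect_true(all(h[[i]] %in% h[[i - 1]]))
})

test_that("toy matches behave at the boundaries and sort stably", {
  fp <- rbind(a = c(1, 1, 0, 0, 1, 0, 0, 0),
              b = c(0, 0, 1, 1, 0, 0, 1, 0),
              c = c(1, 1, 0, 0, 1, 0, 0, 0))
  cand <- tibble::tibble(id = c("a", "b", "c"), canonical_smiles = "X")
  act <- tibble::tibble(id = c("act1", "act2"), canonical_smiles = "X",
                        target = "T1")
  act_fp <- rbind(c(1, 1, 0, 0, 1, 0, 0, 0), c(0, 0, 0, 0, 0, 1, 1, 1))

  res <- predict_candidates(cand, act, candidate_fp = fp, active_fp = act_fp)
  expect_equal(res$best_similarity[res$id == "a"], 1)
  expect_true(res$is_hit[res$id == "a"])
  # candidate b shares one bit of three with act2: below threshold
  expect_false(res$is_hit[res$id == "b"])
  # ties (a and c identical) resolve by id
  expect_equal(res$id[1:2], c("a", "c"))

  # exactly at the threshold is not a hit (strictly greater rule)
  at <- predict_candidates(
    tibble::tibble(id = "x", canonical_smiles = "X"),
    tibble::tibble(id = "y", canonical_smiles = "X", target = "T"),
    threshold = 0.5,
    candidate_fp = matrix(c(1, 1, 0, 0), 1), active_fp = matrix(c(1, 0, 1, 0), 1)
  )
  expect_equal(at$best_similarity, 0.5)
  expect_false(at$is_hit)

  expect_error(
    predict_candidates(cand, act[0, ], candidate_fp = fp, active_fp = act_fp[0, , drop = FALSE]),
    class = "ncscreen_domain_error"
  )
})

test_that("recall counts recovered positives", {
  results <- tibble::tibble(
    id = sprintf("c%d", 1:10), target = "T",
    is_hit = c(rep(TRUE, 7), rep(FALSE, 3))
  )
  truth <- tibble::tibble(id = sprintf("c%d", 1:10), target = "T", label = 1)
  expect_equal(recall_score(results, truth), 0.7)

  truth4 <- tibble::tibble(id = sprintf("c%d", 1:4), target = "T", label = 1)
  res4 <- tibble::tibble(id = sprintf("c%d", 1:4), target = "T",
                         is_hit = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(recall_score(res4, truth4), 0.75)
  expect_equal(recall_score(dplyr::mutate(res4, is_hit = TRUE), truth4), 1)

  expect_error(recall_score(res4, dplyr::mutate(truth4, label = 0)),
               class = "ncscreen_domain_error")
  expect_error(recall_score(res4, truth4[1:2, ]), class = "ncscreen_domain_error")
})
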