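test_that("canonicalization maps equivalent encodings to one string and is idempotent", {
  expect_identical(canon("C1=CC=CC=C1"), canon("c1ccccc1"))
  expect_identical(canon("OCC"), canon("CCO"))
  expect_false(canon("c1ccccc1") == canon("C1CCCCC1"))

  # idempotence over the embedded panel and generated fixtures
  smis <- c(flavonoid_panel()$smiles, head(small_compounds()$smiles, 20))
  once <- canon(smis)
  expect_identical(canon(once), once)
})

test_that("unparseable SMILES become NA and are skipped with a report", {
  expect_true(is.na(canon("C1CC")))

  df <- tibble::tibble(
    id = c("a", "b", "c"),
    smiles = c("CCO", "C1CC", "c1ccccc1")
  )
  expect_warning(out <- parse_compounds(df), "unparseable")
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_skipped"), 1L)
  expect_equal(attr(out, "skipped")$row, 2L)
  expect_equal(attr(out, "skipped")$id, "b")
})

test_that("salts are stripped to the largest organic fragment by default", {
  expect_identical(canon("CCO.[Na]"), canon("CCO"))
  expect_identical(canonicalize_smiles("c1ccccc1.Cl")[1],
                   canonicalize_smiles("c1ccccc1")[1])
  # opt out keeps the salt intact
  expect_true(grepl("\\.", canonicalize_smiles("CCO.[Na]", strip_salts = FALSE)))
})

test_that("compound table reader enforces schema and reports skips", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "a,CCO", "b,c1ccccc1", "c,CC(C)=O"), f)
  out <- read_compound_table(f)
  expect_equal(nrow(out), 3L)
  expect_true(all(!is.na(out$canonical_smiles)))

  writeLines(c("id,smiles", "a,CCO", "b,C1CC", "c,CC(C)=O"), f)
  expect_warning(out <- read_compound_table(f), "unparseable")
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_skipped"), 1L)

  writeLines(c("id,structure", "a,CCO"), f)
  expect_error(read_compound_table(f), "smiles", class = "ncscreen_config_error")

  writeLines("id,smiles", f)
  expect_warning(out <- read_compound_table(f), "no rows")
  expect_equal(nrow(out), 0L)
})

test_that("activity tables require target and ic50 and gain derived pIC50", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,target,ic50_nm", "a,CCO,AChE,1000", "b,c1ccccc1,AChE,10"), f)
  out <- read_compound_table(f, kind = "activities")
  expect_equal(out$pic50, c(6, 8))

  writeLines(c("id,smiles", "a,CCO"), f)
  expect_error(read_compound_table(f, kind = "activities"), "target")
})

test_that("sources cells split into normalized sets and round-trip through CSV", {
  df <- tibble::tibble(
    id = c("a", "b"), smiles = c("CCO", "CC=O"),
    sources = c(" Black Walnut ; fig", "")
  )
  out <- parse_compounds(df)
  expect_equal(out$sources[[1]], c("black walnut", "fig"))
  expect_equal(out$sources[[2]], character(0))

  f <- withr::local_tempfile(fileext = ".csv")
  write_compound_table(out, f)
  back <- read_compound_table(f)
  expect_equal(back$sources[[1]], c("black walnut", "fig"))
})

test_that("descriptors match reference values for known molecules", {
  d <- compute_descriptors(flavonoid_panel())
  quercetin <- d[d$id == "quercetin", ]
  expect_equal(quercetin$tpsa, 131.36, tolerance = 1e-6)
  expect_equal(quercetin$h_donors, 5L)
  expect_equal(quercetin$h_acceptors, 7L)
  expect_equal(d$mol_wt[d$id == "coumarin"], 146.145, tolerance = 1e-4)

  # molecular weight additivity: ethanol C2H6O from standard atomic weights
  eth <- compute_descriptors(tibble::tibble(id = "eth", smiles = "CCO"))
  expect_equal(eth$mol_wt, 2 * 12.011 + 6 * 1.008 + 15.999, tolerance = 0.01)
})

test_that("descriptors satisfy non-negativity invariants on generated structures", {
  d <- compute_descriptors(head(small_compounds(), 25))
  expect_true(all(d$mol_wt > 0))
  expect_true(all(d$h_donors >= 0))
  expect_true(all(d$h_acceptors >= 0))
  expect_true(all(d$tpsa >= 0))
})
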