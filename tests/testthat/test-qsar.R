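test_that("pIC50 conversion matches the defining formula and inverts exactly", {
  expect_equal(ic50_to_pic50(1000), 6)
  expect_equal(ic50_to_pic50(1), 9)
  expect_equal(ic50_to_pic50(50), 9 - log10(50))

  set.seed(42)
  x <- 10^runif(1e4, -3, 6)  # 1 pM .. 1 mM in nM units
  expect_lt(max(abs(pic50_to_ic50(ic50_to_pic50(x)) - x) / x), 1e-6)

  # strictly decreasing
  a <- 10^runif(500, -3, 6); b <- a * (1 + runif(500, 0.01, 2))
  expect_true(all(ic50_to_pic50(b) < ic50_to_pic50(a)))

  expect_error(ic50_to_pic50(0), class = "ncscreen_domain_error")
  expect_error(ic50_to_pic50(-5), class = "ncscreen_domain_error")
  expect_error(ic50_to_pic50(Inf), class = "ncscreen_domain_error")
})

test_that("train/test split is a seeded disjoint partition with rounded sizes", {
  df <- tibble::tibble(i = 1:100)
  parts <- split_dataset(df, 0.8, seed = 7)
  expect_equal(nrow(parts$train), 80L)
  expect_equal(nrow(parts$test), 20L)
  expect_setequal(c(parts$train$i, parts$test$i), 1:100)
  expect_length(intersect(parts$train$i, parts$test$i), 0L)

  small <- split_dataset(tibble::tibble(i = 1:5), 0.8, seed = 1)
  expect_equal(nrow(small$train), 4L)
  expect_equal(nrow(small$test), 1L)

  expect_identical(split_dataset(df, 0.8, seed = 7), parts)
  expect_error(split_dataset(df[1, ], 0.8), class = "ncscreen_domain_error")
})

test_that("regression metrics agree with hand arithmetic and rmse^2 == mse", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(m$mse, m$mae, m$r2), c(0, 0, 1))

  m <- regression_metrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(c(m$mse, m$mae), c(1, 1))

  m <- regression_metrics(c(5, 6, 7), c(5, 7, 7))
  expect_equal(m$mse, 1 / 3)
  expect_equal(m$mae, 1 / 3)

  set.seed(1)
  for (i in 1:10) {
    m <- regression_metrics(rnorm(50), rnorm(50))
    expect_equal(m$rmse^2, m$mse, tolerance = 1e-12)
  }
  expect_error(regression_metrics(numeric(0), numeric(0)),
               class = "ncscreen_domain_error")
})

test_that("residual cutoff equals the interpolated quantile oracle", {
  expect_equal(residual_cutoff(1:10, 0.95), 9.55)
  expect_equal(residual_cutoff(1:10, 0.95), oracle_quantile(1:10, 0.95))

  expect_equal(residual_cutoff(rep(2.5, 40), 0.95), 2.5)

  set.seed(11)
  for (i in 1:5) {
    r <- runif(1000)
    cut <- residual_cutoff(r, 0.95)
    expect_equal(cut, oracle_quantile(r, 0.95), tolerance = 1e-12)
    expect_gte(sum(r <= cut), 950)  # quantile definition retains >= 95%
  }

  expect_error(residual_cutoff(numeric(0)), class = "ncscreen_domain_error")
  expect_error(residual_cutoff(1:10, 1.0), class = "ncscreen_domain_error")
  expect_error(residual_cutoff(c(-1, 2)), class = "ncscreen_domain_error")
})

test_that("applicability filter stages match brute-force recomputation", {
  acts <- small_activities()
  model <- small_model()

  # craft a 20-record set with 4 records below the pIC50 floor
  sub <- acts[1:20, ]
  sub$pic50 <- c(rep(4.2, 4), seq(5.1, 7.9, length.out = 16))
  sub$ic50_nm <- pic50_to_ic50(sub$pic50)

  out <- filter_applicability(sub, model, q = 0.95, pic50_min = 5)
  rep <- attr(out, "report")
  expect_equal(rep$n_input, 20L)
  expect_equal(rep$n_after_pic50, 16L)

  # brute-force: recompute residuals and the oracle quantile independently
  stage1 <- sub[sub$pic50 >= 5, ]
  res <- abs(stage1$pic50 - unname(predict(model, stage1)))
  cut <- oracle_quantile(res, 0.95)
  expect_equal(rep$cutoff, cut, tolerance = 1e-12)
  expect_equal(rep$n_retained, sum(res <= cut))
  expect_gte(rep$n_retained, ceiling(0.95 * 16) - 1L)

  expect_error(filter_applicability(sub, model, q = 1.0),
               class = "ncscreen_domain_error")
})

test_that("the model learns a planted signal and beats chance held out", {
  acts <- noisefree_activities()  # n = 150, noise-free linear bit signal
  parts <- split_dataset(acts, 0.8, seed = 5)
  model <- evaluate_model(
    train_qsar(parts$train, num_trees = 200L, k_folds = 5L, seed = 5),
    parts$test
  )
  expect_gt(model$test_metrics$r2, 0.5)
  expect_equal(model$test_metrics$rmse, sqrt(model$test_metrics$mse), tolerance = 1e-12)
  expect_equal(nrow(model$cv_metrics), 5L)

  # the least-squares oracle on the planted features is the upper bound;
  # the forest must land within striking distance of it
  pl <- attr(acts, "planted")[[1]]
  fp <- attr(acts, "fingerprints")
  d <- data.frame(y = acts$pic50, fp[, pl$bits, drop = FALSE])
  tri <- match(parts$train$id, acts$id)
  fit <- lm(y ~ ., d[tri, ])
  pr <- predict(fit, d[-tri, ])
  oracle_r2 <- 1 - sum((d$y[-tri] - pr)^2) / sum((d$y[-tri] - mean(d$y[-tri]))^2)
  expect_gt(oracle_r2, 0.99)  # noise-free: oracle is essentially exact
  expect_gt(model$test_metrics$r2, oracle_r2 - 0.5)
})

test_that("degenerate and repeated fits behave deterministically", {
  acts <- small_activities()[1:30, ]
  const <- dplyr::mutate(acts, pic50 = 6)
  m <- train_qsar(const, num_trees = 50L, k_folds = 0L, seed = 9)
  expect_equal(unname(predict(m, const[1:5, ])), rep(6, 5))

  m1 <- train_qsar(acts, num_trees = 50L, k_folds = 0L, seed = 4)
  m2 <- train_qsar(acts, num_trees = 50L, k_folds = 0L, seed = 4)
  expect_identical(predict(m1, acts), predict(m2, acts))

  mixed <- dplyr::mutate(acts, target = rep(c("A", "B"), length.out = nrow(acts)))
  expect_error(train_qsar(mixed), "one target", class = "ncscreen_domain_error")
  expect_error(train_qsar(acts[1:3, ], k_folds = 5L), class = "ncscreen_domain_error")
})

test_that("PCA projection reports variance structure correctly", {
  # rank-1 data: first component carries ~all variance
  t_line <- seq(-5, 5, length.out = 40)
  line3d <- cbind(t_line, 2 * t_line, -t_line) +
    matrix(rnorm(120, sd = 1e-8), ncol = 3)
  pr <- pca_projection(line3d, 2)
  expect_gt(attr(pr, "explained_variance")[1], 0.999)

  # isotropic 2-D Gaussian: both components near 50%, matching the
  # covariance eigenvalue decomposition
  set.seed(3)
  g <- matrix(rnorm(2000), ncol = 2)
  pr <- pca_projection(g, 2)
  ev <- attr(pr, "explained_variance")
  expect_equal(ev[1], 0.5, tolerance = 0.1)
  eig <- eigen(stats::cov(g))$values
  expect_equal(ev, eig / sum(eig), tolerance = 1e-10)
  expect_true(ev[1] >= ev[2])

  # duplicating every row changes nothing about the variance split
  pr2 <- pca_projection(rbind(g, g), 2)
  expect_equal(attr(pr2, "explained_variance"), ev, tolerance = 1e-10)

  expect_error(pca_projection(g[1, , drop = FALSE], 2),
               class = "ncscreen_domain_error")
})

test_that("tidy and glance expose fold metrics and the one-row summary", {
  m <- small_model()
  g <- glance(m)
  expect_equal(nrow(g), 1L)
  expect_equal(g$target, "AChE")
  expect_equal(g$test_rmse, m$test_metrics$rmse)
  td <- tidy(train_qsar(small_activities()[1:40, ], num_trees = 50L,
                        k_folds = 4L, seed = 2))
  expect_equal(nrow(td), 4L)
  expect_true(all(c("fold", "mse", "r2", "mae", "rmse") %in% names(td)))
})
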