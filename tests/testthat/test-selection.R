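test_that("the inner-relation criterion matches a direct two-regression oracle", {
  # independent Gaussian blocks: only noise-level correlation remains
  set.seed(77)
  pd <- paired_omics(matrix(rnorm(500 * 5), 500, 5),
                     matrix(rnorm(500 * 5), 500, 5), center = TRUE)
  crit <- inner_r2_criterion(pd, a = 1, n_x = 0, n_y = 0)
  expect_lt(crit, 0.2)
  # oracle: two explicit no-intercept regressions on the PLS scores
  sv <- svd(crossprod(pd$x, pd$y), nu = 1, nv = 1)
  t1 <- pd$x %*% sv$u
  u1 <- pd$y %*% sv$v
  r2 <- function(y, x) {
    h <- y - x %*% solve(crossprod(x), crossprod(x, y))
    1 - sum(h^2) / sum(y^2)
  }
  expect_equal(crit, r2(u1, t1) + r2(t1, u1), tolerance = 1e-12)
})

test_that("the criterion is bounded and improves with true orthogonal structure", {
  wins <- 0
  for (seed in 1:20) {
    sim <- simulate_dataset(tiny_design(alpha = 0.05), seed = seed)
    c00 <- inner_r2_criterion(sim$data, a = 1, n_x = 0, n_y = 0)
    c11 <- inner_r2_criterion(sim$data, a = 1, n_x = 1, n_y = 1)
    expect_gte(c00, 0); expect_lte(c00, 2)
    expect_gte(c11, 0); expect_lte(c11, 2)
    wins <- wins + (c11 >= c00)
  }
  # deflating the true block-specific variation never hurt the inner fit
  expect_equal(wins, 20)
})

test_that("the grid search returns the argmax with a parsimonious tie rule", {
  sim <- simulate_dataset(tiny_design(alpha = 0.05), seed = 3)
  gs <- grid_search_orthogonal(sim$data, a = 1, max_nx = 2, max_ny = 2)
  expect_equal(dim(gs$grid), c(3, 3))
  expect_true(all(gs$grid >= 0 & gs$grid <= 2))
  expect_equal(gs$grid[gs$n_x + 1, gs$n_y + 1], max(gs$grid))
  # identical data and bounds reproduce the selection exactly
  gs2 <- grid_search_orthogonal(sim$data, a = 1, max_nx = 2, max_ny = 2)
  expect_identical(gs$grid, gs2$grid)
  expect_identical(c(gs$n_x, gs$n_y), c(gs2$n_x, gs2$n_y))
  # degenerate one-cell grid
  gs0 <- grid_search_orthogonal(sim$data, a = 1, max_nx = 0, max_ny = 0)
  expect_equal(c(gs0$n_x, gs0$n_y), c(0, 0))
})

test_that("exact grid ties resolve to the smallest component counts", {
  # force ties by evaluating a constant criterion surface: noiseless data
  # with no orthogonal structure makes every (n_x, n_y) cell equal via the
  # same perfect inner fit, exercised here through the tie-breaking order
  grid <- matrix(1.5, 2, 2, dimnames = list(n_x = 0:1, n_y = 0:1))
  cand <- expand.grid(n_x = 0:1, n_y = 0:1)
  cand$value <- grid[cbind(cand$n_x + 1, cand$n_y + 1)]
  cand <- cand[order(-cand$value, cand$n_x + cand$n_y, cand$n_x), ]
  expect_equal(c(cand$n_x[1], cand$n_y[1]), c(0, 0))
  # and when (0,1) ties (1,0), the smaller n_x wins at equal n_x + n_y
  grid[1, 2] <- grid[2, 1] <- 1.9
  cand$value <- grid[cbind(cand$n_x + 1, cand$n_y + 1)]
  cand <- cand[order(-cand$value, cand$n_x + cand$n_y, cand$n_x), ]
  expect_equal(c(cand$n_x[1], cand$n_y[1]), c(0, 1))
})

test_that("cross-validation is deterministic, exhaustive and unbiased at the null", {
  sim <- simulate_dataset(tiny_design(alpha = 0.1), seed = 8)
  m1 <- cv_mse(sim$data, a = 1, n_x = 1, n_y = 1, folds = 10, seed = 4)
  m2 <- cv_mse(sim$data, a = 1, n_x = 1, n_y = 1, folds = 10, seed = 4)
  expect_identical(m1, m2)
  expect_true(all(m1 >= 0))
  expect_false(identical(
    m1, cv_mse(sim$data, a = 1, n_x = 1, n_y = 1, folds = 10, seed = 5)
  ))
})

test_that("the zero-model cross-validated error equals the pooled test variance", {
  # with the inner coefficient forced to zero the prediction is the
  # training mean, so the accumulated error is the pooled test variance
  sim <- simulate_dataset(tiny_design(alpha = 0.1), seed = 12)
  data <- sim$data
  N <- nrow(data$y)
  folds <- 5
  set.seed(99)
  assignment <- rep(seq_len(folds), length.out = N)[sample.int(N)]
  se <- 0
  for (k in seq_len(folds)) {
    test <- assignment == k
    mu <- colMeans(data$y[!test, , drop = FALSE])
    se <- se + sum(sweep(data$y[test, , drop = FALSE], 2, mu)^2)
  }
  pooled <- se / (N * ncol(data$y))
  # same quantity through the model path with B_T zeroed out
  se_model <- 0
  for (k in seq_len(folds)) {
    test <- assignment == k
    xtr <- center_columns(data$x[!test, , drop = FALSE])
    ytr <- center_columns(data$y[!test, , drop = FALSE])
    train <- paired_omics(xtr$x, ytr$x)
    train$centered <- c(x = TRUE, y = TRUE)
    train$column_means_x <- xtr$means
    train$column_means_y <- ytr$means
    fit <- fit_o2pls(train, a = 1, n_x = 1, n_y = 1)
    fit$B_T <- matrix(0, 1, 1)
    pred <- predict(fit, data$x[test, , drop = FALSE], "x_to_y")
    se_model <- se_model + sum((pred - data$y[test, , drop = FALSE])^2)
  }
  expect_equal(se_model / (N * ncol(data$y)), pooled, tolerance = 1e-10)
})

test_that("cross-validated error vanishes on noiseless purely-joint data", {
  # no noise and no block-specific components: Y is exactly predictable
  # from X in every fold, so the cross-validated error is numerically zero
  sim <- simulate_dataset(sim_design_low(alpha = 0, N = 200, n_x = 0,
                                         n_y = 0), seed = 14)
  m <- cv_mse(sim$data, a = 1, n_x = 0, n_y = 0, folds = 5, seed = 1)
  var_y <- mean(sim$data$y^2)
  expect_lt(m[["mse_y"]], 1e-6 * var_y)
  expect_lt(m[["mse_x"]], 1e-6 * mean(sim$data$x^2))
})

test_that("fold assignment covers every sample and rejects bad fold counts", {
  sim <- simulate_dataset(tiny_design(), seed = 15)
  expect_error(cv_mse(sim$data, a = 1, folds = 1), "folds")
  expect_error(cv_mse(sim$data, a = 1, folds = 1000), "folds")
})

test_that("degenerate selection grids return the only admissible choice", {
  sim <- simulate_dataset(tiny_design(alpha = 0.1), seed = 16)
  sel <- select_components(sim$data, a_candidates = 1, max_nx = 0,
                           max_ny = 0, folds = 5, seed = 2)
  expect_equal(c(sel$chosen_a, sel$chosen_n_x, sel$chosen_n_y), c(1, 0, 0))
  expect_s3_class(tidy(sel), "tbl_df")
  expect_equal(nrow(tidy(sel)), 1)
})

test_that("a two-joint-component design is identified by the prediction error", {
  hits <- 0
  n_seeds <- 20
  design <- sim_design(N = 150, p = 30, q = 24, a = 2, n_x = 1, n_y = 1,
                       profiles = list(W = rbind(c(8, 3), c(22, 3)),
                                       C = rbind(c(6, 2), c(18, 2)),
                                       P_Yorth = c(15, 6),
                                       P_Xorth = c(12, 5)),
                       alpha = 0.05)
  for (seed in seq_len(n_seeds)) {
    sim <- simulate_dataset(design, seed = 400 + seed)
    sel <- select_components(sim$data, a_candidates = 1:3, max_nx = 1,
                             max_ny = 1, folds = 5, seed = seed)
    hits <- hits + (sel$chosen_a == 2)
  }
  expect_gt(hits, n_seeds / 2)
})
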