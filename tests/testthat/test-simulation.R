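test_that("loading profiles are normal density values over the variable index", {
  expect_equal(loading_profile(1, mu = 1, sigma = 5), 1.0)
  # standard-normal density at -1, 0, 1 (textbook values)
  expect_equal(loading_profile(3, mu = 2, sigma = 1, normalize = FALSE),
               dnorm(c(-1, 0, 1)), tolerance = 1e-12)
  expect_equal(round(loading_profile(3, 2, 1, normalize = FALSE), 5),
               c(0.24197, 0.39894, 0.24197))
  # reference X-block profile is symmetric about its mode
  w <- loading_profile(100, mu = 60, sigma = 10)
  expect_equal(w[50], w[70], tolerance = 1e-12)
  expect_equal(which.max(w), 60)
  expect_equal(sum(w^2), 1, tolerance = 1e-12)
  expect_error(loading_profile(10, 5, 0), "spread")
  expect_error(loading_profile(10, 5, -1), "spread")
})

test_that("noise variances follow the calibration formulas", {
  expect_equal(unlist(noise_variances(sim_design_low(alpha = 0))),
               c(var_e = 0, var_f = 0, var_h = 0))
  # alpha-explicit check of all three formulas at alpha = 0.5
  d <- sim_design_low(alpha = 0.5)
  nv <- noise_variances(d)
  ratio <- 0.5 / 0.5
  expect_equal(nv$var_e, ratio * (1 * 1 + 1 * 1) / 100)
  expect_equal(nv$var_h, ratio * 4 * 1)
  expect_equal(nv$var_f, ratio * (1 * (4 + nv$var_h) + 1) / 50)
  expect_error(sim_design_low(alpha = 1), "alpha")
  expect_error(sim_design_low(alpha = -0.1), "alpha")
})

test_that("datasets are reproducible and noiseless data has the model rank", {
  d <- tiny_design(alpha = 0.1)
  s1 <- simulate_dataset(d, seed = 5)
  s2 <- simulate_dataset(d, seed = 5)
  expect_identical(s1$data$x, s2$data$x)
  expect_identical(s1$data$y, s2$data$y)
  expect_identical(s1$truth$W, s2$truth$W)
  s3 <- simulate_dataset(d, seed = 6)
  expect_false(identical(s1$data$x, s3$data$x))

  s0 <- simulate_dataset(sim_design_low(alpha = 0), seed = 7)
  sv <- svd(s0$data$x)$d
  expect_lt(sv[3] / sv[1], 1e-10)  # rank <= a + n_x = 2
})

test_that("the realized noise share matches the calibration target", {
  s <- simulate_dataset(sim_design_low(alpha = 0.05), seed = 8)
  expect_lt(abs(sum(s$truth$E^2) / sum(s$data$x^2) - 0.05), 0.01)
  expect_lt(abs(sum(s$truth$F^2) / sum(s$data$y^2) - 0.05), 0.01)
})

test_that("sign correction aligns estimates with the truth columnwise", {
  set.seed(9)
  truth <- matrix(rnorm(12), 6, 2)
  expect_equal(sign_correct(-truth, truth), truth, ignore_attr = TRUE)
  expect_equal(sign_correct(truth, truth), truth, ignore_attr = TRUE)
  # orthogonal estimate (zero cross-product) is left unchanged
  est <- matrix(c(1, 0, 0, 0, 0, 0), 6, 1)
  tr <- matrix(c(0, 1, 0, 0, 0, 0), 6, 1)
  expect_equal(sign_correct(est, tr), est, ignore_attr = TRUE)
  expect_error(sign_correct(truth, truth[, 1, drop = FALSE]), "shape")
})

test_that("replicate studies summarize and reproduce deterministically", {
  d <- tiny_design(alpha = 0.05)
  st1 <- run_study(d, replicates = 3, base_seed = 30)
  st2 <- run_study(d, replicates = 3, base_seed = 30)
  expect_identical(st1$summaries, st2$summaries)
  expect_equal(st1$n_failed, 0)
  expect_equal(dim(st1$summaries$W$bias), dim(st1$truth$W))
  expect_equal(dim(st1$summaries$P_Xorth$mean), dim(st1$truth$P_Xorth))

  # a single replicate collapses the quartiles onto the single estimate
  st <- run_study(d, replicates = 1, base_seed = 40)
  expect_equal(st$summaries$W$q25, st$summaries$W$median)
  expect_equal(st$summaries$W$q75, st$summaries$W$median)
  expect_equal(st$summaries$W$mean, st$summaries$W$median)

  td <- tidy(st1)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$factor), c("W", "C", "P_Yorth", "P_Xorth"))
  expect_equal(nrow(td), 24 + 18 + 24 + 18)
})

test_that("the true bias ratio between noise levels is bounded once resolved", {
  # at 100 replicates the max-|bias| statistic is dominated by Monte-Carlo
  # error of the replicate mean (which scales with the noise level); 300
  # replicates resolve the systematic bias itself, whose degradation under
  # tenfold noise stays within a factor of three
  st_low <- run_study(sim_design_low(alpha = 0.05), replicates = 300,
                      base_seed = 9000)
  st_high <- run_study(sim_design_low(alpha = 0.5), replicates = 300,
                       base_seed = 9500)
  ratio <- max(abs(st_high$summaries$W$bias)) /
    max(abs(st_low$summaries$W$bias))
  expect_lt(ratio, 3)
})

test_that("joint loadings stay accurate in low and high dimensions alike", {
  st_low <- run_study(sim_design_low(alpha = 0.05), replicates = 30,
                      base_seed = 100)
  st_high <- run_study(sim_design_high(alpha = 0.05), replicates = 30,
                       base_seed = 100)
  b_low <- max(abs(st_low$summaries$W$bias))
  b_high <- max(abs(st_high$summaries$W$bias))
  expect_lt(b_low, 0.02)
  expect_lt(b_high, 0.02)
  ratio <- b_high / b_low
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})
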