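test_that("noiseless model-exact data is recovered at machine precision", {
  sim <- simulate_dataset(sim_design_low(alpha = 0, N = 200), seed = 11,
                          exact_orthogonality = TRUE)
  fit <- fit_o2pls(sim$data, a = 1, n_x = 1, n_y = 1)
  expect_lt(principal_angle(fit$W, sim$truth$W), 1e-6)
  expect_lt(principal_angle(fit$C, sim$truth$C), 1e-6)
  expect_lt(principal_angle(fit$P_Yorth, sim$truth$P_Yorth), 1e-6)
  expect_lt(principal_angle(fit$P_Xorth, sim$truth$P_Xorth), 1e-6)
  expect_lt(sum(fit$E^2) / sum(sim$data$x^2), 1e-10)
  expect_lt(sum(fit$F^2) / sum(sim$data$y^2), 1e-10)
})

test_that("with no orthogonal components the fit equals plain two-block PLS", {
  pd <- random_paired(21)
  fit <- fit_o2pls(pd, a = 2, n_x = 0, n_y = 0)
  sv <- svd(crossprod(pd$x, pd$y), nu = 2, nv = 2)
  for (j in 1:2) {
    # equal up to the deterministic sign convention
    s <- sign(sum(sv$u[, j] * fit$W[, j]))
    expect_equal(fit$W[, j], s * sv$u[, j], tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(fit$C[, j], s * sv$v[, j], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_equal(fit$T, pd$x %*% fit$W, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fit$U, pd$y %*% fit$C, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fit$singular_values, sv$d[1:2], tolerance = 1e-12)
})

test_that("every fit satisfies the model invariants", {
  for (seed in 1:5) {
    sim <- simulate_dataset(tiny_design(alpha = 0.2), seed = seed)
    fit <- fit_o2pls(sim$data, a = 1, n_x = 1, n_y = 1)
    # orthonormal loading factors
    for (m in list(fit$W, fit$C, fit$W_Yorth, fit$C_Xorth)) {
      expect_lt(max(abs(crossprod(m) - diag(ncol(m)))), 1e-10)
    }
    expect_true(all(diff(fit$singular_values) <= 0))
    expect_true(all(fit$singular_values >= 0))
    # reconstruction identities
    xhat <- tcrossprod(fit$T, fit$W) + tcrossprod(fit$T_Yorth, fit$P_Yorth) +
      fit$E
    yhat <- tcrossprod(fit$U, fit$C) + tcrossprod(fit$U_Xorth, fit$P_Xorth) +
      fit$F
    expect_lt(sum((xhat - sim$data$x)^2) / sum(sim$data$x^2), 1e-16)
    expect_lt(sum((yhat - sim$data$y)^2) / sum(sim$data$y^2), 1e-16)
    # inner residual definitions hold by construction
    expect_identical(fit$H_UT, fit$U - fit$T %*% fit$B_T)
    expect_identical(fit$H_TU, fit$T - fit$U %*% fit$B_U)
  }
})

test_that("one low-noise replicate recovers the joint X loadings elementwise", {
  sim <- simulate_dataset(sim_design_low(alpha = 0.05), seed = 101)
  fit <- fit_o2pls(sim$data, a = 1, n_x = 1, n_y = 1)
  w_hat <- sign_correct(fit$W, sim$truth$W)
  expect_lt(max(abs(w_hat - sim$truth$W)), 0.05)
})

test_that("component bounds and centering are enforced", {
  pd <- random_paired(31, N = 20, p = 6, q = 5)
  expect_error(fit_o2pls(pd, a = 6), "component count")
  expect_error(fit_o2pls(pd, a = 2, n_x = 5), "component count")
  expect_error(fit_o2pls(pd, a = 2, n_y = 4), "component count")
  raw <- paired_omics(matrix(rnorm(60) + 5, 20, 3),
                      matrix(rnorm(60) + 3, 20, 3))
  expect_error(fit_o2pls(raw, a = 1), "centered")
})

test_that("prediction follows the inner-relation algebra", {
  # hand-computable configuration: W = e1, C = e1, B_T = 2
  sim <- simulate_dataset(tiny_design(), seed = 5)
  fit <- fit_o2pls(sim$data, a = 1, n_x = 1, n_y = 1)
  fit$W <- matrix(c(1, rep(0, 23)), 24, 1)
  fit$C <- matrix(c(1, rep(0, 17)), 18, 1)
  fit$B_T <- matrix(2, 1, 1)
  fit$W_Yorth <- fit$P_Yorth <- matrix(0, 24, 0)  # no orthogonal filtering
  fit$column_means_x <- rep(0, 24)
  fit$column_means_y <- rep(0, 18)
  x_new <- matrix(0, 1, 24)
  x_new[1, 1] <- 3
  pred <- predict(fit, x_new, "x_to_y")
  expect_equal(drop(pred), c(6, rep(0, 17)), ignore_attr = TRUE)

  # B_T = 0 collapses the prediction onto the training means
  fit$B_T <- matrix(0, 1, 1)
  fit$column_means_y <- stats::setNames(rnorm(18), paste0("y", 1:18))
  pred0 <- predict(fit, matrix(rnorm(48), 2, 24), "x_to_y")
  expect_equal(pred0, rbind(fit$column_means_y, fit$column_means_y),
               ignore_attr = TRUE)
})

test_that("training predictions on noiseless data recover the signal", {
  sim <- simulate_dataset(sim_design_low(alpha = 0, N = 200), seed = 13,
                          exact_orthogonality = TRUE)
  fit <- fit_o2pls(sim$data, a = 1, n_x = 1, n_y = 1)
  x_orig <- sweep(sim$data$x, 2, fit$column_means_x, "+")
  pred <- predict(fit, x_orig, "x_to_y")
  pred_centered <- sweep(pred, 2, fit$column_means_y)
  y_joint <- tcrossprod(sim$truth$U, sim$truth$C)  # the predictable part of Y
  expect_lt(mean((pred_centered - y_joint)^2) / mean(y_joint^2), 1e-8)
})

test_that("prediction rejects shape and direction errors", {
  sim <- simulate_dataset(tiny_design(), seed = 6)
  fit <- fit_o2pls(sim$data, a = 1, n_x = 1, n_y = 1)
  expect_error(predict(fit, matrix(0, 2, 5), "x_to_y"), "columns")
  expect_error(predict(fit, matrix(0, 2, 5), "sideways"), "arg")
})
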