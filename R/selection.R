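#' Inner-relation fit criterion for a component configuration
#'
#' Fits the decomposition at `(a, n_x, n_y)` and returns the sum of the two
#' inner-relation coefficients of determination,
#' \deqn{(1 - \sum H_{UT}^2 / \sum U^2) + (1 - \sum H_{TU}^2 / \sum T^2)
#'   \in [0, 2].}
#' Removing genuine block-specific variation before the joint step typically
#' improves this criterion up to the true number of orthogonal components,
#' which is what the grid search in [grid_search_orthogonal()] exploits.
#'
#' @inheritParams fit_o2pls
#' @return A single number in `[0, 2]`.
#' @export
inner_r2_criterion <- function(data, a, n_x = 0, n_y = 0) {
  fit <- fit_o2pls(data, a = a, n_x = n_x, n_y = n_y)
  fit$r2_u_on_t + fit$r2_t_on_u
}

#' Grid search for the numbers of orthogonal components
#'
#' Evaluates [inner_r2_criterion()] on the full grid
#' `{0..max_nx} x {0..max_ny}` at fixed `a` and returns the maximizing pair.
#' Exact ties are resolved parsimoniously: smallest `n_x + n_y` first, then
#' smallest `n_x`.
#'
#' @inheritParams fit_o2pls
#' @param max_nx,max_ny Upper grid bounds (defaults 10; the bounds must
#'   respect `n_x <= p - a`, `n_y <= q - a`).
#' @return A list with `n_x`, `n_y` and `grid` (a
#'   `(max_nx + 1) x (max_ny + 1)` matrix of criterion values with the
#'   component numbers as dimnames).
#' @export
grid_search_orthogonal <- function(data, a, max_nx = 10, max_ny = 10) {
  max_nx <- check_count(max_nx, "max_nx")
  max_ny <- check_count(max_ny, "max_ny")
  grid <- matrix(NA_real_, max_nx + 1, max_ny + 1,
                 dimnames = list(n_x = 0:max_nx, n_y = 0:max_ny))
  for (i in 0:max_nx) {
    for (j in 0:max_ny) {
      grid[i + 1, j + 1] <- inner_r2_criterion(data, a, i, j)
    }
  }
  cand <- expand.grid(n_x = 0:max_nx, n_y = 0:max_ny)
  cand$value <- as.vector(grid[cbind(cand$n_x + 1, cand$n_y + 1)])
  cand <- cand[order(-cand$value, cand$n_x + cand$n_y, cand$n_x), ]
  list(n_x = cand$n_x[1], n_y = cand$n_y[1], grid = grid)
}

#' Cross-validated two-way prediction error
#'
#' Estimates the per-entry squared prediction error of both directions by
#' k-fold cross-validation. Samples are partitioned by a seeded shuffle into
#' near-equal folds; within each fold the training blocks are re-centered and
#' the training means applied to the held-out samples (no information leaks
#' from the test fold), the model is fitted at `(a, n_x, n_y)`, and both
#' blocks of the fold are predicted from one another.
#'
#' @inheritParams fit_o2pls
#' @param folds Number of folds (`>= 2`, at most the number of samples).
#' @param seed Integer seed controlling the fold assignment; results are
#'   deterministic given the seed and the global random-number state is left
#'   untouched.
#' @return Named numeric vector `c(mse_x, mse_y)`: mean squared error per
#'   matrix entry for predicting X from Y and Y from X.
#' @export
cv_mse <- function(data, a, n_x = 0, n_y = 0, folds = 10, seed = 1) {
  stopifnot(inherits(data, "paired_omics"))
  folds <- check_count(folds, "folds", positive = TRUE)
  N <- nrow(data$x)
  if (folds < 2 || folds > N) {
    stop("invalid folds: need 2 <= folds <= number of samples", call. = FALSE)
  }
  assignment <- with_seed(seed, {
    fold_of <- rep(seq_len(folds), length.out = N)
    fold_of[sample.int(N)]
  })
  se_x <- se_y <- 0
  for (k in seq_len(folds)) {
    test <- assignment == k
    xtr <- center_columns(data$x[!test, , drop = FALSE])
    ytr <- center_columns(data$y[!test, , drop = FALSE])
    train <- paired_omics(xtr$x, ytr$x)
    train$centered <- c(x = TRUE, y = TRUE)
    train$column_means_x <- xtr$means
    train$column_means_y <- ytr$means
    fit <- fit_o2pls(train, a = a, n_x = n_x, n_y = n_y)
    xte <- data$x[test, , drop = FALSE]
    yte <- data$y[test, , drop = FALSE]
    se_y <- se_y + sum((predict(fit, xte, "x_to_y") - yte)^2)
    se_x <- se_x + sum((predict(fit, yte, "y_to_x") - xte)^2)
  }
  c(mse_x = se_x / (N * ncol(data$x)), mse_y = se_y / (N * ncol(data$y)))
}

#' Choose the numbers of joint and orthogonal components
#'
#' Two-stage alternative to a full three-dimensional cross-validation, which
#' becomes prohibitive with thousands of variables: for each candidate number
#' of joint components `a`, the numbers of orthogonal components are chosen
#' by maximizing the inner-relation criterion on the full data
#' ([grid_search_orthogonal()]); `a` itself is then chosen by k-fold
#' cross-validated prediction error ([cv_mse()]) at the selected
#' `(n_x, n_y)`. Because the two raw errors live on the scales of different
#' blocks, `a` minimizes their total-sum-of-squares-normalized sum
#' `combined_mse = SE_x / sum(X^2) + SE_y / sum(Y^2)`; both raw errors are
#' always reported.
#'
#' @inheritParams cv_mse
#' @param a_candidates Integer vector of candidate joint component numbers.
#' @param max_nx,max_ny Grid bounds passed to [grid_search_orthogonal()].
#' @return An object of class `o2pls_selection`: a list with `summary` (a
#'   tibble with one row per candidate `a`: chosen `n_x`, `n_y`, criterion
#'   value, `mse_x`, `mse_y`, `combined_mse`), `grids` (the full criterion
#'   grids, one matrix per `a`), `chosen_a`, `chosen_n_x`, `chosen_n_y`,
#'   `folds`, `seed`.
#' @examples
#' sim <- simulate_dataset(sim_design_low(N = 100, p = 20, q = 15), seed = 2)
#' sel <- select_components(sim$data, a_candidates = 1:2,
#'                          max_nx = 2, max_ny = 2, seed = 3)
#' sel$chosen_a
#' @export
select_components <- function(data, a_candidates, max_nx = 10, max_ny = 10,
                              folds = 10, seed = 1) {
  if (length(a_candidates) < 1) {
    stop("`a_candidates` must be non-empty", call. = FALSE)
  }
  a_candidates <- sort(unique(vapply(a_candidates, check_count, integer(1),
                                     name = "a_candidates", positive = TRUE)))
  ss_x <- sum(data$x^2)
  ss_y <- sum(data$y^2)
  grids <- list()
  rows <- vector("list", length(a_candidates))
  for (i in seq_along(a_candidates)) {
    a <- a_candidates[i]
    gs <- grid_search_orthogonal(data, a, max_nx = max_nx, max_ny = max_ny)
    grids[[as.character(a)]] <- gs$grid
    mse <- cv_mse(data, a, gs$n_x, gs$n_y, folds = folds, seed = seed)
    N <- nrow(data$x)
    rows[[i]] <- tibble::tibble(
      a = a, n_x = gs$n_x, n_y = gs$n_y,
      criterion = gs$grid[gs$n_x + 1, gs$n_y + 1],
      mse_x = mse[["mse_x"]], mse_y = mse[["mse_y"]],
      combined_mse = mse[["mse_x"]] * N * ncol(data$x) / ss_x +
        mse[["mse_y"]] * N * ncol(data$y) / ss_y
    )
  }
  summary <- dplyr::bind_rows(rows)
  best <- which.min(summary$combined_mse)
  structure(
    list(
      summary = summary, grids = grids,
      chosen_a = summary$a[best],
      chosen_n_x = summary$n_x[best],
      chosen_n_y = summary$n_y[best],
      folds = folds, seed = seed
    ),
    class = "o2pls_selection"
  )
}

#' @export
print.o2pls_selection <- function(x, ...) {
  cat("Component selection (inner-relation grid + ", x$folds,
      "-fold CV)\n", sep = "")
  print(x$summary)
  cat(sprintf("chosen: a = %d, n_x = %d, n_y = %d\n",
              x$chosen_a, x$chosen_n_x, x$chosen_n_y))
  invisible(x)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
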