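#' Normal-density loading profile
#'
#' Builds a loading vector over variable index `i = 1..n_vars` whose entry
#' `i` is the normal density value `N(i; mu, sigma)`: a smooth bump
#' emulating the realistic situation where a contiguous subset of variables
#' is important for a component and the rest are not.
#'
#' @param n_vars Number of variables.
#' @param mu,sigma Center and spread of the bump, in variable-index units;
#'   `sigma > 0`.
#' @param normalize If `TRUE` (default) the vector is scaled to unit
#'   Euclidean norm, the convention under which the noise-calibration
#'   formulas of [noise_variances()] are exact.
#' @return Numeric vector of length `n_vars`.
#' @examples
#' loading_profile(3, mu = 2, sigma = 1, normalize = FALSE)
#' @export
loading_profile <- function(n_vars, mu, sigma, normalize = TRUE) {
  n_vars <- check_count(n_vars, "n_vars", positive = TRUE)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("invalid spread: sigma must be a positive number", call. = FALSE)
  }
  v <- stats::dnorm(seq_len(n_vars), mean = mu, sd = sigma)
  if (normalize) v <- v / sqrt(sum(v^2))
  v
}

#' Define a simulation design
#'
#' Collects the generative-model parameters used by [simulate_dataset()] and
#' [run_study()]: dimensions, numbers of components, normal-density loading
#' profiles per factor, the inner-relation slope, score variances and the
#' noise fraction `alpha`. [sim_design_low()] and [sim_design_high()] return
#' the two reference designs (100/50 and 500/250 variables, profiles
#' W: (60,10)/(300,50), C: (70,5)/(175,25), X-block orthogonal loading
#' (20,20)/(100,100), Y-block orthogonal loading (15,10)/(75,50), slope 2,
#' unit score variances, 500 samples).
#'
#' @param N,p,q Samples and variables per block.
#' @param a,n_x,n_y Numbers of joint and orthogonal components.
#' @param profiles Named list with elements `W`, `C`, `P_Yorth`, `P_Xorth`,
#'   each a `(mu, sigma)` pair, or a matrix with one `(mu, sigma)` row per
#'   component for multi-component factors.
#' @param b_t Inner-relation slope(s); a scalar or a length-`a` vector
#'   forming a diagonal `B_T`.
#' @param var_t,var_t_orth,var_u_orth Score variances (all positive).
#' @param alpha Noise fraction in `[0, 1)`: the expected share of each
#'   block's total sum of squares contributed by noise.
#' @param normalize_loadings Scale each loading column to unit norm
#'   (default `TRUE`; required for `alpha` to be the exact expected noise
#'   share).
#' @return An object of class `o2pls_design` (a validated list of the
#'   above).
#' @export
sim_design <- function(N = 500, p = 100, q = 50, a = 1, n_x = 1, n_y = 1,
                       profiles = list(W = c(60, 10), C = c(70, 5),
                                       P_Yorth = c(20, 20),
                                       P_Xorth = c(15, 10)),
                       b_t = 2, var_t = 1, var_t_orth = 1, var_u_orth = 1,
                       alpha = 0.05, normalize_loadings = TRUE) {
  N <- check_count(N, "N", positive = TRUE)
  p <- check_count(p, "p", positive = TRUE)
  q <- check_count(q, "q", positive = TRUE)
  a <- check_count(a, "a", positive = TRUE)
  n_x <- check_count(n_x, "n_x")
  n_y <- check_count(n_y, "n_y")
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    stop("invalid noise level: alpha must lie in [0, 1)", call. = FALSE)
  }
  if (any(c(var_t, var_t_orth, var_u_orth) <= 0)) {
    stop("score variances must be positive", call. = FALSE)
  }
  needed <- c("W", "C", "P_Yorth", "P_Xorth")
  if (!all(needed %in% names(profiles))) {
    stop("profiles must name W, C, P_Yorth and P_Xorth", call. = FALSE)
  }
  profiles <- lapply(profiles[needed], function(pr) {
    pr <- if (is.matrix(pr)) pr else matrix(pr, nrow = 1)
    if (ncol(pr) != 2 || any(pr[, 2] <= 0)) {
      stop("each profile is a (mu, sigma) pair (or one row per component) ",
           "with sigma > 0", call. = FALSE)
    }
    colnames(pr) <- c("mu", "sigma")
    pr
  })
  b_t <- rep_len(as.numeric(b_t), a)
  structure(
    list(N = N, p = p, q = q, a = a, n_x = n_x, n_y = n_y,
         profiles = profiles, b_t = b_t, var_t = var_t,
         var_t_orth = var_t_orth, var_u_orth = var_u_orth, alpha = alpha,
         normalize_loadings = normalize_loadings),
    class = "o2pls_design"
  )
}

#' @rdname sim_design
#' @param ... Overrides passed on to [sim_design()].
#' @export
sim_design_low <- function(alpha = 0.05, ...) {
  sim_design(alpha = alpha, ...)
}

#' @rdname sim_design
#' @export
sim_design_high <- function(alpha = 0.05, ...) {
  sim_design(p = 500, q = 250,
             profiles = list(W = c(300, 50), C = c(175, 25),
                             P_Yorth = c(100, 100), P_Xorth = c(75, 50)),
             alpha = alpha, ...)
}

#' Noise variances calibrated to a target noise fraction
#'
#' Computes the variances of the three noise terms (X-block residual E,
#' Y-block residual F, inner-relation residual H) such that, under
#' unit-norm loadings, the expected noise share of each block's total sum of
#' squares equals the design's `alpha`:
#' \deqn{\sigma_E^2 = \frac{\alpha}{1-\alpha}\,
#'         \frac{a\,\sigma_T^2 + n_x\,\sigma_{T\perp}^2}{p}, \qquad
#'       \sigma_H^2 = \frac{\alpha}{1-\alpha}\, b^2 \sigma_T^2,}
#' \deqn{\sigma_F^2 = \frac{\alpha}{1-\alpha}\,
#'         \frac{a\,(b^2 \sigma_T^2 + \sigma_H^2) + n_y\,\sigma_{U\perp}^2}{q},}
#' with \eqn{\sigma_H^2} substituted into the third formula (so the F-block
#' coefficient of \eqn{\alpha/(1-\alpha)} itself depends on `alpha`). For
#' designs with several joint components the `a (...)` term is summed over
#' the per-component slopes.
#'
#' @param design An [sim_design()] object.
#' @return List with `var_e`, `var_f` (scalars) and `var_h` (length-`a`
#'   vector of inner-residual variances, one per joint component).
#' @examples
#' nv <- noise_variances(sim_design_low(alpha = 0.05))
#' ratio <- 0.05 / 0.95
#' c(nv$var_e, nv$var_f, nv$var_h) / ratio  # 0.02, 0.104, 4
#' @export
noise_variances <- function(design) {
  stopifnot(inherits(design, "o2pls_design"))
  ratio <- design$alpha / (1 - design$alpha)
  var_h <- ratio * design$b_t^2 * design$var_t
  var_e <- ratio *
    (design$a * design$var_t + design$n_x * design$var_t_orth) / design$p
  var_f <- ratio *
    (sum(design$b_t^2 * design$var_t + var_h) +
       design$n_y * design$var_u_orth) / design$q
  list(var_e = var_e, var_f = var_f, var_h = var_h)
}

# build the true loading matrix for one factor of a design
design_loadings <- function(design, factor, n_vars, n_comp) {
  if (n_comp == 0) return(matrix(0, n_vars, 0))
  pr <- design$profiles[[factor]]
  cols <- lapply(seq_len(n_comp), function(j) {
    row <- pr[min(j, nrow(pr)), ]
    loading_profile(n_vars, row["mu"], row["sigma"],
                    normalize = design$normalize_loadings)
  })
  do.call(cbind, cols)
}

#' Draw one dataset from the generative model
#'
#' Scores and noise are drawn i.i.d. normal with mean zero and the design's
#' variances (noise variances from [noise_variances()]); the joint Y scores
#' follow the inner relation `U = T B + H`; the blocks are assembled as
#' `X = T W' + T_orth P_Yorth' + E` and `Y = U C' + U_orth P_Xorth' + F`,
#' then column-mean centered. Deterministic given `seed`; the global RNG
#' state is left untouched.
#'
#' With `exact_orthogonality = TRUE` the score matrices are made exactly
#' mean-zero and mutually orthogonal in sample (QR orthogonalization, norms
#' fixed to their expected values). This realizes the model's orthogonality
#' assumptions *exactly* rather than only in expectation, and is the
#' construction under which a noiseless dataset is recovered by the fit at
#' machine precision; the default (`FALSE`) matches ordinary i.i.d.
#' simulation practice.
#'
#' @param design An [sim_design()] object.
#' @param seed Integer seed.
#' @param exact_orthogonality Enforce exact sample orthogonality of the
#'   score matrices (see Details).
#' @return List with `data` (a centered [paired_omics] object) and `truth`
#'   (all generative factors: `W`, `C`, `P_Yorth`, `P_Xorth`, `T`, `U`,
#'   `T_Yorth`, `U_Xorth`, `B_T`, `E`, `F`, `H`, plus the noise variances
#'   used).
#' @export
simulate_dataset <- function(design, seed, exact_orthogonality = FALSE) {
  stopifnot(inherits(design, "o2pls_design"))
  nv <- noise_variances(design)
  N <- design$N; p <- design$p; q <- design$q
  a <- design$a; n_x <- design$n_x; n_y <- design$n_y

  W <- design_loadings(design, "W", p, a)
  C <- design_loadings(design, "C", q, a)
  P_Yorth <- design_loadings(design, "P_Yorth", p, n_x)
  P_Xorth <- design_loadings(design, "P_Xorth", q, n_y)
  B_T <- diag(design$b_t, nrow = a)

  draws <- with_seed(seed, {
    list(
      T = matrix(stats::rnorm(N * a, sd = sqrt(design$var_t)), N, a),
      T_Yorth = matrix(stats::rnorm(N * n_x, sd = sqrt(design$var_t_orth)),
                       N, n_x),
      U_Xorth = matrix(stats::rnorm(N * n_y, sd = sqrt(design$var_u_orth)),
                       N, n_y),
      H = matrix(stats::rnorm(N * a), N, a) %*%
        diag(sqrt(nv$var_h), nrow = a),
      E = matrix(stats::rnorm(N * p, sd = sqrt(nv$var_e)), N, p),
      F = matrix(stats::rnorm(N * q, sd = sqrt(nv$var_f)), N, q)
    )
  })
  if (exact_orthogonality) {
    S <- cbind(draws$T, draws$T_Yorth, draws$U_Xorth)
    Q <- qr.Q(qr(cbind(1, S)))[, -1, drop = FALSE]
    sdv <- rep(sqrt(c(rep(design$var_t, a), rep(design$var_t_orth, n_x),
                      rep(design$var_u_orth, n_y))), length.out = ncol(S))
    S <- Q %*% diag(sqrt(N) * sdv, nrow = ncol(S))
    draws$T <- S[, seq_len(a), drop = FALSE]
    draws$T_Yorth <- S[, a + seq_len(n_x), drop = FALSE]
    draws$U_Xorth <- S[, a + n_x + seq_len(n_y), drop = FALSE]
  }
  U <- draws$T %*% B_T + draws$H
  X <- tcrossprod(draws$T, W) + tcrossprod(draws$T_Yorth, P_Yorth) + draws$E
  Y <- tcrossprod(U, C) + tcrossprod(draws$U_Xorth, P_Xorth) + draws$F
  dimnames(X) <- list(paste0("S", seq_len(N)), paste0("x", seq_len(p)))
  dimnames(Y) <- list(paste0("S", seq_len(N)), paste0("y", seq_len(q)))

  list(
    data = paired_omics(X, Y, center = TRUE),
    truth = list(W = W, C = C, P_Yorth = P_Yorth, P_Xorth = P_Xorth,
                 T = draws$T, U = U, T_Yorth = draws$T_Yorth,
                 U_Xorth = draws$U_Xorth, B_T = B_T, H = draws$H,
                 E = draws$E, F = draws$F, noise_variances = nv)
  )
}

#' Resolve the sign indeterminacy of estimated loadings
#'
#' Singular vectors are defined only up to sign. For comparing estimates to
#' a known truth, each estimated column is multiplied by the sign of its
#' cross-product with the corresponding true column (a zero cross-product is
#' treated as `+1`, leaving the column unchanged).
#'
#' @param estimate,truth Matrices of identical shape with corresponding
#'   columns.
#' @return The sign-corrected estimate.
#' @export
sign_correct <- function(estimate, truth) {
  if (!identical(dim(estimate), dim(truth))) {
    stop("estimate and truth must have identical shapes", call. = FALSE)
  }
  if (ncol(estimate) == 0) return(estimate)
  s <- sign(colSums(truth * estimate))
  s[s == 0] <- 1
  estimate %*% diag(s, nrow = length(s))
}

#' Replicate study of loading-estimate accuracy
#'
#' Repeatedly simulates from a design, fits the decomposition at the
#' design's true component numbers, sign-corrects the four estimated loading
#' factors (`W`, `C`, `P_Yorth`, `P_Xorth`) against the truth, and
#' summarizes the estimates per variable and component across replicates:
#' mean, median, quartiles, interquartile range, and elementwise bias
#' (mean estimate minus true loading). Orthogonal loading estimates are
#' unit-normalized per column before comparison, since their scale (unlike
#' their direction) is an arbitrary part of the score/loading split and the
#' true profiles are unit vectors.
#'
#' @param design An [sim_design()] object.
#' @param replicates Number of replicates (`>= 1`).
#' @param base_seed Integer; replicate `r` uses seed `base_seed + r`, making
#'   the study reproducible and safely parallelizable.
#' @return An object of class `o2pls_study`: list with `design`,
#'   `replicates`, `seeds`, `n_failed` (replicates whose fit signalled an
#'   error; such replicates are skipped), and `summaries`, a list per factor
#'   of matrices `mean`, `median`, `q25`, `q75`, `iqr`, `bias` (variables x
#'   components), plus the `truth` loadings.
#' @examples
#' st <- run_study(sim_design_low(N = 100, p = 20, q = 15), replicates = 3,
#'                 base_seed = 10)
#' max(abs(st$summaries$W$bias))
#' @export
run_study <- function(design, replicates, base_seed = 0) {
  stopifnot(inherits(design, "o2pls_design"))
  replicates <- check_count(replicates, "replicates", positive = TRUE)
  truth <- simulate_dataset(design, seed = base_seed + 1)$truth
  truth <- truth[c("W", "C", "P_Yorth", "P_Xorth")]
  truth <- truth[vapply(truth, ncol, integer(1)) > 0]
  factors <- names(truth)
  est <- lapply(truth, function(m) {
    array(NA_real_, dim = c(dim(m), replicates))
  })
  seeds <- base_seed + seq_len(replicates)
  n_failed <- 0L
  for (r in seq_len(replicates)) {
    sim <- simulate_dataset(design, seed = seeds[r])
    fit <- tryCatch(
      fit_o2pls(sim$data, a = design$a, n_x = design$n_x, n_y = design$n_y),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    for (f in factors) {
      e <- fit[[f]]
      if (f %in% c("P_Yorth", "P_Xorth")) {
        # the score/loading split of an orthogonal component has an
        # arbitrary scale; loadings are compared as unit-norm vectors,
        # matching the unit-norm true profiles
        e <- e %*% diag(1 / sqrt(colSums(e^2)), nrow = ncol(e))
      }
      est[[f]][, , r] <- sign_correct(e, sim$truth[[f]])
    }
  }
  summaries <- lapply(factors, function(f) {
    arr <- est[[f]]
    stat <- function(fun) apply(arr, c(1, 2), fun, na.rm = TRUE)
    q <- function(prob) {
      apply(arr, c(1, 2), stats::quantile, probs = prob, na.rm = TRUE,
            names = FALSE)
    }
    m <- stat(mean)
    list(mean = m, median = stat(stats::median),
         q25 = q(0.25), q75 = q(0.75), iqr = q(0.75) - q(0.25),
         bias = m - truth[[f]])
  })
  names(summaries) <- factors
  structure(
    list(design = design, replicates = replicates, seeds = seeds,
         n_failed = n_failed, summaries = summaries, truth = truth),
    class = "o2pls_study"
  )
}

#' @export
print.o2pls_study <- function(x, ...) {
  cat("Loading-accuracy study: ", x$replicates, " replicates (",
      x$n_failed, " failed)\n", sep = "")
  for (f in names(x$summaries)) {
    cat(sprintf("  %-8s max |bias| = %.5f, median IQR = %.5f\n", f,
                max(abs(x$summaries[[f]]$bias)),
                stats::median(x$summaries[[f]]$iqr)))
  }
  invisible(x)
}
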