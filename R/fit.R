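#' Fit a two-way orthogonal PLS decomposition
#'
#' Decomposes two centered, sample-matched blocks `X` (`N x p`) and `Y`
#' (`N x q`) into a joint part shared between the blocks, block-specific
#' orthogonal parts, and residual noise:
#'
#' \deqn{X = T W' + T_{Y\perp} P_{Y\perp}' + E, \qquad
#'       Y = U C' + U_{X\perp} P_{X\perp}' + F,}
#'
#' with the inner relations \eqn{U = T B_T + H_{UT}} and
#' \eqn{T = U B_U + H_{TU}} linking the joint scores. The joint loadings are
#' the leading singular vectors of the cross-product `t(X) %*% Y`, which
#' maximize the covariance between the block scores; orthogonal directions
#' are the leading left singular vectors of the residual-score cross-products.
#'
#' The algorithm: (1) provisional joint loadings from one SVD of
#' `t(X) %*% Y`; (2) extract `n_x` orthogonal directions from the X residual
#' and deflate X; (3) symmetrically extract `n_y` directions from the Y
#' residual and deflate Y; (4) re-estimate the joint part by a second SVD of
#' the deflated cross-product, so the final joint loadings are corrected for
#' the orthogonal variation; (5) fit the inner relations. With
#' `n_x = n_y = 0` the fit reduces to two-block PLS from a single SVD.
#'
#' @param data A centered [paired_omics] object. Uncentered data is refused;
#'   center explicitly with `paired_omics(..., center = TRUE)` or
#'   [center_paired()].
#' @param a Number of joint components, `1 <= a <= min(p, q)`.
#' @param n_x,n_y Numbers of orthogonal components in X and Y
#'   (`n_x <= p - a`, `n_y <= q - a`); zero disables the orthogonal part of
#'   that block.
#' @return An object of class `o2pls`: a list holding the loadings `W`
#'   (`p x a`), `C` (`q x a`), `W_Yorth`, `C_Xorth` (orthonormal orthogonal
#'   direction matrices), `P_Yorth`, `P_Xorth` (orthogonal loadings estimated
#'   by least squares of the undeflated block on the orthogonal scores),
#'   scores `T`, `U`, `T_Yorth`, `U_Xorth`, inner-relation coefficients
#'   `B_T`, `B_U`, residuals `E`, `F`, `H_UT`, `H_TU`, the joint
#'   `singular_values`, inner-relation `r2` values, stored column means, and
#'   diagnostics (provisional loadings from step 1 and the norm of the
#'   difference between residual-based and data-based orthogonal scores).
#' @examples
#' sim <- simulate_dataset(sim_design_low(), seed = 1)
#' fit <- fit_o2pls(sim$data, a = 1, n_x = 1, n_y = 1)
#' fit
#' glance(fit)
#' @seealso [predict.o2pls()], [variance_decomposition()],
#'   [select_components()]
#' @export
fit_o2pls <- function(data, a, n_x = 0, n_y = 0) {
  stopifnot(inherits(data, "paired_omics"))
  a <- check_count(a, "a", positive = TRUE)
  n_x <- check_count(n_x, "n_x")
  n_y <- check_count(n_y, "n_y")
  X <- data$x
  Y <- data$y
  p <- ncol(X); q <- ncol(Y); N <- nrow(X)
  if (a > min(p, q)) {
    stop("invalid component count: a = ", a, " exceeds min(p, q) = ",
         min(p, q), call. = FALSE)
  }
  if (n_x > p - a || n_y > q - a) {
    stop("invalid component count: need n_x <= p - a and n_y <= q - a",
         call. = FALSE)
  }
  if (!is_centered(data)) {
    stop("data must be column-mean centered before fitting; ",
         "use paired_omics(x, y, center = TRUE) or center_paired()",
         call. = FALSE)
  }

  # (1) provisional joint part
  prov <- joint_svd(crossprod(X, Y), a)
  T_prov <- X %*% prov$W
  U_prov <- Y %*% prov$C

  W_Yorth <- matrix(0, p, 0)
  P_Yorth <- matrix(0, p, 0)
  T_Yorth <- matrix(0, N, 0)
  C_Xorth <- matrix(0, q, 0)
  P_Xorth <- matrix(0, q, 0)
  U_Xorth <- matrix(0, N, 0)
  diag_orth_x <- diag_orth_y <- 0
  Xd <- X
  Yd <- Y

  # (2) orthogonal part of X, one direction at a time: the residual-score
  # cross-product has rank at most a, so several directions are reachable
  # only by deflating the block and re-forming the residual between
  # extractions (the provisional joint directions stay fixed). Each
  # orthogonal score equals both residual %*% w and current-block %*% w,
  # and the per-step loading equals the regression of the *undeflated*
  # block on the score because the scores come out mutually orthogonal.
  if (n_x > 0) {
    ox <- sequential_orthogonal(X, prov$W, n_x)
    W_Yorth <- ox$W_orth
    T_Yorth <- ox$T_orth
    P_Yorth <- ox$P_orth
    Xd <- ox$deflated
    diag_orth_x <- sqrt(sum((T_Yorth - X %*% W_Yorth)^2))
  }

  # (3) symmetric step on Y
  if (n_y > 0) {
    oy <- sequential_orthogonal(Y, prov$C, n_y)
    C_Xorth <- oy$W_orth
    U_Xorth <- oy$T_orth
    P_Xorth <- oy$P_orth
    Yd <- oy$deflated
    diag_orth_y <- sqrt(sum((U_Xorth - Y %*% C_Xorth)^2))
  }

  # (4) joint part corrected for orthogonal variation
  if (n_x > 0 || n_y > 0) {
    jnt <- joint_svd(crossprod(Xd, Yd), a)
  } else {
    jnt <- prov
  }
  Tj <- Xd %*% jnt$W
  Uj <- Yd %*% jnt$C

  # (5) inner relations, (6) residuals
  inner <- inner_relations(Tj, Uj)
  E <- Xd - tcrossprod(Tj, jnt$W)
  F_ <- Yd - tcrossprod(Uj, jnt$C)

  dimnames_set <- function(m, rn, cn) {
    if (length(m)) dimnames(m) <- list(rn, cn)
    m
  }
  comp <- paste0("joint", seq_len(a))
  cx <- paste0("xorth", seq_len(n_x))
  cy <- paste0("yorth", seq_len(n_y))

  structure(
    list(
      a = a, n_x = n_x, n_y = n_y,
      W = dimnames_set(jnt$W, data$x_var_ids, comp),
      C = dimnames_set(jnt$C, data$y_var_ids, comp),
      W_Yorth = dimnames_set(W_Yorth, data$x_var_ids, cx),
      C_Xorth = dimnames_set(C_Xorth, data$y_var_ids, cy),
      P_Yorth = dimnames_set(P_Yorth, data$x_var_ids, cx),
      P_Xorth = dimnames_set(P_Xorth, data$y_var_ids, cy),
      T = dimnames_set(Tj, data$sample_ids, comp),
      U = dimnames_set(Uj, data$sample_ids, comp),
      T_Yorth = dimnames_set(T_Yorth, data$sample_ids, cx),
      U_Xorth = dimnames_set(U_Xorth, data$sample_ids, cy),
      B_T = inner$B_T, B_U = inner$B_U,
      E = E, F = F_,
      H_UT = dimnames_set(inner$H_UT, data$sample_ids, comp),
      H_TU = dimnames_set(inner$H_TU, data$sample_ids, comp),
      r2_u_on_t = inner$r2_u_on_t, r2_t_on_u = inner$r2_t_on_u,
      singular_values = jnt$d,
      column_means_x = stats::setNames(data$column_means_x, data$x_var_ids),
      column_means_y = stats::setNames(data$column_means_y, data$y_var_ids),
      dims = c(N = N, p = p, q = q),
      diagnostics = list(
        W_provisional = prov$W, C_provisional = prov$C,
        singular_values_provisional = prov$d,
        orth_score_residual_vs_data_norm = c(x = diag_orth_x, y = diag_orth_y)
      )
    ),
    class = "o2pls"
  )
}

# strip the fitted orthogonal components from (centered) new data, in the
# training extraction order
remove_orthogonal <- function(block, W_orth, P_orth) {
  if (is.null(W_orth) || length(W_orth) == 0) return(block)
  for (i in seq_len(ncol(W_orth))) {
    t_o <- block %*% W_orth[, i, drop = FALSE]
    block <- block - tcrossprod(t_o, P_orth[, i, drop = FALSE])
  }
  block
}

# extract n orthogonal directions from one block by repeated rank-one
# extraction and deflation against the fixed joint directions W
sequential_orthogonal <- function(block, W, n) {
  m <- ncol(block)
  N <- nrow(block)
  W_orth <- matrix(0, m, n)
  T_orth <- matrix(0, N, n)
  P_orth <- matrix(0, m, n)
  cur <- block
  for (i in seq_len(n)) {
    scores <- cur %*% W
    residual <- cur - tcrossprod(scores, W)
    one <- extract_orthogonal(residual, scores, 1)
    t_o <- one$T_orth
    p_o <- crossprod(cur, t_o) / drop(crossprod(t_o))
    W_orth[, i] <- one$W_orth
    T_orth[, i] <- t_o
    P_orth[, i] <- p_o
    cur <- cur - tcrossprod(t_o, p_o)
  }
  list(W_orth = W_orth, T_orth = T_orth, P_orth = P_orth, deflated = cur)
}

#' @export
print.o2pls <- function(x, ...) {
  cat("Two-way orthogonal PLS fit\n")
  cat(sprintf("  %d samples; X: %d variables, Y: %d variables\n",
              x$dims["N"], x$dims["p"], x$dims["q"]))
  cat(sprintf("  components: %d joint, %d X-orthogonal, %d Y-orthogonal\n",
              x$a, x$n_x, x$n_y))
  cat(sprintf("  inner relation R2 (U on T): %.4f, (T on U): %.4f\n",
              x$r2_u_on_t, x$r2_t_on_u))
  invisible(x)
}

#' @export
summary.o2pls <- function(object, ...) {
  print(object)
  g <- glance(object)
  cat(sprintf("  R2X = %.4f, R2Y = %.4f\n", g$r2x, g$r2y))
  invisible(g)
}

#' Predict one block from the other
#'
#' Cross-block prediction through the joint scores and the inner relation:
#' for `direction = "x_to_y"` the new X rows are centered with the training
#' means, filtered for the block-specific orthogonal variation (each
#' orthogonal component's score `X w` is removed via its loading, exactly
#' as during training deflation), projected onto the joint X loadings,
#' carried across with `B_T`, mapped back through the joint Y loadings, and
#' the training Y means added back (`X_filtered W B_T t(C) + my`);
#' `"y_to_x"` is the mirror image using `B_U` and `t(W)`. Deterministic.
#'
#' @param object A fitted `o2pls` model.
#' @param newdata Numeric matrix whose columns match the model's source block
#'   (X for `"x_to_y"`, Y for `"y_to_x"`).
#' @param direction `"x_to_y"` or `"y_to_x"`.
#' @param ... Unused.
#' @return The predicted matrix for the target block, on the original
#'   (uncentered) scale.
#' @export
predict.o2pls <- function(object, newdata, direction = c("x_to_y", "y_to_x"),
                          ...) {
  direction <- match.arg(direction)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (!is.matrix(newdata) || !is.numeric(newdata)) {
    stop("`newdata` must be a numeric matrix", call. = FALSE)
  }
  if (direction == "x_to_y") {
    if (ncol(newdata) != object$dims["p"]) {
      stop("`newdata` has ", ncol(newdata), " columns but the model's X ",
           "block has ", object$dims["p"], call. = FALSE)
    }
    xc <- sweep(newdata, 2, object$column_means_x)
    xc <- remove_orthogonal(xc, object$W_Yorth, object$P_Yorth)
    pred <- xc %*% object$W %*% object$B_T %*% t(object$C)
    pred <- sweep(pred, 2, object$column_means_y, "+")
    colnames(pred) <- names(object$column_means_y)
  } else {
    if (ncol(newdata) != object$dims["q"]) {
      stop("`newdata` has ", ncol(newdata), " columns but the model's Y ",
           "block has ", object$dims["q"], call. = FALSE)
    }
    yc <- sweep(newdata, 2, object$column_means_y)
    yc <- remove_orthogonal(yc, object$C_Xorth, object$P_Xorth)
    pred <- yc %*% object$C %*% object$B_U %*% t(object$W)
    pred <- sweep(pred, 2, object$column_means_x, "+")
    colnames(pred) <- names(object$column_means_x)
  }
  rownames(pred) <- rownames(newdata)
  pred
}
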