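#' Leading singular pairs of a cross-product matrix
#'
#' Returns the first `a` left and right singular vectors of the cross-product
#' matrix `S = t(X) %*% Y`, whose singular pairs maximize the covariance
#' `t(w) %*% S %*% c` over unit vectors: the defining optimization of the
#' joint part of the two-block decomposition.
#'
#' Exactly tied singular values are resolved by keeping the smallest-index
#' vectors of the decomposition. Signs are fixed deterministically: each
#' column of `W` has its largest-magnitude entry made positive, and the
#' paired column of `C` is flipped together with it so that
#' `S ~ W diag(d) t(C)` is preserved.
#'
#' @param S Numeric `p x q` cross-product matrix; must be finite.
#' @param a Number of singular pairs, `1 <= a <= min(p, q)`.
#' @return A list with `W` (`p x a`), `C` (`q x a`) and `d` (the `a`
#'   non-increasing singular values).
#' @examples
#' joint_svd(diag(c(3, 1)), a = 1)
#' @export
joint_svd <- function(S, a) {
  if (!is.matrix(S) || !is.numeric(S) || !all(is.finite(S))) {
    stop("invalid input: S must be a finite numeric matrix", call. = FALSE)
  }
  a <- check_count(a, "a", positive = TRUE)
  if (a > min(dim(S))) {
    stop("invalid component count: a = ", a, " exceeds min(p, q) = ",
         min(dim(S)), call. = FALSE)
  }
  sv <- svd(S, nu = a, nv = a)
  W <- sv$u
  C <- sv$v
  for (j in seq_len(a)) {
    if (W[which.max(abs(W[, j])), j] < 0) {
      W[, j] <- -W[, j]
      C[, j] <- -C[, j]
    }
  }
  list(W = W, C = C, d = sv$d[seq_len(a)])
}

#' Extract block-specific orthogonal directions
#'
#' Finds the `n` directions in variable space along which the residual of a
#' block (after removing its joint part) co-varies most strongly with the
#' joint scores: the leading left singular vectors of
#' `t(residual) %*% scores`, equivalently the top eigenvectors of
#' `t(residual) %*% scores %*% t(scores) %*% residual`. The orthogonal scores
#' are the residual projected onto those directions.
#'
#' @param residual `N x m` residual matrix, `data - scores %*% t(loadings)`
#'   for the same block.
#' @param scores `N x a` joint score matrix of that block.
#' @param n Number of orthogonal directions, `1 <= n <= m`.
#' @return A list with `W_orth` (`m x n`, orthonormal columns, sign-fixed so
#'   each column's largest-magnitude entry is positive) and `T_orth`
#'   (`N x n`, equal to `residual %*% W_orth`).
#' @section Errors: If `t(residual) %*% scores` is numerically zero the block
#'   carries no detectable orthogonal variation and a classed error
#'   (`o2pls_no_orthogonal_variation`) is signalled; callers wanting that case
#'   should request `n = 0` components instead. Requesting more directions
#'   than the rank of the cross-product signals `o2pls_insufficient_rank`.
#' @export
extract_orthogonal <- function(residual, scores, n) {
  n <- check_count(n, "n", positive = TRUE)
  if (n > ncol(residual)) {
    stop("invalid component count: n exceeds the number of variables",
         call. = FALSE)
  }
  M <- crossprod(residual, scores)
  if (sqrt(sum(M^2)) < 1e-12) {
    stop(structure(
      class = c("o2pls_no_orthogonal_variation", "error", "condition"),
      list(message = "no detectable orthogonal variation (residual-score cross-product is numerically zero)",
           call = NULL)
    ))
  }
  sv <- svd(M)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (n > rank) {
    stop(structure(
      class = c("o2pls_insufficient_rank", "error", "condition"),
      list(message = paste0("insufficient rank: requested ", n,
                            " orthogonal components but the residual-score ",
                            "cross-product has rank ", rank),
           call = NULL)
    ))
  }
  W_orth <- sv$u[, seq_len(n), drop = FALSE]
  for (j in seq_len(n)) {
    if (W_orth[which.max(abs(W_orth[, j])), j] < 0) {
      W_orth[, j] <- -W_orth[, j]
    }
  }
  list(W_orth = W_orth, T_orth = residual %*% W_orth)
}

#' Inner relations between the two blocks' joint scores
#'
#' Fits the two no-intercept least-squares regressions linking the joint
#' scores of the blocks, `U ~ T B_T` and `T ~ U B_U`, and returns the
#' coefficients, residuals and the two coefficients of determination. These
#' regressions are what carries information across blocks in prediction.
#'
#' @param T,U `N x a` joint score matrices (centered).
#' @return A list with `B_T`, `B_U` (`a x a` coefficients), `H_UT = U - T B_T`,
#'   `H_TU = T - U B_U`, and `r2_u_on_t = 1 - sum(H_UT^2) / sum(U^2)`,
#'   `r2_t_on_u` defined symmetrically; both lie in `[0, 1]`.
#' @export
inner_relations <- function(T, U) {
  if (!identical(dim(T), dim(U))) {
    stop("invalid input: T and U must have identical dimensions", call. = FALSE)
  }
  if (any(apply(T, 2, stats::sd) == 0) || any(apply(U, 2, stats::sd) == 0)) {
    stop("degenerate scores: zero-variance score column", call. = FALSE)
  }
  B_T <- ls_coef(T, U)
  B_U <- ls_coef(U, T)
  H_UT <- U - T %*% B_T
  H_TU <- T - U %*% B_U
  list(
    B_T = B_T, B_U = B_U, H_UT = H_UT, H_TU = H_TU,
    r2_u_on_t = 1 - sum(H_UT^2) / sum(U^2),
    r2_t_on_u = 1 - sum(H_TU^2) / sum(T^2)
  )
}

# least-squares coefficient of Y on X without intercept, via an svd-based
# pseudo-inverse; singular values below 1e-12 * largest are treated as zero
ls_coef <- function(X, Y, tol = 1e-12) {
  sv <- svd(crossprod(X))
  pos <- sv$d > sv$d[1] * tol
  inv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  inv %*% crossprod(X, Y)
}

check_count <- function(x, name, positive = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) ||
      x < if (positive) 1 else 0) {
    stop("`", name, "` must be a single ",
         if (positive) "positive" else "non-negative", " integer",
         call. = FALSE)
  }
  as.integer(x)
}
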