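#' Explained-variation summary of a fitted decomposition
#'
#' Computes the standard explained-variation statistics of a two-block
#' orthogonal decomposition, all as sums of squares of reconstructed parts
#' relative to the total sum of squares of the centered data (entrywise
#' Frobenius sums, no degrees-of-freedom correction):
#'
#' * `r2x = 1 - sum(E^2) / sum(X^2)` and `r2y`: variation modeled at all
#'   (joint + orthogonal).
#' * `r2x_corr = sum((T W')^2) / sum(X^2)` and `r2y_corr`: the joint
#'   (between-block correlated) part.
#' * `r2x_hat = sum((U B_U W')^2) / sum(X^2)` and
#'   `r2y_hat = sum((T B_T C')^2) / sum(Y^2)`: the part of each block
#'   predictable *from the other block* through the inner relation.
#' * `ratio_x = r2x_hat / r2x_corr`, `ratio_y = r2y_hat / r2y_corr`: how much
#'   of the joint part is actually carried across.
#'
#' The per-part sums of squares (joint scores `T`, orthogonal part
#' `T_Yorth`, residual `E`, each relative to `sum(X^2)`; `U`, `U_Xorth`,
#' `F` relative to `sum(Y^2)`; the inner residual `H_UT` relative to
#' `sum(U^2)`) are returned as a tibble in `ss_parts`. Because the joint
#' loadings have unit-norm columns the joint rows are score sums of
#' squares; the orthogonal rows are the reconstructed parts
#' `T_Yorth %*% t(P_Yorth)` (whose scale, unlike the raw scores', is not
#' arbitrary), so the three parts of each block partition its total.
#'
#' @param model A fitted `o2pls` object.
#' @param data The centered [paired_omics] object the model was fitted on.
#' @return An object of class `o2pls_variance`: list with the six statistics,
#'   the two ratios, and `ss_parts`.
#' @export
variance_decomposition <- function(model, data) {
  stopifnot(inherits(model, "o2pls"), inherits(data, "paired_omics"))
  X <- data$x
  Y <- data$y
  ss_x <- sum(X^2)
  ss_y <- sum(Y^2)
  if (ss_x == 0 || ss_y == 0) {
    stop("degenerate data: a block has zero total sum of squares",
         call. = FALSE)
  }
  # residuals may be absent on a deserialized model; rebuild from the data
  E <- model$E
  F_ <- model$F
  H_UT <- model$H_UT
  if (is.null(E)) {
    E <- X - tcrossprod(model$T, model$W) -
      tcrossprod(model$T_Yorth, model$P_Yorth)
  }
  if (is.null(F_)) {
    F_ <- Y - tcrossprod(model$U, model$C) -
      tcrossprod(model$U_Xorth, model$P_Xorth)
  }
  if (is.null(H_UT)) H_UT <- model$U - model$T %*% model$B_T

  r2x <- 1 - sum(E^2) / ss_x
  r2y <- 1 - sum(F_^2) / ss_y
  r2x_corr <- sum(tcrossprod(model$T, model$W)^2) / ss_x
  r2y_corr <- sum(tcrossprod(model$U, model$C)^2) / ss_y
  r2x_hat <- sum((model$U %*% model$B_U %*% t(model$W))^2) / ss_x
  r2y_hat <- sum((model$T %*% model$B_T %*% t(model$C))^2) / ss_y

  # the split of an orthogonal component into score and loading carries an
  # arbitrary scale; the component's reconstructed part T_orth P' does not,
  # and under unit-norm joint loadings the three X parts (equally Y parts)
  # are mutually orthogonal, so these sums partition each block exactly
  ss <- c(T = sum(model$T^2),
          T_Yorth = sum(tcrossprod(model$T_Yorth, model$P_Yorth)^2),
          E = sum(E^2),
          U = sum(model$U^2),
          U_Xorth = sum(tcrossprod(model$U_Xorth, model$P_Xorth)^2),
          F = sum(F_^2), H_UT = sum(H_UT^2))
  denom <- c(rep(ss_x, 3), rep(ss_y, 3), sum(model$U^2))
  ss_parts <- tibble::tibble(
    part = names(ss),
    block = c("X", "X", "X", "Y", "Y", "Y", "inner"),
    ss = unname(ss),
    share = unname(ss / denom)
  )
  structure(
    list(r2x = r2x, r2y = r2y, r2x_corr = r2x_corr, r2y_corr = r2y_corr,
         r2x_hat = r2x_hat, r2y_hat = r2y_hat,
         ratio_x = r2x_hat / r2x_corr, ratio_y = r2y_hat / r2y_corr,
         ss_parts = ss_parts),
    class = "o2pls_variance"
  )
}

#' @export
print.o2pls_variance <- function(x, ...) {
  cat("Explained variation (shares of total sum of squares)\n")
  cat(sprintf("  R2X      = %6.2f %%   R2Y      = %6.2f %%\n",
              100 * x$r2x, 100 * x$r2y))
  cat(sprintf("  R2Xcorr  = %6.2f %%   R2Ycorr  = %6.2f %%\n",
              100 * x$r2x_corr, 100 * x$r2y_corr))
  cat(sprintf("  R2Xhat   = %6.2f %%   R2Yhat   = %6.2f %%\n",
              100 * x$r2x_hat, 100 * x$r2y_hat))
  cat(sprintf("  Xhat/Xcorr = %.2f     Yhat/Ycorr = %.2f\n",
              x$ratio_x, x$ratio_y))
  invisible(x)
}
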