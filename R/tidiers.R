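#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

matrix_to_long <- function(m, comp_prefix = "comp") {
  if (length(m) == 0) return(NULL)
  tibble::tibble(
    variable = rep(rownames(m) %||% as.character(seq_len(nrow(m))), ncol(m)),
    index = rep(seq_len(nrow(m)), ncol(m)),
    component = rep(colnames(m) %||% paste0(comp_prefix, seq_len(ncol(m))),
                    each = nrow(m)),
    loading = as.vector(m)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy the loadings of a fitted model
#'
#' One row per variable and component, for the joint loadings of both blocks
#' and (when present) the orthogonal loadings, ready for dplyr/ggplot2 work.
#'
#' @param x A fitted `o2pls` object.
#' @param ... Unused.
#' @return A tibble with columns `block` ("X"/"Y"), `part`
#'   ("joint"/"orthogonal"), `component`, `variable`, `index` and `loading`.
#' @method tidy o2pls
#' @export
tidy.o2pls <- function(x, ...) {
  pieces <- list(
    X_joint = matrix_to_long(x$W),
    Y_joint = matrix_to_long(x$C),
    X_orth = matrix_to_long(x$P_Yorth),
    Y_orth = matrix_to_long(x$P_Xorth)
  )
  keys <- tidyr::separate(
    tibble::tibble(key = rep(names(pieces), vapply(pieces, function(p) {
      if (is.null(p)) 0L else nrow(p)
    }, integer(1)))),
    "key", into = c("block", "part"), sep = "_"
  )
  dplyr::bind_cols(keys, dplyr::bind_rows(pieces))
}

#' One-row summary of a fitted model
#'
#' @param x A fitted `o2pls` object.
#' @param ... Unused.
#' @return A one-row tibble: component numbers, inner-relation R-squared in
#'   both directions, and the overall explained-variation shares `r2x`,
#'   `r2y` (computed from the stored residuals).
#' @method glance o2pls
#' @export
glance.o2pls <- function(x, ...) {
  # the model identity X = T W' + T_orth P' + E recovers the training data,
  # so the total sum of squares is available without the data itself
  recon_x <- tcrossprod(x$T, x$W) + tcrossprod(x$T_Yorth, x$P_Yorth)
  recon_y <- tcrossprod(x$U, x$C) + tcrossprod(x$U_Xorth, x$P_Xorth)
  tibble::tibble(
    a = x$a, n_x = x$n_x, n_y = x$n_y,
    r2_u_on_t = x$r2_u_on_t, r2_t_on_u = x$r2_t_on_u,
    r2x = 1 - sum(x$E^2) / sum((recon_x + x$E)^2),
    r2y = 1 - sum(x$F^2) / sum((recon_y + x$F)^2)
  )
}

#' @method tidy o2pls_selection
#' @export
tidy.o2pls_selection <- function(x, ...) x$summary

#' @method glance o2pls_selection
#' @export
glance.o2pls_selection <- function(x, ...) {
  tibble::tibble(chosen_a = x$chosen_a, chosen_n_x = x$chosen_n_x,
                 chosen_n_y = x$chosen_n_y, folds = x$folds, seed = x$seed)
}

#' Tidy an explained-variation summary
#'
#' @param x An `o2pls_variance` object.
#' @param ... Unused.
#' @return A tibble with one row per statistic (`statistic`, `value`,
#'   `percent`).
#' @method tidy o2pls_variance
#' @export
tidy.o2pls_variance <- function(x, ...) {
  nm <- c("r2x", "r2y", "r2x_corr", "r2y_corr", "r2x_hat", "r2y_hat",
          "ratio_x", "ratio_y")
  tibble::tibble(
    statistic = nm,
    value = unlist(x[nm], use.names = FALSE),
    percent = 100 * unlist(x[nm], use.names = FALSE)
  )
}

#' Tidy a replicate study of loading accuracy
#'
#' @param x An `o2pls_study` object.
#' @param ... Unused.
#' @return A long tibble: `factor`, `component`, `index`, `truth`, `mean`,
#'   `median`, `q25`, `q75`, `iqr`, `bias` per variable.
#' @method tidy o2pls_study
#' @export
tidy.o2pls_study <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$summaries), function(f) {
    s <- x$summaries[[f]]
    truth <- x$truth[[f]]
    n <- nrow(truth)
    k <- ncol(truth)
    tibble::tibble(
      factor = f,
      component = rep(seq_len(k), each = n),
      index = rep(seq_len(n), k),
      truth = as.vector(truth),
      mean = as.vector(s$mean),
      median = as.vector(s$median),
      q25 = as.vector(s$q25),
      q75 = as.vector(s$q75),
      iqr = as.vector(s$iqr),
      bias = as.vector(s$bias)
    )
  }))
}
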