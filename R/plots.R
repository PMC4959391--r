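#' Plot the loading profiles of a fitted model
#'
#' Joint and orthogonal loadings per block against variable index, one panel
#' per block/part combination.
#'
#' @param object A fitted `o2pls` object.
#' @param parts Which parts to show, a subset of `c("joint", "orth")`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot o2pls
#' @export
autoplot.o2pls <- function(object, parts = c("joint", "orth"), ...) {
  d <- tidy(object)
  d <- d[d$part %in% parts, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$loading,
                                  colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_grid(part ~ block, scales = "free") +
    ggplot2::labs(x = "variable index", y = "loading") +
    ggplot2::theme_minimal()
}

#' Plot a component-selection result
#'
#' Left: the inner-relation criterion grid over the numbers of orthogonal
#' components for each candidate number of joint components. The
#' cross-validated prediction errors are in `tidy(object)`.
#'
#' @param object An `o2pls_selection` object.
#' @param ... Unused.
#' @return A ggplot object (criterion grids, faceted by `a`).
#' @method autoplot o2pls_selection
#' @export
autoplot.o2pls_selection <- function(object, ...) {
  d <- dplyr::bind_rows(lapply(names(object$grids), function(a) {
    g <- object$grids[[a]]
    tibble::tibble(
      a = paste0("a = ", a),
      n_x = rep(as.integer(rownames(g)), ncol(g)),
      n_y = rep(as.integer(colnames(g)), each = nrow(g)),
      criterion = as.vector(g)
    )
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_y, y = .data$n_x,
                                  fill = .data$criterion)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~a) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "orthogonal components in Y",
                  y = "orthogonal components in X",
                  fill = "inner-relation\ncriterion") +
    ggplot2::theme_minimal()
}

#' Plot a loading-accuracy study
#'
#' Per factor, the across-replicate interquartile band and median of the
#' sign-corrected loading estimates against variable index, with the true
#' loading profile overlaid: the tabular analogue of the usual simulation
#' boxplot figure.
#'
#' @param object An `o2pls_study` object.
#' @param factors Which loading factors to show (default all four).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot o2pls_study
#' @export
autoplot.o2pls_study <- function(object,
                                 factors = c("W", "C", "P_Yorth", "P_Xorth"),
                                 ...) {
  d <- tidy(object)
  d <- d[d$factor %in% factors, , drop = FALSE]
  d$panel <- paste0(d$factor, " (component ", d$component, ")")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$truth), colour = "red",
                       linetype = "dashed") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "variable index", y = "loading estimate") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
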