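#' Box-Cox power transform
#'
#' Entrywise `(x^lambda - 1) / lambda` (natural log for `lambda = 0`),
#' commonly applied with `lambda = 1/4` to right-skewed metabolite
#' concentrations before centering. Strictly increasing in `x`, so ranks
#' within each variable are preserved.
#'
#' @param x Numeric matrix (or vector) of strictly positive values.
#' @param lambda Power parameter (default `0.25`).
#' @return The transformed matrix, same shape and dimnames.
#' @examples
#' box_cox(matrix(16), lambda = 0.25)  # (16^0.25 - 1) / 0.25 = 4
#' @export
box_cox <- function(x, lambda = 0.25) {
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("x must be numeric and finite", call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda)) {
    stop("lambda must be a single finite number", call. = FALSE)
  }
  bad <- which(x <= 0)
  if (length(bad)) {
    if (is.matrix(x)) {
      j <- (bad[1] - 1) %/% nrow(x) + 1
      var <- if (!is.null(colnames(x))) colnames(x)[j] else paste("column", j)
      stop("non-positive value in variable ", var,
           "; the power transform requires strictly positive data",
           call. = FALSE)
    }
    stop("non-positive value at position ", bad[1], call. = FALSE)
  }
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

#' Column-mean centering
#'
#' Centers each column to mean zero and returns the means so that held-out
#' data can be shifted onto the same scale.
#'
#' @param x Numeric matrix.
#' @return List with `x` (the centered matrix) and `means`.
#' @export
center_columns <- function(x) {
  if (!is.matrix(x) || nrow(x) == 0 || ncol(x) == 0) {
    stop("x must be a non-empty numeric matrix", call. = FALSE)
  }
  means <- colMeans(x)
  list(x = sweep(x, 2, means), means = means)
}

#' Filter variables by expression level and spread
#'
#' Keeps the variables that are simultaneously in the top tail of overall
#' magnitude and the top tail of spread, the usual pre-filter for removing
#' uninformative (low, flat) expression variables before integration. The
#' magnitude summary is the per-variable mean of absolute values (or the
#' median); spread is the interquartile range with linear-interpolation
#' quantiles. A variable is kept iff its summary is `>=` the
#' `level_quantile` empirical quantile of all summaries *and* its IQR is
#' `>=` the `iqr_quantile` quantile of all IQRs (ties kept), so the defaults
#' of 0.75 retain roughly the intersection of the two top-25 % sets.
#' Original column order is preserved.
#'
#' @param x Numeric matrix, samples in rows.
#' @param level_quantile,iqr_quantile Quantile thresholds in `(0, 1)`.
#' @param level_stat Magnitude summary, `"mean"` (default) or `"median"` of
#'   absolute values.
#' @return List with `x` (the filtered matrix) and `kept` (retained variable
#'   ids, in original order).
#' @export
filter_expression <- function(x, level_quantile = 0.75, iqr_quantile = 0.75,
                              level_stat = c("mean", "median")) {
  level_stat <- match.arg(level_stat)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("x must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 2) {
    stop("at least 2 samples are required to compute an IQR", call. = FALSE)
  }
  for (qq in c(level_quantile, iqr_quantile)) {
    if (!is.numeric(qq) || length(qq) != 1 || qq <= 0 || qq >= 1) {
      stop("quantile thresholds must lie strictly inside (0, 1)",
           call. = FALSE)
    }
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  level <- apply(abs(x), 2, level_stat)
  spread <- apply(x, 2, stats::IQR)  # type-7 linear interpolation quantiles
  keep <- level >= stats::quantile(level, level_quantile) &
    spread >= stats::quantile(spread, iqr_quantile)
  list(x = x[, keep, drop = FALSE], kept = colnames(x)[keep])
}

#' Pairwise Pearson correlations
#'
#' Pearson correlation matrix between the columns of a matrix, as commonly
#' summarized in a heatmap of metabolite-metabolite correlations.
#'
#' @param x Numeric matrix with at least two rows and no constant column.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2) {
    stop("x must be a numeric matrix with at least 2 samples", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stats::cor(x)
}
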