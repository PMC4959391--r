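#' Pair two sample-matched omics blocks
#'
#' Bundles two numeric matrices measured on the same samples into a single
#' object used by [fit_o2pls()] and friends. Rows are samples, columns are
#' variables; both blocks must have the same samples in the same order and
#' contain no missing values (drop incomplete samples first, e.g. with
#' [align_samples()]).
#'
#' @param x,y Numeric matrices, samples in rows. Row names (sample ids) and
#'   column names (variable ids) are used when present; defaults are generated
#'   otherwise.
#' @param center If `TRUE`, both blocks are column-mean centered and the means
#'   stored for later reuse (prediction, held-out data).
#' @return An object of class `paired_omics`: a list with elements `x`, `y`,
#'   `sample_ids`, `x_var_ids`, `y_var_ids`, `centered` (named logical vector),
#'   `column_means_x`, `column_means_y`.
#' @examples
#' x <- matrix(rnorm(20), 5, 4)
#' y <- matrix(rnorm(15), 5, 3)
#' pd <- paired_omics(x, y, center = TRUE)
#' pd
#' @export
paired_omics <- function(x, y, center = FALSE) {
  x <- as_omics_matrix(x, "x")
  y <- as_omics_matrix(y, "y")
  if (nrow(x) != nrow(y)) {
    stop("x and y must have the same number of samples (rows): ",
         nrow(x), " vs ", nrow(y), call. = FALSE)
  }
  if (!identical(rownames(x), rownames(y))) {
    stop("x and y must have identical sample ids in identical order",
         call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values are not allowed; drop incomplete samples first ",
         "(see align_samples())", call. = FALSE)
  }
  out <- structure(
    list(
      x = x, y = y,
      sample_ids = rownames(x),
      x_var_ids = colnames(x),
      y_var_ids = colnames(y),
      centered = c(x = FALSE, y = FALSE),
      column_means_x = rep(0, ncol(x)),
      column_means_y = rep(0, ncol(y))
    ),
    class = "paired_omics"
  )
  if (center) out <- center_paired(out)
  out
}

# coerce to a labeled numeric matrix, filling in default ids
as_omics_matrix <- function(m, label) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("`", label, "` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0(label, seq_len(ncol(m)))
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sample ids in `", label, "`", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate variable ids in `", label, "`", call. = FALSE)
  }
  m
}

#' Center both blocks of a paired object
#'
#' Column-mean centers `x` and `y`, recording the means so that held-out data
#' can be placed on the training scale. Centering an already-centered object
#' is a no-op beyond floating-point noise.
#'
#' @param data A [paired_omics] object.
#' @return The centered `paired_omics` object with `column_means_x`,
#'   `column_means_y` filled in and `centered` set.
#' @export
center_paired <- function(data) {
  stopifnot(inherits(data, "paired_omics"))
  cx <- center_columns(data$x)
  cy <- center_columns(data$y)
  data$x <- cx$x
  data$y <- cy$x
  # accumulate means so center(center(d)) reports the original means
  data$column_means_x <- data$column_means_x + cx$means
  data$column_means_y <- data$column_means_y + cy$means
  data$centered <- c(x = TRUE, y = TRUE)
  data
}

# TRUE if every column mean of both blocks is numerically zero
is_centered <- function(data, tol = 1e-8) {
  sc_x <- max(1, max(abs(data$x)))
  sc_y <- max(1, max(abs(data$y)))
  max(abs(colMeans(data$x))) < tol * sc_x &&
    max(abs(colMeans(data$y))) < tol * sc_y
}

#' @export
print.paired_omics <- function(x, ...) {
  cat("Paired omics data: ", length(x$sample_ids), " samples\n", sep = "")
  cat("  X block: ", ncol(x$x), " variables", if (x$centered["x"]) " (centered)",
      "\n", sep = "")
  cat("  Y block: ", ncol(x$y), " variables", if (x$centered["y"]) " (centered)",
      "\n", sep = "")
  invisible(x)
}

#' Align two blocks on their shared samples
#'
#' Takes the intersection of the sample ids of two matrices, orders both
#' blocks identically (order of first appearance in `x`), and drops every
#' sample that has one or more missing values in either block. This mirrors
#' the usual cohort-study practice of excluding participants with incomplete
#' measurements rather than imputing.
#'
#' @param x,y Numeric matrices with unique sample ids as row names.
#' @return A [paired_omics] object (uncentered) for the retained samples, with
#'   attributes `n_unmatched` (ids present in only one block) and
#'   `n_dropped_missing` (shared samples removed for missing values).
#' @examples
#' x <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), NULL))
#' y <- matrix(rnorm(9), 3, 3, dimnames = list(paste0("s", 2:4), NULL))
#' y[1, 2] <- NA
#' align_samples(x, y)  # s3, s4 retained
#' @export
align_samples <- function(x, y) {
  x <- as_omics_matrix(x, "x")
  y <- as_omics_matrix(y, "y")
  shared <- intersect(rownames(x), rownames(y))
  if (length(shared) == 0) {
    stop("no shared sample ids between the two blocks", call. = FALSE)
  }
  n_unmatched <- (nrow(x) - length(shared)) + (nrow(y) - length(shared))
  xs <- x[shared, , drop = FALSE]
  ys <- y[shared, , drop = FALSE]
  complete <- !(rowSums(is.na(xs)) > 0 | rowSums(is.na(ys)) > 0)
  n_dropped <- sum(!complete)
  if (!any(complete)) {
    stop("all shared samples contain missing values", call. = FALSE)
  }
  out <- paired_omics(xs[complete, , drop = FALSE], ys[complete, , drop = FALSE])
  attr(out, "n_unmatched") <- n_unmatched
  attr(out, "n_dropped_missing") <- n_dropped
  out
}
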