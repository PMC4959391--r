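#' Read a labeled numeric matrix from delimited text
#'
#' Reads a TSV/CSV file whose first row holds variable ids and whose first
#' column holds sample ids. Empty cells and `NA`/`na` are read as missing
#' (to be handled by [align_samples()]); any other non-numeric cell is an
#' error naming its file coordinates. Ragged rows and duplicate ids are
#' rejected.
#'
#' @param path File path.
#' @param delimiter Field delimiter; by default `","` for `.csv` files and
#'   tab otherwise.
#' @return Numeric matrix with sample ids as row names and variable ids as
#'   column names.
#' @export
read_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("file has no data rows: ", path, call. = FALSE)
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop("ragged row ", bad, " in ", path, ": ", widths[bad],
         " fields, expected ", widths[1], call. = FALSE)
  }
  header <- cells[[1]]
  var_ids <- header[-1]
  body <- cells[-1]
  sample_ids <- vapply(body, `[`, character(1), 1)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in ", path, call. = FALSE)
  }
  if (anyDuplicated(var_ids)) {
    stop("duplicate variable ids in ", path, call. = FALSE)
  }
  raw <- matrix(unlist(lapply(body, function(r) r[-1])),
                nrow = length(body), byrow = TRUE)
  missing <- raw == "" | tolower(trimws(raw)) == "na"
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals) & !missing)
  if (length(bad)) {
    i <- (bad[1] - 1) %% nrow(raw) + 1
    j <- (bad[1] - 1) %/% nrow(raw) + 1
    stop("non-numeric cell at row ", i + 1, ", column ", j + 1, " of ",
         path, ": '", raw[bad[1]], "'", call. = FALSE)
  }
  matrix(vals, nrow = nrow(raw),
         dimnames = list(sample_ids, var_ids))
}

#' Write a labeled numeric matrix as delimited text
#'
#' Counterpart of [read_matrix()]. Values are written with 17 significant
#' digits, which round-trips doubles exactly.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param delimiter Field delimiter; default chosen from the extension as in
#'   [read_matrix()].
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, delimiter = NULL) {
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  header <- paste(c("id", colnames(x)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# matrices serialized in a model directory
model_matrices <- c("W", "C", "W_Yorth", "C_Xorth", "P_Yorth", "P_Xorth",
                    "T", "U", "T_Yorth", "U_Xorth", "B_T", "B_U")

#' Serialize a fitted model to a directory of text files
#'
#' Writes each factor matrix (`W`, `C`, `W_Yorth`, `C_Xorth`, `P_Yorth`,
#' `P_Xorth`, `T`, `U`, `T_Yorth`, `U_Xorth`, `B_T`, `B_U`) as a TSV file
#' plus a `model.json` metadata file (component numbers, singular values,
#' training column means, package version). Residual matrices are not
#' stored; [variance_decomposition()] rebuilds them from data when needed.
#' [load_o2pls()] restores the model with every stored matrix bit-identical.
#'
#' @param model A fitted `o2pls` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_o2pls <- function(model, dir) {
  stopifnot(inherits(model, "o2pls"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in model_matrices) {
    m <- model[[nm]]
    if (length(m) == 0) next
    write_matrix(m, file.path(dir, paste0(nm, ".tsv")))
  }
  meta <- list(
    class = "o2pls",
    a = model$a, n_x = model$n_x, n_y = model$n_y,
    singular_values = model$singular_values,
    column_means_x = as.list(model$column_means_x),
    column_means_y = as.list(model$column_means_y),
    dims = as.list(model$dims),
    r2_u_on_t = model$r2_u_on_t, r2_t_on_u = model$r2_t_on_u,
    package_version = as.character(utils::packageVersion("o2plsr"))
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a model serialized with [save_o2pls()]
#'
#' @param dir Directory written by [save_o2pls()].
#' @return An `o2pls` object (without residual matrices, which are
#'   recomputed from data where required).
#' @export
load_o2pls <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path)) {
    stop("not a model directory (no model.json): ", dir, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  model <- list(a = meta$a, n_x = meta$n_x, n_y = meta$n_y)
  for (nm in model_matrices) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    model[[nm]] <- if (file.exists(f)) {
      m <- read_matrix(f)
      if (nm %in% c("B_T", "B_U")) dimnames(m) <- NULL
      m
    } else {
      matrix(0, 0, 0)
    }
  }
  model$singular_values <- meta$singular_values
  model$column_means_x <- unlist(meta$column_means_x)
  model$column_means_y <- unlist(meta$column_means_y)
  model$dims <- unlist(meta$dims)
  model$r2_u_on_t <- meta$r2_u_on_t
  model$r2_t_on_u <- meta$r2_t_on_u
  structure(model, class = "o2pls")
}

#' Write a run manifest
#'
#' Records what a pipeline run did: the command, a configuration snapshot,
#' input paths with md5 digests, seeds, package version and a timestamp.
#' Every command of the bundled command-line interface writes one manifest
#' per run so results can be traced back to their inputs.
#'
#' @param path Output JSON path.
#' @param command Command name.
#' @param config Named list snapshot of options.
#' @param inputs Character vector of input file paths (digested with md5).
#' @param seed Integer seed(s) used, if any.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), inputs = character(),
                           seed = NULL) {
  manifest <- list(
    command = command,
    config = config,
    inputs = lapply(stats::setNames(inputs, inputs), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    seed = seed,
    package_version = as.character(utils::packageVersion("o2plsr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
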