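# Plain-text I/O: CSV/TSV for series and matrices, JSON for models. All
# matrix files are oriented row = source, column = target, matching the
# coefficient convention used throughout the package.

#' Read a multichannel time series from a delimited text file
#'
#' Rows are time steps, columns are channels. The delimiter is sniffed from
#' the first line unless given. Ragged rows, non-numeric cells and missing
#' values are rejected with descriptive errors.
#'
#' @param path file path.
#' @param delimiter field separator; `NULL` sniffs among tab, comma,
#'   semicolon and whitespace.
#' @param header logical; first row holds channel labels.
#' @param zscore reduce each channel to zero mean and unit variance.
#' @return numeric `N x M` matrix with channel labels as column names.
#' @export
read_timeseries <- function(path, delimiter = NULL, header = TRUE,
                            zscore = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(delimiter)) {
    first <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", first)) "\t"
                 else if (grepl(",", first)) ","
                 else if (grepl(";", first)) ";"
                 else ""
  }
  df <- tryCatch(
    utils::read.table(path, sep = delimiter, header = header,
                      comment.char = "#", stringsAsFactors = FALSE),
    error = function(e)
      stop(sprintf("could not parse %s as a rectangular table: %s",
                   path, conditionMessage(e))))
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop(sprintf("non-numeric column(s): %s",
                 paste(names(df)[bad], collapse = ", ")))
  x <- as.matrix(df)
  if (anyNA(x)) stop(sprintf("missing values in %s", path))
  if (!header) colnames(x) <- default_labels(ncol(x))
  if (zscore) x <- scale(x)[, , drop = FALSE]
  x
}

#' Write a multichannel time series as TSV
#'
#' @param x numeric matrix, rows = time.
#' @param path output path.
#' @export
write_timeseries <- function(x, path) {
  x <- as.matrix(x)
  colnames(x) <- colnames(x) %||% default_labels(ncol(x))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a VAR model to JSON
#'
#' Fields: `M`, `p`, `coeffs` (list of `p` row-major `M x M` arrays, row =
#' source, column = target), `sigma`, `labels`.
#'
#' @param model a [var_model()].
#' @param path output path.
#' @export
write_var_model <- function(model, path) {
  stopifnot(inherits(model, "var_model"))
  jsonlite::write_json(
    list(M = model$M, p = model$p, coeffs = model$coeffs,
         sigma = model$sigma, labels = model$labels,
         orientation = "row=source, column=target"),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a VAR model from JSON
#'
#' @param path a file written by [write_var_model()].
#' @return a [var_model()].
#' @export
read_var_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
  coeffs <- obj$coeffs
  if (is.array(coeffs) && length(dim(coeffs)) == 3)
    coeffs <- lapply(seq_len(dim(coeffs)[1]), function(k) coeffs[k, , ])
  var_model(coeffs, obj$sigma, labels = obj$labels)
}

#' Write a source-by-target matrix as TSV
#'
#' Writes the matrix with a header comment stating the orientation and any
#' provided metadata (seed, configuration); the diagonal and failed entries
#' appear as `NA`.
#'
#' @param mat numeric matrix (row = source, column = target).
#' @param path output path.
#' @param meta optional named list recorded in header comments.
#' @export
write_matrix_tsv <- function(mat, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# orientation: row = source, column = target", con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  colnames(mat) <- colnames(mat) %||% default_labels(ncol(mat))
  utils::write.table(as.data.frame(mat), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              comment.char = "#", check.names = FALSE))
}

#' Write benchmark results in tidy form
#'
#' Emits the per-realization table as TSV and the summary plus metadata as
#' JSON, consumable by external statistics software.
#'
#' @param report a `benchmark_report`.
#' @param dir output directory (created if absent).
#' @param seed seed recorded in the metadata.
#' @return invisibly, the paths written.
#' @export
write_benchmark_report <- function(report, dir, seed = NULL) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "results.tsv")
  utils::write.table(report$results, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(simulation = report$simulation, seed = seed,
         summary = report$summary,
         failures = report$failures,
         theoretical = report$theoretical),
    js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(tsv, js))
}
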