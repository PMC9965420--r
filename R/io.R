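#' Read an expression table from TSV/CSV
#'
#' Expects features (genes or probes) in rows, with the first column holding
#' feature identifiers and the header holding sample identifiers.
#'
#' @param path file path; delimiter inferred from the extension
#'   (".csv" comma, otherwise tab).
#' @param allow_negative passed to [validate_expression()].
#' @return numeric matrix, features x samples.
#' @export
read_expression <- function(path, allow_negative = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  validate_expression(m, allow_negative = allow_negative)
  m
}

#' Write an expression matrix as TSV
#'
#' @param m features x samples matrix with dimnames.
#' @param path output path.
#' @param id_col name of the identifier column in the header.
#' @export
write_expression <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column probe-to-gene map
#'
#' @param path TSV with columns probe_id, gene_id (header optional but
#'   recommended).
#' @return data.frame with columns probe_id, gene_id.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("probe map needs two columns: probe_id, gene_id")
  out <- data.frame(probe_id = as.character(df[[1]]),
                    gene_id = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicated set names in GMT")
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a single-cell reference matrix from TSV or MatrixMarket
#'
#' For MTX input, `genes_path` and `cells_path` name one-column sidecar files
#' with row (gene) and column (cell) identifiers.
#'
#' @param path matrix file (.tsv/.csv or .mtx).
#' @param genes_path,cells_path sidecars, required for .mtx.
#' @return dense numeric matrix, genes x cells.
#' @export
read_reference_matrix <- function(path, genes_path = NULL, cells_path = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stop("reading .mtx requires the Matrix package")
    if (is.null(genes_path) || is.null(cells_path))
      stop("MTX input needs genes and cells sidecar files")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(cells_path)
    validate_expression(m)
    m
  } else {
    read_expression(path)
  }
}
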