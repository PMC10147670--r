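#' Read a genes-by-cells expression matrix
#'
#' Accepts either MatrixMarket triplet format (`.mtx`, with companion
#' `<stem>_genes.txt` and `<stem>_cells.txt` name files, one name per line)
#' or a dense delimited table (first column = gene names, header = cell
#' names). Duplicate gene or cell names are rejected.
#'
#' @param path Path to the matrix file.
#' @return A dense numeric matrix with gene rownames and cell colnames.
#' @seealso [write_expression_matrix()], [score_cells()]
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_fmt("no such expression matrix: %s", path)
  if (file.size(path) == 0L) stop_fmt("expression matrix file is empty: %s", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    gene_f <- paste0(stem, "_genes.txt")
    cell_f <- paste0(stem, "_cells.txt")
    if (!file.exists(gene_f) || !file.exists(cell_f))
      stop_fmt("MatrixMarket input needs name files %s and %s", gene_f, cell_f)
    rownames(m) <- readLines(gene_f)
    colnames(m) <- readLines(cell_f)
  } else {
    first <- readLines(path, n = 1L)
    if (!nzchar(trimws(first))) stop_fmt("expression matrix file is empty: %s", path)
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
  }
  if (!is.numeric(m)) stop_fmt("expression matrix contains non-numeric values")
  storage.mode(m) <- "double"
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop_fmt("duplicate or missing gene names in %s", path)
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop_fmt("duplicate or missing cell names in %s", path)
  if (any(!is.finite(m))) stop_fmt("expression matrix contains non-finite values")
  m
}

#' Write a genes-by-cells expression matrix
#'
#' @param m Numeric matrix with gene rownames and cell colnames.
#' @param path Output path; `.mtx` writes MatrixMarket plus name sidecars,
#'   anything else writes a dense tab-delimited table.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(is.matrix(m), is.numeric(m),
            !is.null(rownames(m)), !is.null(colnames(m)))
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    writeLines(rownames(m), paste0(stem, "_genes.txt"))
    writeLines(colnames(m), paste0(stem, "_cells.txt"))
  } else {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
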