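#' Construct an expression matrix container
#'
#' An `expr_matrix` is a plain numeric matrix of nonnegative expression values
#' (TPM, counts, or any unit) oriented with cells as rows and genes as columns,
#' carrying unique cell and gene identifiers as dimnames. All downstream code
#' in the package assumes this orientation.
#'
#' @param values numeric matrix, n cells x p genes.
#' @param cell_ids character vector of length `nrow(values)`, unique.
#' @param gene_ids character vector of length `ncol(values)`, unique.
#' @return an object of class `expr_matrix` (a matrix with dimnames).
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop2("expression values must be numeric")
  if (is.null(cell_ids) || is.null(gene_ids))
    stop2("cell_ids and gene_ids are required")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop2("length(cell_ids) must equal nrow(values)")
  if (length(gene_ids) != ncol(values))
    stop2("length(gene_ids) must equal ncol(values)")
  if (anyDuplicated(cell_ids))
    stop2("duplicate cell ids: ", paste(unique(cell_ids[duplicated(cell_ids)]),
                                        collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop2("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]),
                                        collapse = ", "))
  if (anyNA(values))
    stop2("expression matrix contains missing values; impute or fix upstream")
  dimnames(values) <- list(cell_ids, gene_ids)
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d cells x %d genes\n", nrow(x), ncol(x)))
  cat(sprintf("  zero fraction: %.3f\n", mean(unclass(x) == 0)))
  invisible(x)
}

#' Read an expression matrix from delimited text or MatrixMarket
#'
#' Delimited files carry gene/cell names in the header row and first column.
#' MatrixMarket files must be accompanied by `genes.txt` and `cells.txt`
#' sidecars (one id per line) in the same directory; stored zeros are expanded
#' to a dense matrix. The returned matrix always has cells as rows and genes
#' as columns: when the file is stored genes-by-cells, pass
#' `orientation = "genes_by_cells"` and the values are transposed on load.
#'
#' @param path file path.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`; defaults to the file
#'   extension (`.csv` comma, `.tsv`/`.txt` tab, `.mtx` MatrixMarket).
#' @param orientation `"cells_by_genes"` (default) or `"genes_by_cells"`,
#'   describing the on-disk layout.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path,
                            format = c("auto", "csv", "tsv", "mtx"),
                            orientation = c("cells_by_genes", "genes_by_cells")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop2("cannot infer format from extension '.", ext,
                           "'; pass format= explicitly"))
  }

  if (format == "mtx") {
    dir <- dirname(path)
    gf <- file.path(dir, "genes.txt")
    cf <- file.path(dir, "cells.txt")
    if (!file.exists(gf) || !file.exists(cf))
      stop2("MatrixMarket input requires sidecar files genes.txt and cells.txt in ", dir)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gf)
    cells <- readLines(cf)
    if (orientation == "genes_by_cells") {
      if (nrow(m) != length(genes) || ncol(m) != length(cells))
        stop2("mtx dimensions ", nrow(m), "x", ncol(m),
              " do not match sidecars (", length(genes), " genes, ",
              length(cells), " cells)")
      m <- t(m)
    } else {
      if (nrow(m) != length(cells) || ncol(m) != length(genes))
        stop2("mtx dimensions ", nrow(m), "x", ncol(m),
              " do not match sidecars (", length(cells), " cells, ",
              length(genes), " genes)")
    }
    return(expression_matrix(m, cells, genes))
  }

  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = ""),
    error = function(e) stop2("parse error in ", path, ": ", conditionMessage(e)))
  if (ncol(df) < 2) stop2("parse error in ", path, ": fewer than two columns")
  rn <- as.character(df[[1]])
  cn <- colnames(df)[-1]          # keep duplicates; subsetting would mangle them
  df <- df[, -1, drop = FALSE]
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    col <- bad[1]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
    stop2("parse error in ", path, ": non-numeric entry at data row ",
          row %||% "?", ", column '", colnames(df)[col], "'")
  }
  m <- as.matrix(df)
  dimnames(m) <- list(rn, cn)
  if (orientation == "genes_by_cells") m <- t(m)
  expression_matrix(m)
}

#' Write an expression matrix to delimited text or MatrixMarket
#'
#' Inverse of [read_expression()]: delimited output carries gene names in the
#' header and cell ids in the first column (cells-by-genes orientation);
#' MatrixMarket output writes the coordinate file plus `genes.txt`/`cells.txt`
#' sidecars next to it.
#'
#' @param em an [expression_matrix()].
#' @param path output file path.
#' @param format `"csv"`, `"tsv"` or `"mtx"`; default from the extension.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, format = c("auto", "csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop2("cannot infer format from extension '.", ext, "'"))
  }
  if (format == "mtx") {
    sm <- Matrix::Matrix(unclass(em), sparse = TRUE)
    Matrix::writeMM(sm, path)
    writeLines(colnames(em), file.path(dirname(path), "genes.txt"))
    writeLines(rownames(em), file.path(dirname(path), "cells.txt"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell_id = rownames(em), unclass(em),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
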