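#' Read an expression matrix
#'
#' Two dialects are supported. Delimited text: cells in rows, a header
#' row of gene names, first column cell ids. MatrixMarket: a `.mtx` file
#' (cells x genes) with sidecar one-name-per-line files for genes and
#' cell barcodes (defaults: same stem with `_genes.txt` /
#' `_barcodes.txt`).
#'
#' @param path matrix file (`.mtx` selects the MatrixMarket dialect).
#' @param genes_path,barcodes_path sidecar name files for the
#'   MatrixMarket dialect.
#' @param labels_path optional two-column delimited file (cell id, label);
#'   every id must match a matrix row.
#' @return a [raw_expression()].
#' @export
read_expression <- function(path, genes_path = NULL, barcodes_path = NULL,
                            labels_path = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(genes_path)) genes_path <- paste0(stem, "_genes.txt")
    if (is.null(barcodes_path)) barcodes_path <- paste0(stem, "_barcodes.txt")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    barcodes <- readLines(barcodes_path)
    if (length(genes) != ncol(m)) stop("gene sidecar length != ncol(mtx)")
    if (length(barcodes) != nrow(m)) stop("barcode sidecar length != nrow(mtx)")
    raw <- raw_expression(m, genes, barcodes)
  } else {
    df <- data.table::fread(path, header = TRUE, data.table = FALSE)
    if (ncol(df) < 2) stop("malformed expression file (need id column + genes): ", path)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(df[-1], is.numeric, TRUE))[1] + 1
      stop("non-numeric expression column ", bad, " in ", path)
    }
    raw <- raw_expression(m, colnames(df)[-1], ids)
  }
  if (!is.null(labels_path)) {
    raw$labels <- read_labels(labels_path, raw$cell_ids)
  }
  raw
}

#' Write an expression matrix as delimited text
#'
#' Cells in rows, header of gene names, first column `cell_id`. Values
#' are written at full precision so write-then-read round-trips exactly.
#'
#' @param path output path.
#' @param x a [raw_expression()], [processed_expression()], or matrix
#'   with dimnames.
#' @param sep field separator (default tab).
#' @export
write_expression <- function(path, x, sep = "\t") {
  m <- if (inherits(x, "raw_expression")) x$counts
       else if (inherits(x, "processed_expression")) x$X_c
       else as.matrix(x)
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Read a labels file
#'
#' Two delimited columns: cell id, label. When `cell_ids` is supplied the
#' labels are validated against and reordered to it.
#'
#' @param path labels file.
#' @param cell_ids optional cell-id universe (order defines the output).
#' @return integer label vector.
#' @export
read_labels <- function(path, cell_ids = NULL) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(df) < 2) stop("labels file needs 2 columns (cell id, label): ", path)
  ids <- as.character(df[[1]])
  lab <- df[[2]]
  if (is.null(cell_ids)) return(as.integer(as.factor(lab)))
  unknown <- setdiff(ids, cell_ids)
  if (length(unknown) > 0) {
    stop("labels file has unknown cell id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  missing <- setdiff(cell_ids, ids)
  if (length(missing) > 0) {
    stop("labels file is missing cell id(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  as.integer(as.factor(lab))[match(cell_ids, ids)]
}

#' Write labels as delimited text
#'
#' @param path output path.
#' @param labels integer/character label vector.
#' @param cell_ids cell identifiers, same length.
#' @export
write_labels <- function(path, labels, cell_ids) {
  stopifnot(length(labels) == length(cell_ids))
  data.table::fwrite(
    data.frame(cell_id = cell_ids, label = labels, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a cell adjacency matrix
#'
#' `format = "mtx"` writes MatrixMarket sparse; `format = "edges"` writes
#' a two-column 0-based edge list (upper triangle).
#'
#' @param path output path.
#' @param adj a [knn_adjacency()] result or binary matrix.
#' @param format `"mtx"` or `"edges"`.
#' @export
write_adjacency <- function(path, adj, format = c("mtx", "edges")) {
  format <- match.arg(format)
  A <- if (inherits(adj, "cell_adjacency")) adj$A_c else as.matrix(adj)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                "generalMatrix"), path)
  } else {
    idx <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
    data.table::fwrite(
      data.frame(from = idx[, 1] - 1L, to = idx[, 2] - 1L),
      path, sep = "\t", quote = FALSE)
  }
  invisible(path)
}

#' Read a cell adjacency matrix written by [write_adjacency()]
#'
#' @param path input path (`.mtx` or edge-list TSV).
#' @param n number of cells (required for the edge-list dialect).
#' @return binary symmetric matrix.
#' @export
read_adjacency <- function(path, n = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    A <- as.matrix(Matrix::readMM(path))
    storage.mode(A) <- "double"   # pattern MTX reads back as logical
  } else {
    df <- data.table::fread(path, header = TRUE, data.table = FALSE)
    if (is.null(n)) stop("read_adjacency: n is required for edge lists")
    A <- matrix(0, n, n)
    A[cbind(df[[1]] + 1L, df[[2]] + 1L)] <- 1
    A <- pmax(A, t(A))
  }
  A
}

#' Write gene embeddings as delimited text with a gene-name index column
#'
#' @param path output path.
#' @param emb a `gene_embeddings` object or matrix with rownames.
#' @export
write_embeddings <- function(path, emb) {
  m <- if (inherits(emb, "gene_embeddings")) emb$X_g else as.matrix(emb)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", paste0("e", seq_len(ncol(m))))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read gene embeddings written by [write_embeddings()]
#'
#' @param path input path.
#' @return numeric matrix with gene rownames.
#' @export
read_embeddings <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write an edge list file
#'
#' @param path output path.
#' @param edges data.frame with columns protein1, protein2 and optional
#'   combined_score.
#' @export
write_edge_list <- function(path, edges) {
  data.table::fwrite(edges, path, sep = "\t", quote = FALSE)
  invisible(path)
}
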