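#' Pearson correlation matrix between cells
#'
#' Computes the n x n matrix of Pearson correlation coefficients between
#' cell rows of the processed expression matrix. Correlation is used
#' directly as the similarity for KNN graph construction: higher is nearer.
#'
#' @param x a [processed_expression()] or a plain numeric matrix
#'   (cells in rows).
#' @return a symmetric matrix with unit diagonal, values in `[-1, 1]`,
#'   of class `correlation_matrix`.
#' @export
pearson_matrix <- function(x) {
  m <- if (inherits(x, "processed_expression")) x$X_c else as.matrix(x)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(m)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("pearson_matrix: zero-variance cell rows (correlation undefined): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  p <- stats::cor(t(m))
  p <- (p + t(p)) / 2            # symmetrize away float asymmetry
  p[p > 1] <- 1; p[p < -1] <- -1
  diag(p) <- 1
  structure(p, class = c("correlation_matrix", "matrix"))
}

#' Binary KNN adjacency from a cell-cell similarity matrix
#'
#' For each cell the `k` most correlated other cells become directed
#' edges (ties broken toward the lower index); the digraph is then
#' symmetrized by union, `A <- max(A, t(A))`, so no cell is isolated and
#' every row has at least `k` ones. The diagonal is zero; self-attention
#' is handled separately inside the encoder.
#'
#' @param p a [pearson_matrix()] result (or any similarity matrix).
#' @param k neighbors per cell, `1 <= k < n` (default 15).
#' @return a list of class `cell_adjacency` with the binary matrix `A_c`
#'   and the `k` used.
#' @export
knn_adjacency <- function(p, k = 15) {
  p <- unclass(p)
  n <- nrow(p)
  if (k < 1) stop("k must be >= 1")
  if (k >= n) stop("k must be < n (got k=", k, ", n=", n, ")")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sim <- p[i, ]
    sim[i] <- -Inf
    nb <- order(-sim, seq_len(n))[seq_len(k)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))
  diag(A) <- 0
  dimnames(A) <- dimnames(p)
  structure(list(A_c = A, k = k), class = "cell_adjacency")
}

#' @export
print.cell_adjacency <- function(x, ...) {
  cat(sprintf("<cell_adjacency> %d cells, k=%d, %d undirected edges\n",
              nrow(x$A_c), x$k, sum(x$A_c) / 2))
  invisible(x)
}

#' Build the KNN cell graph from processed expression
#'
#' Convenience wrapper: [pearson_matrix()] then [knn_adjacency()].
#'
#' @inheritParams pearson_matrix
#' @inheritParams knn_adjacency
#' @return a `cell_adjacency`.
#' @export
build_cell_graph <- function(x, k = 15) {
  knn_adjacency(pearson_matrix(x), k = k)
}
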