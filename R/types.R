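#' Raw expression container
#'
#' A cells x genes nonnegative matrix together with gene names, cell ids and
#' optional ground-truth labels. This is the entry type of the preprocessing
#' chain; the same container carries the matrix through QC, duplicate-gene
#' collapsing and normalization (values become log2-scale after
#' [normalize_log()]).
#'
#' @param counts numeric matrix, cells in rows, genes in columns; all
#'   entries must be nonnegative and finite.
#' @param gene_names character vector, one per column.
#' @param cell_ids character vector, one per row. Defaults to
#'   `cell_1 ... cell_n`.
#' @param labels optional integer-like vector of ground-truth cluster labels,
#'   one per cell; must contain at least two distinct values when present.
#' @return an object of class `raw_expression`.
#' @export
raw_expression <- function(counts, gene_names, cell_ids = NULL, labels = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (length(gene_names) != ncol(counts)) {
    stop("gene_names length (", length(gene_names),
         ") does not match ncol(counts) (", ncol(counts), ")")
  }
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(counts)))
  if (length(cell_ids) != nrow(counts)) {
    stop("cell_ids length does not match nrow(counts)")
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(counts)) {
      stop("labels length does not match nrow(counts)")
    }
    if (length(unique(labels)) < 2) {
      stop("labels must contain at least 2 distinct values")
    }
    labels <- as.integer(as.factor(labels))
  }
  dimnames(counts) <- list(cell_ids, gene_names)
  structure(
    list(counts = counts, gene_names = as.character(gene_names),
         cell_ids = as.character(cell_ids), labels = labels),
    class = "raw_expression"
  )
}

#' @export
print.raw_expression <- function(x, ...) {
  cat(sprintf("<raw_expression> %d cells x %d genes%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$labels)) "" else
                sprintf(", %d label classes", length(unique(x$labels)))))
  invisible(x)
}

#' Processed expression container
#'
#' The log2-scale cells x HVG matrix every downstream stage consumes, plus a
#' provenance record of the filters that produced it.
#'
#' @param X_c numeric matrix (n x d_g), log2 scale, nonnegative.
#' @param hvg_names character vector of unique retained gene names.
#' @param labels optional ground-truth labels carried through from QC.
#' @param cell_ids cell identifiers.
#' @param provenance named list describing applied filters.
#' @return an object of class `processed_expression` with fields `X_c`,
#'   `hvg_names`, `n`, `d_g`, `cell_ids`, `labels`, `provenance`.
#' @export
processed_expression <- function(X_c, hvg_names, cell_ids = NULL,
                                 labels = NULL, provenance = list()) {
  X_c <- as.matrix(X_c)
  if (any(!is.finite(X_c))) stop("X_c must be finite")
  if (any(X_c < -1e-12)) stop("X_c must be nonnegative (log2 of values >= 1)")
  if (length(hvg_names) != ncol(X_c)) stop("hvg_names length != ncol(X_c)")
  if (anyDuplicated(hvg_names)) stop("hvg_names must be unique")
  if (is.null(cell_ids)) cell_ids <- rownames(X_c)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(X_c)))
  dimnames(X_c) <- list(cell_ids, hvg_names)
  structure(
    list(X_c = X_c, hvg_names = as.character(hvg_names), n = nrow(X_c),
         d_g = ncol(X_c), cell_ids = as.character(cell_ids), labels = labels,
         provenance = provenance),
    class = "processed_expression"
  )
}

#' @export
print.processed_expression <- function(x, ...) {
  cat(sprintf("<processed_expression> %d cells x %d HVGs (log2 scale)\n",
              x$n, x$d_g))
  invisible(x)
}
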