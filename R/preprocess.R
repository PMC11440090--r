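#' Quality-control filter on per-cell totals with quartile-deviation fences
#'
#' Removes cells whose library size falls outside asymmetric fences built
#' from the quartile deviation QD = (Q3 - Q1) / 2 of the per-cell totals:
#' a cell is dropped when its total exceeds `Q3 + upper_mult * QD` or falls
#' below `Q1 - lower_mult * QD`. Quartiles use linear interpolation between
#' order statistics. The default multipliers (3 above, 1 below) follow the
#' common single-cell convention of a wide upper fence for doublet-like
#' outliers and a tight lower fence for empty-ish cells.
#'
#' @param raw a [raw_expression()] object (count scale).
#' @param upper_mult multiplier on QD for the upper fence (default 3).
#' @param lower_mult multiplier on QD for the lower fence (default 1).
#' @param covariate `"total_counts"` (default) filters on per-cell library
#'   size; `"detected_genes"` filters on the number of genes with
#'   nonzero counts.
#' @return a filtered `raw_expression`; gene names are preserved, cell ids
#'   and labels of removed cells are dropped. The fences and removal count
#'   are recorded in `attr(, "qc")`.
#' @export
qc_filter_cells <- function(raw, upper_mult = 3, lower_mult = 1,
                            covariate = c("total_counts", "detected_genes")) {
  stopifnot(inherits(raw, "raw_expression"))
  covariate <- match.arg(covariate)
  n <- nrow(raw$counts)
  if (n < 3) stop("qc_filter_cells needs at least 3 cells to define quartiles")
  totals <- switch(covariate,
    total_counts = rowSums(raw$counts),
    detected_genes = rowSums(raw$counts > 0)
  )
  q <- quartile_deviation(totals)
  upper <- q$q3 + upper_mult * q$qd
  lower <- q$q1 - lower_mult * q$qd
  keep <- totals <= upper & totals >= lower
  if (!any(keep)) {
    stop(sprintf(
      "qc_filter_cells removed every cell (lower fence %s, upper fence %s)",
      fmt_num(lower), fmt_num(upper)))
  }
  out <- raw_expression(
    raw$counts[keep, , drop = FALSE], raw$gene_names,
    cell_ids = raw$cell_ids[keep],
    labels = if (is.null(raw$labels)) NULL else raw$labels[keep]
  )
  attr(out, "qc") <- list(
    covariate = covariate, q1 = q$q1, q3 = q$q3, qd = q$qd,
    lower = lower, upper = upper, removed = sum(!keep),
    upper_mult = upper_mult, lower_mult = lower_mult
  )
  out
}

#' Median library-size normalization followed by log2(x + 1)
#'
#' Each cell's counts are rescaled so its total equals the median
#' pre-scaling total across cells (bringing libraries to a consistent
#' range while preserving nonnegativity), then transformed entrywise with
#' `log2(x + 1)`; the pseudocount keeps zeros at zero and all outputs
#' nonnegative.
#'
#' @param raw a [raw_expression()] on the count scale.
#' @return a `raw_expression` whose matrix is on the log2 scale.
#' @export
normalize_log <- function(raw) {
  stopifnot(inherits(raw, "raw_expression"))
  totals <- rowSums(raw$counts)
  zero <- totals == 0
  if (any(zero)) {
    stop("normalize_log: cells with zero total counts: ",
         paste(raw$cell_ids[zero], collapse = ", "))
  }
  target <- stats::median(totals)
  scaled <- raw$counts * (target / totals)
  logged <- log2(scaled + 1)
  out <- raw_expression(logged, raw$gene_names, raw$cell_ids, raw$labels)
  attr(out, "normalization") <- list(target_total = target, scale = "log2")
  out
}

#' Collapse duplicated gene names by averaging their columns
#'
#' Columns sharing a gene name are replaced by a single column holding
#' their arithmetic mean; the output keeps first-occurrence column order
#' and has unique gene names.
#'
#' @param raw a [raw_expression()].
#' @return a `raw_expression` with unique gene names.
#' @export
collapse_duplicate_genes <- function(raw) {
  stopifnot(inherits(raw, "raw_expression"))
  if (!anyDuplicated(raw$gene_names)) return(raw)
  first_idx <- !duplicated(raw$gene_names)
  keep_names <- raw$gene_names[first_idx]
  groups <- split(seq_along(raw$gene_names), raw$gene_names)
  merged <- vapply(keep_names, function(g) {
    cols <- groups[[g]]
    if (length(cols) == 1L) raw$counts[, cols]
    else rowMeans(raw$counts[, cols, drop = FALSE])
  }, numeric(nrow(raw$counts)))
  merged <- matrix(merged, nrow = nrow(raw$counts),
                   dimnames = list(raw$cell_ids, keep_names))
  raw_expression(merged, keep_names, raw$cell_ids, raw$labels)
}

# Bin-normalized dispersion ranking. Dispersion = variance / mean computed
# on the de-logged scale (2^x - 1), z-scored within `n_bins` equal-width
# bins of the gene means. Returns the z-score per gene (NA-safe: genes with
# zero mean get -Inf so they rank last; single-gene or zero-spread bins get
# z = 0).
binned_dispersion <- function(X_log2, n_bins = 20) {
  y <- 2^X_log2 - 1
  mu <- colMeans(y)
  v <- apply(y, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  finite <- is.finite(disp)
  z <- rep(-Inf, length(disp))
  if (any(finite)) {
    m <- mu[finite]
    rng <- range(m)
    if (rng[1] == rng[2]) {
      bins <- rep(1L, length(m))
    } else {
      brks <- seq(rng[1], rng[2], length.out = n_bins + 1)
      bins <- cut(m, breaks = brks, include.lowest = TRUE, labels = FALSE)
    }
    d <- disp[finite]
    zf <- numeric(length(d))
    for (b in unique(bins)) {
      idx <- bins == b
      mb <- mean(d[idx])
      sb <- stats::sd(d[idx])
      zf[idx] <- if (sum(idx) < 2 || !is.finite(sb) || sb == 0) 0
                 else (d[idx] - mb) / sb
    }
    z[finite] <- zf
  }
  z
}

#' Select highly variable genes by bin-normalized dispersion
#'
#' Genes are ranked by their dispersion (variance / mean on the de-logged
#' scale) z-scored within 20 equal-width bins of the gene means, and the
#' top `n_top` are retained in rank order. Must be called on normalized,
#' log-transformed, duplicate-collapsed data. Ties rank by column order.
#'
#' @param raw a log2-scale [raw_expression()] with unique gene names.
#' @param n_top number of genes to keep (default 500); when fewer genes are
#'   available, all are kept.
#' @param n_bins number of mean-bins for the dispersion z-score (default 20).
#' @return a [processed_expression()] restricted to the selected genes.
#' @export
select_hvgs <- function(raw, n_top = 500, n_bins = 20) {
  stopifnot(inherits(raw, "raw_expression"))
  if (n_top < 2) stop("n_top must be >= 2")
  if (anyDuplicated(raw$gene_names)) {
    stop("select_hvgs requires unique gene names; run collapse_duplicate_genes first")
  }
  z <- binned_dispersion(raw$counts, n_bins = n_bins)
  keep_n <- min(n_top, ncol(raw$counts))
  ord <- order(-z, seq_along(z))[seq_len(keep_n)]
  processed_expression(
    raw$counts[, ord, drop = FALSE],
    hvg_names = raw$gene_names[ord],
    cell_ids = raw$cell_ids,
    labels = raw$labels,
    provenance = list(n_top = n_top, n_bins = n_bins,
                      n_available = ncol(raw$counts),
                      dispersion_z = z[ord])
  )
}

#' Run the full preprocessing chain
#'
#' QC filter, duplicate-gene collapse, median library-size normalization
#' with log2 transform, then HVG selection — in that fixed order
#' (duplicate averaging happens on the count scale).
#'
#' @param raw a [raw_expression()] of counts.
#' @param n_top HVG count (default 500).
#' @param upper_mult,lower_mult QC fence multipliers, see [qc_filter_cells()].
#' @param qc_covariate QC covariate, see [qc_filter_cells()].
#' @param verbose emit one log line per step.
#' @return a [processed_expression()].
#' @export
preprocess <- function(raw, n_top = 500, upper_mult = 3, lower_mult = 1,
                       qc_covariate = "total_counts", verbose = FALSE) {
  qc <- qc_filter_cells(raw, upper_mult, lower_mult, qc_covariate)
  log_stage("preprocess", sprintf("QC kept %d/%d cells", nrow(qc$counts),
                                  nrow(raw$counts)), verbose = verbose)
  dedup <- collapse_duplicate_genes(qc)
  norm <- normalize_log(dedup)
  out <- select_hvgs(norm, n_top = n_top)
  out$provenance <- c(out$provenance, list(qc = attr(qc, "qc")))
  log_stage("preprocess", sprintf("selected %d HVGs", out$d_g),
            verbose = verbose)
  out
}
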