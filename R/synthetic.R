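#' Specification of a synthetic single-cell dataset
#'
#' Describes a block-structured counts-plus-gene-graph world: `k`
#' balanced cell clusters, `d_g` genes partitioned into `n_gene_modules`
#' co-expression modules, each cluster up-shifting its own subset of
#' modules by `separation` (natural-log units of mean expression), with
#' log-normal count noise and dropout-style zero inflation. The defaults
#' are the reference fixture used throughout the test-suite: 300 cells,
#' 3 clusters, 120 genes, separation 2, 30% dropout.
#'
#' @param n number of cells (>= 10 * k).
#' @param k number of cell clusters (>= 2).
#' @param d_g number of genes (>= n_gene_modules).
#' @param n_gene_modules gene modules; default `2 * k` so every cluster
#'   owns two modules (must be >= k).
#' @param separation between-cluster mean shift in log units (default 2).
#' @param dropout_rate probability a count is zeroed (default 0.3).
#' @param noise_sd log-scale Gaussian noise sd (default 0.4).
#' @param p_in,p_out planted-partition edge probabilities of the gene
#'   graph within / between modules (defaults 0.3 / 0.02).
#' @param base_logmean baseline natural-log mean expression (default
#'   log(5)).
#' @param seed RNG seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 300, k = 3, d_g = 120, n_gene_modules = 2 * k,
                           separation = 2, dropout_rate = 0.3,
                           noise_sd = 0.4, p_in = 0.3, p_out = 0.02,
                           base_logmean = log(5), seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (n < 10 * k) stop("n must be >= 10 * k")
  if (n_gene_modules < k) stop("n_gene_modules must be >= k")
  if (d_g < n_gene_modules) stop("d_g must be >= n_gene_modules")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate in [0, 1)")
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Simulate a clustered expression matrix with a matched gene graph
#'
#' Genes are split into modules (balanced, contiguous); module `m` is
#' owned by cluster `(m - 1) %% k + 1`, and cells of that cluster have
#' the module's genes up-shifted by `separation` log units. Counts are
#' `round(exp(logmean + N(0, noise_sd)))`, then independently zeroed at
#' `dropout_rate`. The gene graph is a planted-partition graph over the
#' same modules (edge probability `p_in` within, `p_out` between), with
#' uniform confidences in `[0.4, 1]`, so graph communities align with
#' co-expression blocks. Byte-identical for a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_dataset` with `raw` (a
#'   [raw_expression()] carrying balanced labels), `gene_edges`
#'   (data.frame: protein1, protein2, combined_score), `truth_means`
#'   (k x d_g generating means), and `gene_modules` (module id per gene).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(spec$seed, "simulate"), {
    k <- spec$k; n <- spec$n; d_g <- spec$d_g
    gene_names <- sprintf("G%04d", seq_len(d_g))
    modules <- sort(rep_len(seq_len(spec$n_gene_modules), d_g))
    owner <- (seq_len(spec$n_gene_modules) - 1) %% k + 1
    # labels balanced within +/- 1, then shuffled
    labels <- sample(rep_len(seq_len(k), n))
    logmean <- matrix(spec$base_logmean, k, d_g)
    for (m in seq_len(spec$n_gene_modules)) {
      logmean[owner[m], modules == m] <-
        logmean[owner[m], modules == m] + spec$separation
    }
    truth_means <- exp(logmean)
    noise <- matrix(stats::rnorm(n * d_g, 0, spec$noise_sd), n, d_g)
    counts <- round(exp(logmean[labels, , drop = FALSE] + noise))
    if (spec$dropout_rate > 0) {
      keep <- matrix(stats::runif(n * d_g) >= spec$dropout_rate, n, d_g)
      counts <- counts * keep
    }
    raw <- raw_expression(counts, gene_names,
                          cell_ids = sprintf("C%04d", seq_len(n)),
                          labels = labels)
    # planted-partition gene graph
    pairs <- which(upper.tri(matrix(0, d_g, d_g)), arr.ind = TRUE)
    same <- modules[pairs[, 1]] == modules[pairs[, 2]]
    prob <- ifelse(same, spec$p_in, spec$p_out)
    drawn <- stats::runif(nrow(pairs)) < prob
    gene_edges <- data.frame(
      protein1 = gene_names[pairs[drawn, 1]],
      protein2 = gene_names[pairs[drawn, 2]],
      combined_score = round(stats::runif(sum(drawn), 0.4, 1), 3),
      stringsAsFactors = FALSE
    )
    structure(
      list(raw = raw, gene_edges = gene_edges, truth_means = truth_means,
           gene_modules = modules, spec = spec),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d cells, %d clusters, %d genes (%d modules), %d gene edges\n",
    nrow(x$raw$counts), x$spec$k, x$spec$d_g, x$spec$n_gene_modules,
    nrow(x$gene_edges)))
  invisible(x)
}

#' Newman modularity of a gene graph under a module partition
#'
#' Used to check that the planted gene-graph communities are real
#' structure (higher modularity than degree-matched rewired graphs).
#'
#' @param edges two-column matrix/data.frame of node indices or names.
#' @param membership module id per node.
#' @param nodes node name universe when `edges` holds names.
#' @return scalar modularity.
#' @export
graph_modularity <- function(edges, membership, nodes = NULL) {
  e <- as.matrix(edges[, 1:2])
  if (is.character(e)) {
    idx <- stats::setNames(seq_along(nodes), nodes)
    e <- cbind(idx[e[, 1]], idx[e[, 2]])
  }
  storage.mode(e) <- "integer"
  m <- nrow(e)
  if (m == 0) return(0)
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = length(membership))
  same <- membership[e[, 1]] == membership[e[, 2]]
  q <- sum(same) / m
  for (comm in unique(membership)) {
    q <- q - (sum(deg[membership == comm]) / (2 * m))^2
  }
  q
}
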