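#' Train skip-gram embeddings with negative sampling on a walk corpus
#'
#' Fits node vectors that maximize the log probability of observing each
#' node's walk-context within a window of `cfg$window`, using negative
#' sampling (noise distribution proportional to unigram frequency to the
#' 3/4 power, the word2vec convention) and SGD with a linearly decayed
#' learning rate. Deterministic given `cfg$seed`. Only nodes that appear
#' in at least one walk receive a vector.
#'
#' @param walks list of walks as integer or character vectors (e.g. from
#'   [generate_walks()]).
#' @param cfg a [walk_config()].
#' @return numeric matrix, one row per trained node, `cfg$dim` columns;
#'   rownames are the node tokens as characters.
#' @export
train_skipgram <- function(walks, cfg) {
  if (cfg$dim <= 0) stop("embedding dim must be positive")
  if (length(walks) < 1) stop("train_skipgram needs at least one walk")
  tokens <- lapply(walks, as.character)
  vocab <- sort(unique(unlist(tokens)))
  vid <- stats::setNames(seq_along(vocab), vocab)
  seqs <- lapply(tokens, function(w) unname(vid[w]))
  counts <- tabulate(unlist(seqs), nbins = length(vocab))
  noise_p <- counts^0.75
  noise_p <- noise_p / sum(noise_p)
  d <- cfg$dim
  ns <- cfg$negative_samples
  w <- cfg$window
  total_tokens <- sum(lengths(seqs)) * cfg$epochs
  with_seed(derive_seed(cfg$seed, "skipgram"), {
    v_in <- matrix(stats::runif(length(vocab) * d, -0.5, 0.5) / d,
                   nrow = length(vocab))
    v_out <- matrix(0, nrow = length(vocab), ncol = d)
    seen <- 0L
    min_lr <- cfg$lr * 1e-4
    for (ep in seq_len(cfg$epochs)) {
      for (s in seqs) {
        L <- length(s)
        for (t in seq_len(L)) {
          seen <- seen + 1L
          ctx <- s[max(1L, t - w):min(L, t + w)][-(t - max(1L, t - w) + 1L)]
          if (length(ctx) == 0L) next
          lr_t <- max(min_lr,
                      cfg$lr * (1 - (seen - 1L) / max(1L, total_tokens)))
          c_id <- s[t]
          neg <- sample.int(length(vocab), length(ctx) * ns,
                            replace = TRUE, prob = noise_p)
          targets <- c(ctx, neg)
          labels <- c(rep(1, length(ctx)), rep(0, length(neg)))
          vin_c <- v_in[c_id, ]
          score <- as.vector(v_out[targets, , drop = FALSE] %*% vin_c)
          g <- lr_t * (labels - sigmoid(score))
          grad_in <- as.vector(crossprod(v_out[targets, , drop = FALSE], g))
          # targets may repeat inside one batch: aggregate before updating
          upd <- rowsum(outer(g, vin_c), group = targets)
          uid <- as.integer(rownames(upd))
          v_out[uid, ] <- v_out[uid, ] + upd
          v_in[c_id, ] <- vin_c + grad_in
        }
      }
    }
    rownames(v_in) <- vocab
    v_in
  })
}

#' Assemble the gene embedding matrix in HVG order
#'
#' Builds the d_g x d_e matrix whose i-th row is the trained vector of the
#' i-th highly variable gene. HVGs that never appeared in a walk (isolated
#' in, or absent from, the interaction graph) receive a seeded low-variance
#' Gaussian row (sd 0.01) so downstream shapes are independent of
#' interaction coverage; `matched_mask` records which rows are real.
#'
#' @param vectors matrix from [train_skipgram()] with node-token rownames,
#'   or a named list of vectors.
#' @param hvg_names HVG names defining the row order.
#' @param cfg a [walk_config()] (supplies `dim` and `seed`).
#' @param node_names optional mapping from walk tokens to gene names; pass
#'   `g$nodes` when walks were generated over ordinals.
#' @return list of class `gene_embeddings` with `X_g` (d_g x d_e),
#'   `matched_mask` (logical d_g), `hvg_names`.
#' @export
assemble_gene_embeddings <- function(vectors, hvg_names, cfg,
                                     node_names = NULL) {
  if (is.list(vectors) && !is.matrix(vectors)) {
    vectors <- do.call(rbind, vectors)
  }
  if (!is.null(node_names) && !is.null(rownames(vectors))) {
    rownames(vectors) <- node_names[as.integer(rownames(vectors))]
  }
  d_e <- cfg$dim
  d_g <- length(hvg_names)
  X_g <- matrix(NA_real_, d_g, d_e, dimnames = list(hvg_names, NULL))
  matched <- hvg_names %in% rownames(vectors)
  if (any(matched)) {
    X_g[matched, ] <- vectors[hvg_names[matched], , drop = FALSE]
  }
  if (any(!matched)) {
    # one seeded draw per gene NAME (not row position) so that permuting
    # hvg_names permutes the rows identically
    base <- derive_seed(cfg$seed, "fallback")
    for (i in which(!matched)) {
      gseed <- (base + sum(utf8ToInt(hvg_names[i]) *
                             seq_along(utf8ToInt(hvg_names[i])))) %% 2147483629
      X_g[i, ] <- with_seed(gseed, stats::rnorm(d_e, 0, 0.01))
    }
  }
  stopifnot(all(is.finite(X_g)))
  structure(list(X_g = X_g, matched_mask = matched, hvg_names = hvg_names),
            class = "gene_embeddings")
}

#' @export
print.gene_embeddings <- function(x, ...) {
  cat(sprintf("<gene_embeddings> %d genes x %d dims (%d matched)\n",
              nrow(x$X_g), ncol(x$X_g), sum(x$matched_mask)))
  invisible(x)
}

#' Embed the HVG set on a gene-interaction graph
#'
#' Convenience wrapper for stage one of the pipeline: biased random walks
#' on the gene graph, skip-gram training, and assembly of the embedding
#' matrix in HVG order.
#'
#' @param g a [parse_edge_list()] gene graph over the HVGs.
#' @param cfg a [walk_config()].
#' @return a `gene_embeddings` object.
#' @export
embed_genes <- function(g, cfg) {
  walks <- generate_walks(g, cfg)
  if (length(walks) == 0) {
    vectors <- matrix(numeric(0), 0, cfg$dim)
  } else {
    vectors <- train_skipgram(walks, cfg)
    rownames(vectors) <- g$nodes[as.integer(rownames(vectors))]
  }
  assemble_gene_embeddings(vectors, g$nodes, cfg)
}
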