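#' Graph-attention layer parameters
#'
#' One layer holds a weight matrix `W` (in_dim x out_dim) and an attention
#' vector `a` of length `2 * out_dim` (stored split as `a1`, `a2` for the
#' source and target halves of the concatenation); attention scores pass
#' through a LeakyReLU with negative slope 0.2 before the neighborhood
#' softmax.
#'
#' @param in_dim,out_dim layer dimensions.
#' @param slope LeakyReLU negative slope inside the attention (default 0.2).
#' @param activation `"elu"` for hidden layers, `"identity"` at the
#'   bottleneck.
#' @return a list of class `gat_params`. Initialization is Glorot-uniform
#'   for `W` and small uniform for `a`; call inside [with_seed()] or a
#'   seeded context for reproducibility.
#' @export
gat_params <- function(in_dim, out_dim, slope = 0.2,
                       activation = c("elu", "identity")) {
  activation <- match.arg(activation)
  lim <- sqrt(6 / (in_dim + out_dim))
  structure(list(
    W = matrix(stats::runif(in_dim * out_dim, -lim, lim), in_dim, out_dim),
    a1 = stats::runif(out_dim, -0.1, 0.1),
    a2 = stats::runif(out_dim, -0.1, 0.1),
    slope = slope, activation = activation,
    in_dim = in_dim, out_dim = out_dim
  ), class = "gat_params")
}

dense_params <- function(in_dim, out_dim, activation = c("elu", "identity")) {
  activation <- match.arg(activation)
  lim <- sqrt(6 / (in_dim + out_dim))
  structure(list(
    W = matrix(stats::runif(in_dim * out_dim, -lim, lim), in_dim, out_dim),
    b = rep(0, out_dim), activation = activation,
    in_dim = in_dim, out_dim = out_dim
  ), class = "dense_params")
}

#' Assemble the cooperative cell-gene model
#'
#' Builds the two-branch architecture: a cell encoder made of two graph
#' attention layers (`d_g -> hidden -> d_m`, ELU between layers, identity
#' at the bottleneck) and a gene mapper multilayer perceptron
#' (`d_e -> hidden -> d_m`). Both branches share the bottleneck width
#' `d_m`; their outputs are decoded by an inner-product adjacency decoder
#' and the gene-cell cooperative product.
#'
#' @param d_g number of highly variable genes (cell-encoder input width).
#' @param d_e gene-embedding dimension (gene-mapper input width).
#' @param hidden shared hidden width (default 512).
#' @param d_m bottleneck width (default 256).
#' @param seed seed for parameter initialization.
#' @return a list of class `coop_model` with elements `cell_enc` (list of
#'   `gat_params`), `gene_enc` (list of `dense_params`) and the dims.
#' @export
coop_model <- function(d_g, d_e, hidden = 512, d_m = 256, seed = 1) {
  with_seed(derive_seed(seed, "model"), {
    structure(list(
      cell_enc = list(
        gat_params(d_g, hidden, activation = "elu"),
        gat_params(hidden, d_m, activation = "identity")
      ),
      gene_enc = list(
        dense_params(d_e, hidden, activation = "elu"),
        dense_params(hidden, d_m, activation = "identity")
      ),
      d_g = d_g, d_e = d_e, hidden = hidden, d_m = d_m
    ), class = "coop_model")
  })
}

#' @export
print.coop_model <- function(x, ...) {
  cat(sprintf("<coop_model> cell encoder %d-%d-%d (GAT), gene mapper %d-%d-%d (MLP)\n",
              x$d_g, x$hidden, x$d_m, x$d_e, x$hidden, x$d_m))
  invisible(x)
}

# Self-loop-augmented neighborhood mask used by the attention layers.
adj_with_self <- function(adj) {
  A <- if (inherits(adj, "cell_adjacency")) adj$A_c else as.matrix(adj)
  diag(A) <- 1
  A
}

#' Graph attention coefficients
#'
#' Computes the attention matrix alpha over the self-loop-augmented
#' neighborhoods: `alpha_ij = softmax_j( LeakyReLU( a^T [W h_i || W h_j] ) )`
#' restricted to `j` in `N(i) + {i}`. Each row sums to 1 over the
#' neighborhood and is zero elsewhere.
#'
#' @param H node feature matrix (n x in_dim).
#' @param params a [gat_params()].
#' @param adj a [knn_adjacency()] result or binary matrix (zero diagonal).
#' @return n x n matrix of attention coefficients.
#' @export
gat_attention <- function(H, params, adj) {
  gat_forward(H, params, adj)$alpha
}

# Full forward pass of one GAT layer; returns output and the cache needed
# for the backward pass.
gat_forward <- function(H, params, adj) {
  H <- as.matrix(H)
  if (ncol(H) != params$in_dim) {
    stop("gat layer: feature dim ", ncol(H), " != expected ", params$in_dim)
  }
  mask <- adj_with_self(adj)
  n <- nrow(H)
  G <- H %*% params$W
  s1 <- as.vector(G %*% params$a1)
  s2 <- as.vector(G %*% params$a2)
  E <- matrix(s1, n, n) + matrix(s2, n, n, byrow = TRUE)
  Z <- leaky_relu(E, params$slope)
  Zm <- ifelse(mask > 0, Z, -Inf)
  Zm <- Zm - apply(Zm, 1, max)
  expZ <- ifelse(mask > 0, exp(Zm), 0)
  alpha <- expZ / rowSums(expZ)
  M <- alpha %*% G
  out <- if (params$activation == "elu") elu(M) else M
  list(out = out, alpha = alpha, M = M, G = G, E = E, H = H, mask = mask)
}

gat_backward <- function(cache, params, d_out) {
  act_g <- if (params$activation == "elu") elu_grad(cache$M) else 1
  dM <- d_out * act_g
  G <- cache$G; alpha <- cache$alpha; mask <- cache$mask
  d_alpha <- (dM %*% t(G)) * (mask > 0)
  dG <- t(alpha) %*% dM
  # softmax backward, row-wise over neighborhoods
  rs <- rowSums(alpha * d_alpha)
  dZ <- alpha * (d_alpha - rs)
  dE <- dZ * leaky_relu_grad(cache$E, params$slope)
  ds1 <- rowSums(dE)
  ds2 <- colSums(dE)
  dG <- dG + outer(ds1, params$a1) + outer(ds2, params$a2)
  list(
    dW = crossprod(cache$H, dG),
    da1 = as.vector(crossprod(G, ds1)),
    da2 = as.vector(crossprod(G, ds2)),
    dH = dG %*% t(params$W)
  )
}

#' One graph attention layer update
#'
#' `h_i' = sigma( sum_{j in N(i)+{i}} alpha_ij W h_j )` with sigma = ELU
#' on hidden layers and the identity at the bottleneck.
#'
#' @inheritParams gat_attention
#' @return updated node feature matrix (n x out_dim).
#' @export
gat_layer <- function(H, params, adj) {
  gat_forward(H, params, adj)$out
}

dense_forward <- function(H, params) {
  H <- as.matrix(H)
  if (ncol(H) != params$in_dim) {
    stop("dense layer: feature dim ", ncol(H), " != expected ", params$in_dim)
  }
  M <- sweep(H %*% params$W, 2, params$b, "+")
  out <- if (params$activation == "elu") elu(M) else M
  list(out = out, M = M, H = H)
}

dense_backward <- function(cache, params, d_out) {
  act_g <- if (params$activation == "elu") elu_grad(cache$M) else 1
  dM <- d_out * act_g
  list(
    dW = crossprod(cache$H, dM),
    db = colSums(dM),
    dH = dM %*% t(params$W)
  )
}

#' Encode cells into the bottleneck space
#'
#' Applies the stacked graph attention layers to the processed expression
#' matrix over the cell graph, compressing `d_g -> hidden -> d_m`.
#'
#' @param x a [processed_expression()] or matrix (n x d_g).
#' @param adj a [knn_adjacency()] result.
#' @param model a [coop_model()].
#' @return `Z_c`, an n x d_m matrix.
#' @export
encode_cells <- function(x, adj, model) {
  H <- if (inherits(x, "processed_expression")) x$X_c else as.matrix(x)
  for (layer in model$cell_enc) H <- gat_forward(H, layer, adj)$out
  H
}

#' Map gene embeddings into the bottleneck space
#'
#' Runs the gene-mapper multilayer perceptron `d_e -> hidden -> d_m` so
#' gene and cell representations live in the same feature space.
#'
#' @param x_g a `gene_embeddings` object or matrix (d_g x d_e).
#' @param model a [coop_model()].
#' @return `Z_g`, a d_g x d_m matrix.
#' @export
encode_genes <- function(x_g, model) {
  H <- if (inherits(x_g, "gene_embeddings")) x_g$X_g else as.matrix(x_g)
  for (layer in model$gene_enc) H <- dense_forward(H, layer)$out
  H
}

#' Inner-product adjacency decoder
#'
#' `A_hat = sigmoid(Z_c Z_c^T)`: symmetric by construction, entries in
#' the open interval (0, 1).
#'
#' @param z_c cell bottleneck matrix (n x d_m).
#' @return n x n reconstruction of the cell adjacency.
#' @export
reconstruct_adjacency <- function(z_c) {
  s <- tcrossprod(as.matrix(z_c))
  sigmoid((s + t(s)) / 2)
}

#' Gene-cell cooperative reconstruction
#'
#' `X_hat = Z_c Z_g^T` — the linear matrix product of the cell and gene
#' bottleneck representations (no nonlinearity; the log-scale target is
#' real-valued).
#'
#' @param z_c cell bottleneck matrix (n x d_m).
#' @param z_g gene bottleneck matrix (d_g x d_m).
#' @return n x d_g reconstruction of the expression matrix.
#' @export
cooperative_reconstruction <- function(z_c, z_g) {
  z_c <- as.matrix(z_c); z_g <- as.matrix(z_g)
  if (ncol(z_c) != ncol(z_g)) {
    stop("cooperative_reconstruction: bottleneck dims differ (",
         ncol(z_c), " vs ", ncol(z_g), ")")
  }
  tcrossprod(z_c, z_g)
}

#' Reconstruction loss
#'
#' Mean-squared-error alignment of both decoders:
#' `L_r = mean((A - A_hat)^2) + mean((X - X_hat)^2)`. Each term is the
#' mean over its own entries so the two stay scale-comparable across
#' `n` and `d_g`.
#'
#' @param adj target adjacency ([knn_adjacency()] result or matrix).
#' @param A_hat reconstructed adjacency.
#' @param x target expression ([processed_expression()] or matrix).
#' @param X_hat cooperative reconstruction.
#' @return scalar loss, >= 0, zero iff both reconstructions are exact.
#' @export
reconstruction_loss <- function(adj, A_hat, x, X_hat) {
  A <- if (inherits(adj, "cell_adjacency")) adj$A_c else as.matrix(adj)
  X <- if (inherits(x, "processed_expression")) x$X_c else as.matrix(x)
  if (!all(dim(A) == dim(A_hat))) stop("adjacency shape mismatch")
  if (!all(dim(X) == dim(X_hat))) stop("expression shape mismatch")
  mean((A - A_hat)^2) + mean((X - X_hat)^2)
}

#' Student-t soft cluster assignment
#'
#' `q_ij = (1 + ||z_i - mu_j||^2)^(-1) / sum_j' (1 + ||z_i - mu_j'||^2)^(-1)`
#' (Student-t kernel with one degree of freedom); rows sum to 1.
#'
#' @param z_c cell bottleneck matrix (n x d_m).
#' @param centers cluster center matrix mu (k x d_m).
#' @return n x k soft assignment matrix Q.
#' @export
soft_assignment <- function(z_c, centers) {
  z_c <- as.matrix(z_c); centers <- as.matrix(centers)
  if (any(!is.finite(z_c)) || any(!is.finite(centers))) {
    stop("soft_assignment: non-finite embeddings or centers")
  }
  d2 <- sq_dist(z_c, centers)
  w <- 1 / (1 + d2)
  w / rowSums(w)
}

# pairwise squared Euclidean distances, rows of a vs rows of b
sq_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Auxiliary target distribution
#'
#' Sharpens Q by squaring and normalizing by soft cluster frequency:
#' `p_ij = (q_ij^2 / f_j) / sum_j'(q_ij'^2 / f_j')` with `f_j = sum_i q_ij`.
#' Rows sum to 1; one-hot rows are fixed points.
#'
#' @param Q soft assignment matrix from [soft_assignment()].
#' @return n x k target matrix P.
#' @export
target_distribution <- function(Q) {
  Q <- as.matrix(Q)
  f <- colSums(Q)
  if (any(f <= 0)) {
    stop("target_distribution: empty soft cluster (zero Q column ",
         paste(which(f <= 0), collapse = ", "), ")")
  }
  num <- sweep(Q^2, 2, f, "/")
  num / rowSums(num)
}

#' KL clustering loss
#'
#' `L_c = sum_ij p_ij log(p_ij / q_ij)` with the convention
#' `0 * log(0/q) = 0`; nonnegative, zero iff P equals Q.
#'
#' @param P target distribution rows.
#' @param Q soft assignment rows.
#' @return scalar KL divergence.
#' @export
clustering_loss <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("clustering_loss: shape mismatch")
  pos <- P > 0
  if (any(Q[pos] == 0)) {
    stop("clustering_loss: q_ij = 0 where p_ij > 0 (infinite divergence)")
  }
  sum(P[pos] * log(P[pos] / Q[pos]))
}

#' Total training objective
#'
#' `L = L_r + lambda * L_c`, with lambda balancing reconstruction against
#' the clustering loss (default 100).
#'
#' @param L_r reconstruction loss.
#' @param L_c clustering loss.
#' @param lambda nonnegative balance weight.
#' @return scalar total loss.
#' @export
total_loss <- function(L_r, L_c, lambda = 100) {
  if (lambda < 0) stop("lambda must be >= 0")
  L_r + lambda * L_c
}
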