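#' Training configuration
#'
#' Defaults mirror the reference setting: 500 total epochs at learning
#' rate 1e-5 with balance weight lambda = 100; the first `warmup_epochs`
#' epochs optimize the reconstruction loss alone (the clustering head is
#' only initialized afterwards, the standard deep-embedded-clustering
#' schedule), and the target distribution P is recomputed every
#' `p_update_interval` epochs and held fixed in between (no gradient
#' flows through P).
#'
#' @param k number of clusters (>= 2).
#' @param total_epochs total epochs, warm-up included (default 500).
#' @param lr Adam learning rate (default 1e-5).
#' @param lambda clustering-loss weight (default 100).
#' @param warmup_epochs reconstruction-only epochs (default 100); must be
#'   smaller than `total_epochs`.
#' @param p_update_interval epochs between target-distribution refreshes
#'   (default 1).
#' @param seed RNG seed (initialization and center seeding).
#' @return a list of class `train_config`.
#' @export
train_config <- function(k, total_epochs = 500, lr = 1e-5, lambda = 100,
                         warmup_epochs = 100, p_update_interval = 1,
                         seed = 1) {
  stopifnot(k >= 2, lr > 0, lambda >= 0, warmup_epochs >= 0,
            warmup_epochs < total_epochs, p_update_interval >= 1)
  structure(list(k = as.integer(k), total_epochs = as.integer(total_epochs),
                 lr = lr, lambda = lambda,
                 warmup_epochs = as.integer(warmup_epochs),
                 p_update_interval = p_update_interval,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' A small-data profile used by the test-suite and examples: learning
#' rate 1e-3, 50 warm-up plus 150 joint epochs. The reference profile
#' (500 epochs at 1e-5) is tuned to real dataset sizes and is far too
#' slow-moving for the few-hundred-cell synthetic fixtures.
#'
#' @inheritParams train_config
#' @param ... overrides forwarded to [train_config()].
#' @return a `train_config`.
#' @export
desk_train_config <- function(k, seed = 1, ...) {
  args <- utils::modifyList(
    list(k = k, total_epochs = 200, lr = 1e-3, warmup_epochs = 50,
         seed = seed),
    list(...))
  do.call(train_config, args)
}

# ---- parameter flattening & Adam ------------------------------------------

param_list <- function(model) {
  out <- list()
  for (i in seq_along(model$cell_enc)) {
    l <- model$cell_enc[[i]]
    out[[paste0("c", i, ".W")]] <- l$W
    out[[paste0("c", i, ".a1")]] <- l$a1
    out[[paste0("c", i, ".a2")]] <- l$a2
  }
  for (i in seq_along(model$gene_enc)) {
    l <- model$gene_enc[[i]]
    out[[paste0("g", i, ".W")]] <- l$W
    out[[paste0("g", i, ".b")]] <- l$b
  }
  out
}

set_params <- function(model, plist) {
  for (i in seq_along(model$cell_enc)) {
    model$cell_enc[[i]]$W <- plist[[paste0("c", i, ".W")]]
    model$cell_enc[[i]]$a1 <- plist[[paste0("c", i, ".a1")]]
    model$cell_enc[[i]]$a2 <- plist[[paste0("c", i, ".a2")]]
  }
  for (i in seq_along(model$gene_enc)) {
    model$gene_enc[[i]]$W <- plist[[paste0("g", i, ".W")]]
    model$gene_enc[[i]]$b <- plist[[paste0("g", i, ".b")]]
  }
  model
}

adam_init <- function(plist) {
  list(m = lapply(plist, function(p) p * 0),
       v = lapply(plist, function(p) p * 0), t = 0L)
}

adam_step <- function(plist, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(plist)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    plist[[nm]] <- plist[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = plist, state = state)
}

# ---- full forward / backward ----------------------------------------------

model_forward <- function(model, X, adj, X_g) {
  cc <- vector("list", length(model$cell_enc))
  H <- X
  for (i in seq_along(model$cell_enc)) {
    cc[[i]] <- gat_forward(H, model$cell_enc[[i]], adj)
    H <- cc[[i]]$out
  }
  Z_c <- H
  gc_ <- vector("list", length(model$gene_enc))
  H <- X_g
  for (i in seq_along(model$gene_enc)) {
    gc_[[i]] <- dense_forward(H, model$gene_enc[[i]])
    H <- gc_[[i]]$out
  }
  Z_g <- H
  S <- tcrossprod(Z_c)
  A_hat <- sigmoid(S)
  X_hat <- tcrossprod(Z_c, Z_g)
  list(Z_c = Z_c, Z_g = Z_g, A_hat = A_hat, X_hat = X_hat,
       cell_caches = cc, gene_caches = gc_)
}

# Gradients of L_r (+ lambda * L_c when a cluster head is supplied) with
# respect to every parameter. Returns grads, the loss pieces, and Q.
model_backward <- function(model, fw, A, X, lambda = 0, centers = NULL,
                           P = NULL, gene_branch = TRUE) {
  n <- nrow(A); d_g <- ncol(X)
  Z_c <- fw$Z_c; Z_g <- fw$Z_g
  dA_hat <- 2 * (fw$A_hat - A) / (n * n)
  dS <- dA_hat * fw$A_hat * (1 - fw$A_hat)
  dZ_c <- (dS + t(dS)) %*% Z_c
  R <- fw$X_hat - X
  dZ_c <- dZ_c + (2 / (n * d_g)) * (R %*% Z_g)
  dZ_g <- (2 / (n * d_g)) * crossprod(R, Z_c)
  L_r <- mean((A - fw$A_hat)^2) + mean(R^2)

  Q <- NULL; L_c <- NA_real_; d_mu <- NULL
  if (!is.null(centers)) {
    d2 <- sq_dist(Z_c, centers)
    w <- 1 / (1 + d2)
    Q <- w / rowSums(w)
    if (!is.null(P)) {
      pos <- P > 0
      L_c <- sum(P[pos] * log(P[pos] / Q[pos]))
      if (lambda > 0) {
        B <- w * (P - Q)
        dZ_c <- dZ_c + lambda * 2 * (rowSums(B) * Z_c - B %*% centers)
        d_mu <- lambda * 2 * (colSums(B) * centers - crossprod(B, Z_c))
      }
    }
  }

  grads <- list()
  d_back <- dZ_c
  for (i in rev(seq_along(model$cell_enc))) {
    bk <- gat_backward(fw$cell_caches[[i]], model$cell_enc[[i]], d_back)
    grads[[paste0("c", i, ".W")]] <- bk$dW
    grads[[paste0("c", i, ".a1")]] <- bk$da1
    grads[[paste0("c", i, ".a2")]] <- bk$da2
    d_back <- bk$dH
  }
  if (gene_branch) {
    d_back <- dZ_g
    for (i in rev(seq_along(model$gene_enc))) {
      bk <- dense_backward(fw$gene_caches[[i]], model$gene_enc[[i]], d_back)
      grads[[paste0("g", i, ".W")]] <- bk$dW
      grads[[paste0("g", i, ".b")]] <- bk$db
      d_back <- bk$dH
    }
  }
  list(grads = grads, L_r = L_r, L_c = L_c, Q = Q, d_mu = d_mu)
}

# ---- public training operations -------------------------------------------

#' Warm-up training on the reconstruction loss alone
#'
#' Runs `cfg$warmup_epochs` full-batch Adam steps on
#' `L_r = mean((A - A_hat)^2) + mean((X - X_hat)^2)`, before any cluster
#' head exists. Deterministic given the model and inputs.
#'
#' @param model a [coop_model()].
#' @param x a [processed_expression()] or matrix (n x d_g).
#' @param adj a [knn_adjacency()] result.
#' @param x_g a `gene_embeddings` object or matrix (d_g x d_e).
#' @param cfg a [train_config()].
#' @param gene_branch set `FALSE` to freeze the gene mapper (ablation).
#' @return the trained model, with the per-epoch `L_r` trace in
#'   `attr(, "history")`.
#' @export
pretrain <- function(model, x, adj, x_g, cfg, gene_branch = TRUE) {
  X <- if (inherits(x, "processed_expression")) x$X_c else as.matrix(x)
  A <- if (inherits(adj, "cell_adjacency")) adj$A_c else as.matrix(adj)
  X_g <- if (inherits(x_g, "gene_embeddings")) x_g$X_g else as.matrix(x_g)
  if (cfg$warmup_epochs == 0) {
    attr(model, "history") <- numeric(0)
    return(model)
  }
  plist <- param_list(model)
  state <- adam_init(plist)
  hist <- numeric(cfg$warmup_epochs)
  for (ep in seq_len(cfg$warmup_epochs)) {
    fw <- model_forward(model, X, adj, X_g)
    bk <- model_backward(model, fw, A, X, gene_branch = gene_branch)
    if (!is.finite(bk$L_r)) {
      stop("pretrain: non-finite reconstruction loss at epoch ", ep)
    }
    hist[ep] <- bk$L_r
    st <- adam_step(plist, bk$grads, state, cfg$lr)
    plist <- st$params; state <- st$state
    model <- set_params(model, plist)
  }
  attr(model, "history") <- hist
  model
}

#' Initialize cluster centers on the current embedding
#'
#' k-means (k-means++ seeding, 20 restarts) on `Z_c`; the converged means
#' become the initial trainable centers of the clustering head.
#'
#' @param z_c cell bottleneck matrix (n x d_m).
#' @param k number of centers.
#' @param seed RNG seed.
#' @return k x d_m center matrix.
#' @export
init_centers <- function(z_c, k, seed = 1) {
  z_c <- as.matrix(z_c)
  if (nrow(z_c) < k) stop("init_centers: n < k")
  if (k == nrow(z_c)) return(z_c)   # one center per point
  km <- kmeans_cluster(z_c, k, seed = derive_seed(seed, "centers"))
  km$centers
}

#' Fit the cooperative model: warm-up, center seeding, joint optimization
#'
#' The optimization schedule: (1) `warmup_epochs` reconstruction-only
#' epochs; (2) k-means center initialization on the warm embedding;
#' (3) joint epochs minimizing `L = L_r + lambda * L_c`, where Q is the
#' Student-t soft assignment, P is the sharpened target recomputed every
#' `p_update_interval` epochs with no gradient flowing through it, and
#' the centers are updated by gradient alongside the network. An empty
#' soft cluster triggers reinitialization of that center to the
#' embedding farthest from all current centers.
#'
#' @inheritParams pretrain
#' @param labels optional ground-truth labels; when given, the per-epoch
#'   ARI of `argmax Q` is recorded in the history.
#' @return list with `model`, `head` (list: `centers`, `Q`, `P`, `k`),
#'   and `history` (data.frame: epoch, phase, L_r, L_c, L_total, ari).
#' @export
fit <- function(model, x, adj, x_g, cfg, gene_branch = TRUE, labels = NULL) {
  X <- if (inherits(x, "processed_expression")) x$X_c else as.matrix(x)
  A <- if (inherits(adj, "cell_adjacency")) adj$A_c else as.matrix(adj)
  X_g <- if (inherits(x_g, "gene_embeddings")) x_g$X_g else as.matrix(x_g)
  stopifnot(nrow(X) == nrow(A), ncol(X) == nrow(X_g))

  model <- pretrain(model, x, adj, x_g, cfg, gene_branch = gene_branch)
  warm_hist <- attr(model, "history")

  fw <- model_forward(model, X, adj, X_g)
  centers <- init_centers(fw$Z_c, cfg$k, seed = cfg$seed)

  plist <- param_list(model)
  plist$mu <- centers
  state <- adam_init(plist)
  n_joint <- cfg$total_epochs - cfg$warmup_epochs
  hist <- data.frame(
    epoch = seq_len(cfg$total_epochs), phase = "warmup",
    L_r = NA_real_, L_c = NA_real_, L_total = NA_real_, ari = NA_real_
  )
  if (cfg$warmup_epochs > 0) {
    hist$L_r[seq_len(cfg$warmup_epochs)] <- warm_hist
    hist$L_total[seq_len(cfg$warmup_epochs)] <- warm_hist
  }
  P <- NULL
  events <- character(0)
  for (je in seq_len(n_joint)) {
    ep <- cfg$warmup_epochs + je
    fw <- model_forward(model, X, adj, X_g)
    Q_now <- soft_assignment(fw$Z_c, plist$mu)
    empty <- which(colSums(Q_now) < 1e-12)
    if (length(empty) > 0) {
      d2 <- sq_dist(fw$Z_c, plist$mu)
      far <- which.max(apply(d2, 1, min))
      for (j in empty) plist$mu[j, ] <- fw$Z_c[far, ]
      events <- c(events, sprintf("epoch %d: reinitialized center(s) %s",
                                  ep, paste(empty, collapse = ",")))
      Q_now <- soft_assignment(fw$Z_c, plist$mu)
    }
    if (is.null(P) || (je - 1) %% cfg$p_update_interval == 0) {
      P <- target_distribution(Q_now)
    }
    bk <- model_backward(model, fw, A, X, lambda = cfg$lambda,
                         centers = plist$mu, P = P,
                         gene_branch = gene_branch)
    L_tot <- total_loss(bk$L_r, bk$L_c, cfg$lambda)
    if (!is.finite(L_tot)) stop("fit: non-finite total loss at epoch ", ep)
    hist$phase[ep] <- "joint"
    hist$L_r[ep] <- bk$L_r
    hist$L_c[ep] <- bk$L_c
    hist$L_total[ep] <- L_tot
    if (!is.null(labels)) {
      hist$ari[ep] <- ari(labels, max.col(bk$Q, ties.method = "first"))
    }
    grads <- bk$grads
    if (!is.null(bk$d_mu)) grads$mu <- bk$d_mu
    st <- adam_step(plist, grads, state, cfg$lr)
    plist <- st$params; state <- st$state
    model <- set_params(model, plist)
  }
  fw <- model_forward(model, X, adj, X_g)
  Q <- soft_assignment(fw$Z_c, plist$mu)
  P_final <- tryCatch(target_distribution(Q), error = function(e) NULL)
  list(
    model = model,
    head = list(centers = plist$mu, Q = Q, P = P_final, k = cfg$k),
    history = hist,
    events = events,
    Z_c = fw$Z_c,
    Z_g = fw$Z_g
  )
}
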