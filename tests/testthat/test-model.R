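# hand-buildable layer parameters
manual_gat <- function(W, a1, a2, activation = "identity") {
  structure(list(W = W, a1 = a1, a2 = a2, slope = 0.2,
                 activation = activation,
                 in_dim = nrow(W), out_dim = ncol(W)),
            class = "gat_params")
}

test_that("gat_attention matches a scalar softmax oracle on a 3-node path", {
  # path 1-2-3, hand-set parameters, manual evaluation of the attention row
  adj <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  H <- rbind(c(1, 0), c(0, 1), c(1, 1))
  W <- rbind(c(0.5, -0.2), c(0.3, 0.4))
  a1 <- c(0.7, -0.1); a2 <- c(0.2, 0.6)
  params <- manual_gat(W, a1, a2)
  alpha <- gat_attention(H, params, adj)

  lrelu <- function(x) if (x > 0) x else 0.2 * x
  G <- H %*% W
  # middle node attends over {1, 2, 3} (self-loop included)
  e <- sapply(1:3, function(j) {
    lrelu(sum(a1 * G[2, ]) + sum(a2 * G[j, ]))
  })
  oracle <- exp(e) / sum(exp(e))
  expect_equal(alpha[2, ], oracle, tolerance = 1e-12)
  # node 1 attends over {1, 2} only
  e1 <- sapply(1:2, function(j) lrelu(sum(a1 * G[1, ]) + sum(a2 * G[j, ])))
  expect_equal(alpha[1, 1:2], exp(e1) / sum(exp(e1)), tolerance = 1e-12)
  expect_equal(alpha[1, 3], 0)

  # rows are simplex vectors over the augmented neighborhood
  expect_equal(rowSums(alpha), rep(1, 3))

  # singleton neighborhood -> attention 1 on the self-loop
  iso <- matrix(0, 2, 2)
  ai <- gat_attention(H[1:2, ], params, iso)
  expect_equal(diag(ai), c(1, 1))

  # identical features -> uniform attention over each neighborhood
  Hc <- rbind(c(1, 2), c(1, 2), c(1, 2))
  ac <- gat_attention(Hc, params, adj)
  expect_equal(ac[2, ], rep(1 / 3, 3))
  expect_equal(ac[1, 1:2], rep(1 / 2, 2))

  expect_error(gat_attention(cbind(H, 1), params, adj), "feature dim")
})

test_that("gat_layer continues the same manual computation", {
  adj <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  H <- rbind(c(1, 0), c(0, 1), c(1, 1))
  W <- rbind(c(0.5, -0.2), c(0.3, 0.4))
  params <- manual_gat(W, c(0.7, -0.1), c(0.2, 0.6))
  alpha <- gat_attention(H, params, adj)
  out <- gat_layer(H, params, adj)
  G <- H %*% W
  for (i in 1:3) {
    expect_equal(out[i, ], as.vector(alpha[i, ] %*% G), tolerance = 1e-12)
  }
  # zero features give sigma(0) everywhere; uniform alpha + equal h gives W h
  expect_equal(gat_layer(H * 0, params, adj), matrix(0, 3, 2),
               ignore_attr = TRUE)
  Hc <- rbind(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(gat_layer(Hc, params, adj)[2, ], as.vector(Hc[1, ] %*% W))
})

test_that("encoders produce the annotated shapes", {
  set.seed(2)
  n <- 12; d_g <- 9; d_e <- 6; d_m <- 3
  model <- coop_model(d_g, d_e, hidden = 5, d_m = d_m, seed = 1)
  X <- matrix(rnorm(n * d_g), n, d_g)
  adj <- knn_adjacency(pearson_matrix(X), 3)
  Z_c <- encode_cells(X, adj, model)
  expect_equal(dim(Z_c), c(n, d_m))
  X_g <- matrix(rnorm(d_g * d_e), d_g, d_e)
  Z_g <- encode_genes(X_g, model)
  expect_equal(dim(Z_g), c(d_g, d_m))

  # single-cell graph (self-loop only) degenerates to a plain perceptron:
  # alpha = 1 so each layer is just act(h W)
  one <- matrix(0, 1, 1)
  x1 <- X[1, , drop = FALSE]
  z1 <- encode_cells(x1, one, model)
  l1 <- x1 %*% model$cell_enc[[1]]$W
  l1 <- ifelse(l1 > 0, l1, exp(l1) - 1)
  oracle <- l1 %*% model$cell_enc[[2]]$W
  expect_equal(z1, oracle, tolerance = 1e-12)

  # gene mapper fixture with hand-set weights: explicit matrix arithmetic
  gm <- model$gene_enc
  h <- X_g %*% gm[[1]]$W + matrix(gm[[1]]$b, d_g, 5, byrow = TRUE)
  h <- ifelse(h > 0, h, exp(h) - 1)
  expect_equal(Z_g, h %*% gm[[2]]$W + matrix(gm[[2]]$b, d_g, 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("decoders match their closed forms", {
  # zero embedding: all entries sigmoid(0) = 0.5
  expect_equal(reconstruct_adjacency(matrix(0, 3, 2)),
               matrix(0.5, 3, 3))
  # orthogonal unit rows: off-diagonal 0.5, diagonal sigmoid(1)
  I <- diag(2)
  A_hat <- reconstruct_adjacency(I)
  expect_equal(diag(A_hat), rep(1 / (1 + exp(-1)), 2))
  expect_equal(A_hat[1, 2], 0.5)
  # random Gram oracle + exact symmetry
  set.seed(5)
  Z <- matrix(rnorm(12), 4, 3)
  got <- reconstruct_adjacency(Z)
  expect_equal(got, 1 / (1 + exp(-Z %*% t(Z))), tolerance = 1e-12)
  expect_identical(got, t(got))
  expect_true(all(got > 0 & got < 1))

  # cooperative reconstruction: triple-loop oracle
  Zc <- matrix(rnorm(6), 3, 2); Zg <- matrix(rnorm(8), 4, 2)
  X_hat <- cooperative_reconstruction(Zc, Zg)
  expect_equal(dim(X_hat), c(3, 4))
  for (i in 1:3) for (j in 1:4) {
    expect_equal(X_hat[i, j], sum(Zc[i, ] * Zg[j, ]))
  }
  # basis rows copy coordinates; zero factor nulls the product
  expect_equal(cooperative_reconstruction(Zc, diag(2)), Zc)
  expect_equal(cooperative_reconstruction(Zc, Zg * 0), matrix(0, 3, 4))
  expect_error(cooperative_reconstruction(Zc, matrix(0, 4, 3)),
               "bottleneck dims")
})

test_that("reconstruction_loss is the two-term mean squared error", {
  A <- rbind(c(0, 1), c(1, 0)); X <- rbind(c(1, 2), c(3, 4))
  expect_equal(reconstruction_loss(A, A, X, X), 0)
  # constant unit residual on X contributes exactly 1
  expect_equal(reconstruction_loss(A, A, X, X + 1), 1)
  # random fixture against the flat sum-of-squares oracle
  set.seed(8)
  A_hat <- matrix(runif(4), 2, 2); X_hat <- matrix(rnorm(4), 2, 2)
  expect_equal(reconstruction_loss(A, A_hat, X, X_hat),
               sum((A - A_hat)^2) / 4 + sum((X - X_hat)^2) / 4)
  expect_error(reconstruction_loss(A, matrix(0, 3, 3), X, X_hat), "shape")
})

test_that("soft_assignment is the Student-t kernel of the hand oracle", {
  mu <- rbind(c(0, 0), c(2, 0))
  # equidistant point: (0.5, 0.5)
  expect_equal(soft_assignment(rbind(c(1, 0)), mu)[1, ], c(0.5, 0.5))
  # z at center 1, center 2 at squared distance 3: q = (1 / (1 + 1/4)) = 0.8
  mu2 <- rbind(c(0, 0), c(sqrt(3), 0))
  expect_equal(soft_assignment(rbind(c(0, 0)), mu2)[1, ], c(0.8, 0.2))
  # rows sum to one for random inputs
  set.seed(3)
  Q <- soft_assignment(matrix(rnorm(40), 20, 2), mu)
  expect_equal(rowSums(Q), rep(1, 20))
  expect_true(all(Q > 0))
  expect_error(soft_assignment(rbind(c(NA, 1)), mu), "non-finite")
})

test_that("target_distribution matches the termwise sharpening oracle", {
  # uniform is a fixed point
  Qu <- matrix(1 / 3, 4, 3)
  expect_equal(target_distribution(Qu), Qu)
  # 2x2 hand evaluation: column sums 1.4 and 0.6
  Q <- rbind(c(0.8, 0.2), c(0.6, 0.4))
  num <- rbind(c(0.64 / 1.4, 0.04 / 0.6), c(0.36 / 1.4, 0.16 / 0.6))
  expect_equal(target_distribution(Q), num / rowSums(num))
  # idempotent on one-hot rows
  hard <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(target_distribution(hard), hard)
  expect_error(target_distribution(rbind(c(1, 0), c(1, 0))), "empty soft")
})

test_that("clustering_loss is the termwise KL divergence", {
  P <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  expect_equal(clustering_loss(P, P), 0)
  expect_equal(clustering_loss(rbind(c(1, 0)), rbind(c(0.5, 0.5))), log(2))
  # 0 log 0 convention
  expect_equal(clustering_loss(rbind(c(1, 0)), rbind(c(1, 0))), 0)
  # random pair against a scalar summation oracle
  set.seed(9)
  Q <- matrix(runif(8) + 0.1, 4, 2); Q <- Q / rowSums(Q)
  P2 <- matrix(runif(8) + 0.1, 4, 2); P2 <- P2 / rowSums(P2)
  acc <- 0
  for (i in 1:4) for (j in 1:2) acc <- acc + P2[i, j] * log(P2[i, j] / Q[i, j])
  expect_equal(clustering_loss(P2, Q), acc)
  expect_gte(clustering_loss(P2, Q), 0)
  # perturbation growth ~ O(eps^2)
  eps <- c(1e-2, 1e-3)
  ls <- sapply(eps, function(e) {
    Qe <- P + rbind(c(e, -e), c(-e, e))
    clustering_loss(P, Qe)
  })
  expect_equal(ls[1] / ls[2], 100, tolerance = 0.05)
  expect_error(clustering_loss(rbind(c(1, 0)), rbind(c(0, 1))),
               "infinite divergence")
})

test_that("total_loss combines terms exactly", {
  expect_identical(total_loss(2, 0.03, 100), 2 + 100 * 0.03)
  expect_identical(total_loss(1.5, 99, 0), 1.5)
  expect_equal(formals(total_loss)$lambda, 100)
  expect_error(total_loss(1, 1, -1), "lambda")
})
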