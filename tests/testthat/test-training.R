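# small but non-trivial training setup shared by the blocks below
setup_problem <- function(seed = 1, n = 60, k = 2, d_g = 20) {
  ds <- simulate_dataset(synthetic_spec(n = n, k = k, d_g = d_g,
                                        n_gene_modules = k * 2, seed = seed))
  x <- preprocess(ds$raw, n_top = d_g)
  adj <- build_cell_graph(x, k = 5)
  wc <- walk_config(walk_length = 10, walks_per_node = 3, window = 3,
                    dim = 8, seed = seed)
  g <- parse_edge_list(ds$gene_edges, x$hvg_names)
  emb <- embed_genes(g, wc)
  model <- coop_model(x$d_g, 8, hidden = 12, d_m = 6, seed = seed)
  list(x = x, adj = adj, emb = emb, model = model, k = k)
}

test_that("pretrain reduces reconstruction loss deterministically", {
  pb <- setup_problem()
  cfg <- train_config(k = 2, total_epochs = 40, lr = 1e-3,
                      warmup_epochs = 30, seed = 1)
  m1 <- pretrain(pb$model, pb$x, pb$adj, pb$emb, cfg)
  h1 <- attr(m1, "history")
  expect_length(h1, 30)
  expect_true(all(is.finite(h1)))
  expect_lt(tail(h1, 1), h1[1])     # monotone trend over the warm-up

  # identical seed/model/config -> identical traces
  m2 <- pretrain(pb$model, pb$x, pb$adj, pb$emb, cfg)
  expect_identical(h1, attr(m2, "history"))
  expect_identical(param_list_of(m1), param_list_of(m2))

  # warmup_epochs = 0 returns the model unchanged
  cfg0 <- train_config(k = 2, total_epochs = 10, warmup_epochs = 0, seed = 1)
  m0 <- pretrain(pb$model, pb$x, pb$adj, pb$emb, cfg0)
  expect_identical(param_list_of(m0), param_list_of(pb$model))
})

test_that("init_centers recovers blob means and is seed-stable", {
  set.seed(4)
  blob1 <- matrix(rnorm(40, 0, 0.05), 20, 2)
  blob2 <- sweep(matrix(rnorm(40, 0, 0.05), 20, 2), 2, c(5, 5), "+")
  z <- rbind(blob1, blob2)
  mu <- init_centers(z, 2, seed = 3)
  mu <- mu[order(mu[, 1]), ]
  expect_equal(mu[1, ], colMeans(blob1), tolerance = 0.05)
  expect_equal(mu[2, ], colMeans(blob2), tolerance = 0.05)
  expect_identical(mu, {
    m <- init_centers(z, 2, seed = 3); m[order(m[, 1]), ]
  })
  # k = n: each center equals one embedding row
  z5 <- z[1:5, ]
  expect_equal(init_centers(z5, 5, seed = 1), z5)
  expect_error(init_centers(z5, 9), "n < k")
})

test_that("fit runs the warm-up + joint schedule and records history", {
  pb <- setup_problem()
  cfg <- train_config(k = 2, total_epochs = 60, lr = 1e-3,
                      warmup_epochs = 20, seed = 1)
  res <- fit(pb$model, pb$x, pb$adj, pb$emb, cfg, labels = pb$x$labels)
  h <- res$history
  expect_equal(nrow(h), 60)
  expect_equal(sum(h$phase == "warmup"), 20)
  expect_equal(sum(h$phase == "joint"), 40)
  expect_true(all(is.finite(h$L_total)))
  # identity L_total = L_r + lambda * L_c holds bit-for-bit in the joint phase
  joint <- h[h$phase == "joint", ]
  expect_identical(joint$L_total, joint$L_r + cfg$lambda * joint$L_c)
  expect_true(all(is.finite(joint$ari)))
  # cluster head invariants
  expect_equal(dim(res$head$Q), c(pb$x$n, 2))
  expect_equal(unname(rowSums(res$head$Q)), rep(1, pb$x$n), tolerance = 1e-8)
  expect_equal(unname(rowSums(res$head$P)), rep(1, pb$x$n), tolerance = 1e-8)
  expect_equal(dim(res$head$centers), c(2, 6))

  # reproducibility: identical histories run-to-run
  res2 <- fit(pb$model, pb$x, pb$adj, pb$emb, cfg, labels = pb$x$labels)
  expect_identical(res$history, res2$history)
  expect_identical(res$Z_c, res2$Z_c)
})

test_that("lambda = 0 degenerates to pure autoencoder training", {
  pb <- setup_problem()
  cfg <- train_config(k = 2, total_epochs = 30, lr = 1e-3, lambda = 0,
                      warmup_epochs = 10, p_update_interval = Inf, seed = 1)
  res <- fit(pb$model, pb$x, pb$adj, pb$emb, cfg)
  joint <- res$history[res$history$phase == "joint", ]
  # total loss reduces to the reconstruction loss
  expect_identical(joint$L_total, joint$L_r)
  # final Q is still computable and valid
  expect_equal(unname(rowSums(res$head$Q)), rep(1, pb$x$n), tolerance = 1e-8)

  # and matches a run that never builds the clustering gradient:
  # pure pretrain for the same number of epochs gives the same L_r trace
  cfg_ae <- train_config(k = 2, total_epochs = 31, lr = 1e-3,
                         warmup_epochs = 30, seed = 1)
  m_ae <- pretrain(pb$model, pb$x, pb$adj, pb$emb, cfg_ae)
  expect_equal(res$history$L_r[1:10], attr(m_ae, "history")[1:10])
})

test_that("frozen gene branch changes only the gene mapper updates", {
  pb <- setup_problem()
  cfg <- train_config(k = 2, total_epochs = 25, lr = 1e-3,
                      warmup_epochs = 10, seed = 1)
  res <- fit(pb$model, pb$x, pb$adj, pb$emb, cfg, gene_branch = FALSE)
  # gene mapper parameters never move
  p0 <- param_list_of(pb$model)
  p1 <- param_list_of(res$model)
  expect_identical(p1[["g1.W"]], p0[["g1.W"]])
  expect_identical(p1[["g2.W"]], p0[["g2.W"]])
  # cell encoder still trains
  expect_false(identical(p1[["c1.W"]], p0[["c1.W"]]))
  # shapes unchanged relative to the full model
  expect_equal(dim(res$Z_g), c(pb$x$d_g, 6))
})
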