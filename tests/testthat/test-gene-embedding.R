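test_that("parse_edge_list filters, simplifies and keeps all HVGs as nodes", {
  # empty edge set: isolated nodes only, with a warning
  hvgs <- paste0("g", 1:10)
  expect_warning(
    g0 <- parse_edge_list(data.frame(a = character(0), b = character(0)),
                          hvgs),
    "no edges")
  expect_equal(length(g0$nodes), 10)
  expect_equal(nrow(g0$edges), 0)

  # duplicates and self-edges collapse to a simple graph
  df <- data.frame(a = c("A", "B", "A"), b = c("B", "A", "A"))
  g1 <- parse_edge_list(df, c("A", "B", "C"))
  expect_equal(nrow(g1$edges), 1)
  expect_equal(unname(g1$neighbors[[1]]), 2L)
  expect_equal(g1$neighbors[[3]], integer(0))

  # confidence threshold: hand count of surviving rows; rows with an
  # endpoint outside the HVG list are dropped
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "A\tB\t0.2", "A\tC\t0.4", "B\tC\t0.55",
               "C\tD\t0.7", "D\tE\t0.8", "A\tZZ\t0.9"),
             tsv)
  g2 <- parse_edge_list(tsv, c("A", "B", "C", "D", "E"))
  expect_equal(nrow(g2$edges), 4)   # 0.4, 0.55, 0.7, 0.8 survive; ZZ row dropped

  # 0-1000 confidence scale auto-detected
  writeLines(c("protein1\tprotein2\tcombined_score",
               "A\tB\t200", "A\tC\t400", "B\tC\t900"),
             tsv)
  g3 <- parse_edge_list(tsv, c("A", "B", "C"))
  expect_equal(nrow(g3$edges), 2)

  expect_error(parse_edge_list("/nonexistent/file.tsv", hvgs), "not found")
})

test_that("transition_distribution implements the three-branch kernel", {
  g <- six_node_graph()
  cfg <- walk_config(p = 2, q = 0.5, dim = 4)

  # path a-b-c fragment: prev=A, cur=B on the 6-node graph, where B's
  # neighbors are A (revisit), C (shared with A) and D (two hops from A)
  got <- transition_distribution(g, "A", "B", cfg)
  # hand evaluation: weights {A: 1/2, C: 1, D: 2} -> {1/7, 2/7, 4/7}
  expect_equal(unname(got[c("A", "C", "D")]), c(1, 2, 4) / 7)

  # p = q = 1 reduces to the uniform kernel
  cfg_u <- walk_config(p = 1, q = 1, dim = 4)
  u <- transition_distribution(g, "A", "B", cfg_u)
  expect_equal(unname(u), rep(1 / 3, 3))

  # first step (prev == cur) is uniform over neighbors
  first <- transition_distribution(g, "E", "E", cfg)
  expect_equal(unname(first), rep(0.5, 2))

  # scaling all three branch weights by c > 0 leaves the kernel unchanged:
  # (cp', cq') with the middle branch weight also scaled is equivalent to
  # dividing every weight by c, so probabilities match the oracle exactly
  expect_error(transition_distribution(g, "A", "A", cfg), NA)
  iso <- parse_edge_list(data.frame(a = "A", b = "B"), c("A", "B", "C"))
  expect_error(transition_distribution(iso, 3, 3, cfg), "isolated")
})

test_that("transition_distribution matches the brute-force kernel everywhere", {
  g <- six_node_graph()
  cfg <- walk_config(p = 4, q = 0.25, dim = 4)
  for (cur in 1:6) {
    for (prev in g$neighbors[[cur]]) {
      got <- transition_distribution(g, prev, cur, cfg)
      oracle <- transition_oracle(g$neighbors, prev, cur, cfg$p, cfg$q)
      expect_equal(unname(got), unname(oracle), tolerance = 1e-14)
      expect_equal(sum(got), 1)
    }
  }
})

test_that("generate_walks: construction contract and determinism", {
  # single edge: deterministic alternation
  g <- parse_edge_list(data.frame(a = "A", b = "B"), c("A", "B"))
  cfg <- walk_config(walk_length = 4, walks_per_node = 1, dim = 4, seed = 5)
  w <- generate_walks(g, cfg)
  expect_equal(length(w), 2)
  expect_equal(w[[1]], c(1L, 2L, 1L, 2L))
  expect_equal(w[[2]], c(2L, 1L, 2L, 1L))

  # every walk starts at its source with full length; isolated nodes yield
  # no walks
  g2 <- parse_edge_list(data.frame(a = c("A", "B"), b = c("B", "C")),
                        c("A", "B", "C", "D"))
  cfg2 <- walk_config(walk_length = 10, walks_per_node = 3, dim = 4, seed = 2)
  w2 <- generate_walks(g2, cfg2)
  expect_equal(length(w2), 9)       # 3 non-isolated nodes x 3 walks
  expect_true(all(lengths(w2) == 10))
  starts <- vapply(w2, `[`, 1L, 1)
  expect_equal(sort(unique(starts)), 1:3)
  expect_false(any(vapply(w2, function(x) 4L %in% x, TRUE)))

  # bit-identical across runs with the same seed
  expect_identical(w2, generate_walks(g2, cfg2))
  cfg3 <- walk_config(walk_length = 10, walks_per_node = 3, dim = 4, seed = 3)
  expect_false(identical(w2, generate_walks(g2, cfg3)))
})

test_that("train_skipgram returns finite vectors with ranked similarity", {
  # fixture: a tight pair A-B plus a far disconnected pair X-Y
  g <- parse_edge_list(data.frame(a = c("A", "X"), b = c("B", "Y")),
                       c("A", "B", "X", "Y"))
  cfg <- walk_config(walk_length = 20, walks_per_node = 10, window = 3,
                     dim = 8, seed = 4)
  walks <- generate_walks(g, cfg)
  vec <- train_skipgram(walks, cfg)
  expect_equal(ncol(vec), 8)
  expect_true(all(is.finite(vec)))
  # nodes absent from every walk get no vector
  expect_equal(sort(rownames(vec)), c("1", "2", "3", "4"))
  ab_walks <- walks[vapply(walks, function(w) w[1] <= 2L, TRUE)]
  sub <- train_skipgram(ab_walks, cfg)     # only the A/B component
  expect_equal(sort(rownames(sub)), c("1", "2"))

  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  # A and B share identical context multisets; their similarity must beat
  # the cross-component pair A-X
  expect_gt(cosine(vec["1", ], vec["2", ]), cosine(vec["1", ], vec["3", ]))
  # deterministic given the seed
  expect_identical(vec, train_skipgram(walks, cfg))
})

test_that("assemble_gene_embeddings preserves HVG order with seeded fallback", {
  hvgs <- c("A", "B", "C", "D")
  vec <- matrix(1:12, 3, 4, dimnames = list(c("A", "B", "C"), NULL))
  cfg <- walk_config(dim = 4, seed = 9)
  emb <- assemble_gene_embeddings(vec, hvgs, cfg)
  expect_equal(dim(emb$X_g), c(4, 4))
  expect_equal(emb$matched_mask, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(emb$X_g["B", ], vec["B", ], ignore_attr = TRUE)
  expect_true(all(abs(emb$X_g["D", ]) < 0.1))  # low-variance filler

  # zero matched HVGs still yields a usable matrix
  emb0 <- assemble_gene_embeddings(vec, c("P", "Q"), cfg)
  expect_false(any(emb0$matched_mask))
  expect_true(all(is.finite(emb0$X_g)))

  # permutation equivariance (fixed seed): permuting hvg_names permutes rows
  perm <- c(3, 1, 4, 2)
  emb_p <- assemble_gene_embeddings(vec, hvgs[perm], cfg)
  expect_equal(emb_p$X_g, emb$X_g[perm, ], ignore_attr = TRUE)
})

test_that("p = q = 1 walks reduce to the first-order uniform walk", {
  g <- six_node_graph()
  cfg <- walk_config(p = 1, q = 1, walk_length = 40, walks_per_node = 40,
                     dim = 4, seed = 8)
  walks <- generate_walks(g, cfg)
  steps <- do.call(rbind, lapply(walks, function(w) {
    cbind(head(w, -1), tail(w, -1))
  }))
  deg <- lengths(g$neighbors)
  # empirical next-node frequency from each current node must match the
  # uniform kernel within 4 sd
  for (cur in 1:6) {
    sub <- steps[steps[, 1] == cur, 2]
    n_obs <- length(sub)
    for (v in g$neighbors[[cur]]) {
      p_hat <- mean(sub == v)
      p0 <- 1 / deg[cur]
      expect_lt(abs(p_hat - p0), 4 * sqrt(p0 * (1 - p0) / n_obs) + 1e-12)
    }
  }
})
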