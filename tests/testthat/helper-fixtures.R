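# Shared fixture builders and independent oracles. Oracles deliberately use
# naive scalar code paths, never the package implementation.

make_raw <- function(counts, genes = NULL, cells = NULL, labels = NULL) {
  counts <- as.matrix(counts)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(counts)))
  if (is.null(cells)) cells <- paste0("c", seq_len(nrow(counts)))
  raw_expression(counts, genes, cells, labels)
}

# a deterministic small expression matrix with clear structure
toy_counts <- function(n = 20, d = 10, seed = 99) {
  set.seed(seed)
  matrix(rpois(n * d, lambda = 5) + 1, n, d)
}

# term-by-term Pearson correlation of two vectors (Eq.-style sums)
pearson_oracle <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# brute-force three-branch second-order walk kernel on a neighbor list
transition_oracle <- function(neighbors, prev, cur, p, q) {
  nb <- neighbors[[cur]]
  w <- vapply(nb, function(v) {
    if (v == prev) 1 / p
    else if (v %in% neighbors[[prev]]) 1
    else 1 / q
  }, numeric(1))
  setNames(w / sum(w), nb)
}

# pair-counting Rand/ARI oracle, O(n^2), independent of the contingency
# table route
ari_oracle <- function(truth, pred) {
  n <- length(truth)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]; sp <- pred[i] == pred[j]
    if (st && sp) a <- a + 1
    else if (st && !sp) b <- b + 1
    else if (!st && sp) c_ <- c_ + 1
    else d <- d + 1
  }
  tot <- a + b + c_ + d
  exp_idx <- (a + b) * (a + c_) / tot
  max_idx <- ((a + b) + (a + c_)) / 2
  if (max_idx == exp_idx) return(if (a == exp_idx) 1 else 0)
  (a - exp_idx) / (max_idx - exp_idx)
}

# plug-in MI / entropy oracle with explicit double loops
nmi_oracle <- function(truth, pred) {
  n <- length(truth)
  tu <- unique(truth); pu <- unique(pred)
  mi <- 0
  for (u in tu) for (v in pu) {
    puv <- sum(truth == u & pred == v) / n
    if (puv > 0) {
      mi <- mi + puv * log(puv / ((sum(truth == u) / n) * (sum(pred == v) / n)))
    }
  }
  h <- function(lab) {
    p <- table(lab) / length(lab)
    -sum(p * log(p))
  }
  denom <- h(truth) + h(pred)
  if (denom == 0) 0 else 2 * mi / denom
}

param_list_of <- function(m) asNamespace("gcclust")$param_list(m)

# small fixed gene graph used by the walk-kernel acceptance checks:
# 6 nodes, mixed degrees, contains triangles and a pendant vertex
six_node_graph <- function() {
  edges <- data.frame(
    protein1 = c("A", "A", "B", "B", "C", "D", "E"),
    protein2 = c("B", "C", "C", "D", "D", "E", "F"),
    stringsAsFactors = FALSE
  )
  parse_edge_list(edges, LETTERS[1:6])
}

# the reference synthetic fixture of the test-suite
fixture_spec <- function(seed = 7) {
  synthetic_spec(n = 300, k = 3, d_g = 120, separation = 2,
                 dropout_rate = 0.3, seed = seed)
}
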