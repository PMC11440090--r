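#' k-means clustering with k-means++ seeding and restarts
#'
#' Minimizes the within-cluster sum of squares `||Z - U V||^2` over an
#' indicator partition U and center matrix V by Lloyd iterations, with
#' k-means++ initialization and `nstart` independent restarts; the
#' restart with the lowest inertia is returned. Empty clusters are
#' repaired by reassigning the point farthest from its center.
#'
#' @param z_c numeric matrix (n x d), rows are observations.
#' @param k number of clusters, `2 <= k <= n`.
#' @param seed RNG seed.
#' @param nstart number of restarts (default 20).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return a list of class `kmeans_result` with `labels` (1-based integer
#'   vector), `centers` (k x d), `inertia`, and `inertia_trace` (per-
#'   iteration inertia of the winning restart, non-increasing).
#' @export
kmeans_cluster <- function(z_c, k, seed = 1, nstart = 20, max_iter = 100) {
  z <- as.matrix(z_c)
  n <- nrow(z)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("kmeans_cluster: n (", n, ") < k (", k, ")")
  with_seed(derive_seed(seed, "kmeans"), {
    best <- NULL
    for (s in seq_len(nstart)) {
      centers <- kmeanspp_init(z, k)
      res <- lloyd(z, centers, max_iter)
      if (is.null(best) || res$inertia < best$inertia) best <- res
    }
    structure(best, class = "kmeans_result")
  })
}

kmeanspp_init <- function(z, k) {
  n <- nrow(z)
  centers <- matrix(0, k, ncol(z))
  first <- sample.int(n, 1)
  centers[1, ] <- z[first, ]
  d2 <- rowSums(sweep(z, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- z[pick, ]
    d2 <- pmin(d2, rowSums(sweep(z, 2, centers[j, ])^2))
  }
  centers
}

lloyd <- function(z, centers, max_iter) {
  n <- nrow(z); k <- nrow(centers)
  labels <- integer(n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist(z, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # repair empty clusters: move the globally farthest point there
    for (j in which(tabulate(new_labels, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(n), new_labels)])
      new_labels[far] <- j
      d2[far, ] <- Inf; d2[far, j] <- 0
    }
    inertia <- sum(vapply(seq_len(k), function(j) {
      idx <- new_labels == j
      sum(sweep(z[idx, , drop = FALSE], 2, centers[j, ])^2)
    }, numeric(1)))
    trace <- c(trace, inertia)
    if (it > 1 && all(new_labels == labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(z[labels == j, , drop = FALSE])
    }
  }
  # final inertia with converged centers
  d2 <- sq_dist(z, centers)
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, inertia = inertia,
       inertia_trace = c(trace, inertia))
}

#' @export
print.kmeans_result <- function(x, ...) {
  cat(sprintf("<kmeans_result> %d points, k=%d, inertia=%s\n",
              length(x$labels), nrow(x$centers), fmt_num(x$inertia)))
  invisible(x)
}

contingency <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("partition lengths differ (", length(truth), " vs ",
         length(pred), ")")
  }
  table(factor(truth), factor(pred))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed from their
#' contingency table of pair counts. Equals 1 iff the partitions are
#' identical up to relabeling; independent partitions score near 0.
#'
#' @param truth,pred label vectors of equal length (any atomic type).
#' @return scalar ARI in (-1, 1].
#' @export
ari <- function(truth, pred) {
  tab <- contingency(truth, pred)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' `NMI = 2 MI(U, V) / (H(U) + H(V))` with natural-log entropies
#' (arithmetic-mean normalization). When both partitions are constant the
#' ratio is 0/0 and is defined as 0.
#'
#' @param truth,pred label vectors of equal length.
#' @return scalar NMI in `[0, 1]`.
#' @export
nmi <- function(truth, pred) {
  tab <- contingency(truth, pred)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- h(pi_) + h(pj_)
  if (denom == 0) return(0)
  2 * mi / denom
}
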