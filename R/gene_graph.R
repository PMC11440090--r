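#' Parse a STRING-style edge list into a gene graph over the HVG set
#'
#' Reads a tab- or comma-delimited file with two gene-identifier columns
#' and an optional confidence column (accepted on either a 0-1 or a
#' 0-1000 scale, auto-detected by the column maximum). Rows below
#' `min_confidence`, self-edges, parallel edges and edges with an endpoint
#' outside `hvg_names` are dropped. Every HVG becomes a node even when it
#' ends up isolated, so downstream shapes never depend on interaction
#' coverage.
#'
#' @param path path to the edge-list file, or a data.frame with the same
#'   columns.
#' @param hvg_names character vector of gene names (node universe, in
#'   order).
#' @param min_confidence confidence threshold on the 0-1 scale
#'   (default 0.4); ignored when the file has no confidence column.
#' @param case_fold match gene identifiers case-insensitively
#'   (default FALSE).
#' @return a list of class `gene_graph` with `nodes` (= `hvg_names`),
#'   `edges` (two-column integer matrix of node ordinals, i < j),
#'   `confidence` (numeric per edge, NA when absent), `index` (name ->
#'   ordinal), and `neighbors` (adjacency list).
#' @export
parse_edge_list <- function(path, hvg_names, min_confidence = 0.4,
                            case_fold = FALSE) {
  if (is.character(path)) {
    if (!file.exists(path)) stop("edge list file not found: ", path)
    df <- tryCatch(
      data.table::fread(path, header = "auto", data.table = FALSE),
      error = function(e) stop("unreadable edge list '", path, "': ",
                               conditionMessage(e))
    )
  } else {
    df <- as.data.frame(path)
  }
  if (nrow(df) > 0 && ncol(df) < 2) {
    stop("edge list must have at least 2 columns")
  }
  hvg_names <- as.character(hvg_names)
  key <- if (case_fold) tolower(hvg_names) else hvg_names
  if (anyDuplicated(key)) stop("hvg_names must be unique (after case folding)")
  index <- stats::setNames(seq_along(hvg_names), key)

  edges <- matrix(integer(0), ncol = 2)
  conf_kept <- numeric(0)
  if (nrow(df) > 0) {
    a <- as.character(df[[1]]); b <- as.character(df[[2]])
    if (case_fold) { a <- tolower(a); b <- tolower(b) }
    conf <- if (ncol(df) >= 3 && is.numeric(df[[3]])) as.numeric(df[[3]])
            else rep(NA_real_, nrow(df))
    if (any(is.finite(conf)) && max(conf, na.rm = TRUE) > 1) {
      conf <- conf / 1000   # STRING combined_score convention
    }
    keep <- is.na(conf) | conf >= min_confidence
    ia <- index[a]; ib <- index[b]
    keep <- keep & !is.na(ia) & !is.na(ib) & ia != ib
    if (any(keep)) {
      ia <- ia[keep]; ib <- ib[keep]; conf <- conf[keep]
      lo <- pmin(ia, ib); hi <- pmax(ia, ib)
      dup <- duplicated(paste(lo, hi))
      edges <- cbind(unname(lo[!dup]), unname(hi[!dup]))
      conf_kept <- conf[!dup]
    }
  }
  if (nrow(edges) == 0) {
    warning("parse_edge_list: no edges matched the HVG set; ",
            "all genes will be isolated nodes")
  }
  neighbors <- vector("list", length(hvg_names))
  for (i in seq_along(neighbors)) neighbors[[i]] <- integer(0)
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      neighbors[[i]] <- c(neighbors[[i]], j)
      neighbors[[j]] <- c(neighbors[[j]], i)
    }
    neighbors <- lapply(neighbors, sort)
  }
  structure(
    list(nodes = hvg_names, edges = edges, confidence = conf_kept,
         index = stats::setNames(seq_along(hvg_names), hvg_names),
         neighbors = neighbors),
    class = "gene_graph"
  )
}

#' @export
print.gene_graph <- function(x, ...) {
  iso <- sum(vapply(x$neighbors, length, 1L) == 0)
  cat(sprintf("<gene_graph> %d nodes, %d edges, %d isolated\n",
              length(x$nodes), nrow(x$edges), iso))
  invisible(x)
}

#' Walk and skip-gram hyperparameters
#'
#' Defaults follow the reference node2vec setting: return parameter
#' `p = 1`, in-out parameter `q = 1` (the unbiased DeepWalk limit), walk
#' length `M = 80`, `r = 10` walks per node, window `w = 10`, embedding
#' dimension `d_e = 128`, 5 negative samples, 1 training epoch.
#'
#' @param p return parameter (> 0); larger values discourage revisiting
#'   the previous node.
#' @param q in-out parameter (> 0); larger values keep the walk local
#'   (BFS-like), smaller values push it outward (DFS-like).
#' @param walk_length nodes per walk, M (>= 2).
#' @param walks_per_node walks started from each node, r (>= 1).
#' @param window skip-gram context window, w (>= 1).
#' @param dim embedding dimension d_e (>= 2).
#' @param negative_samples negatives per positive pair (>= 1).
#' @param epochs passes over the walk corpus (>= 1).
#' @param lr skip-gram SGD learning rate (linearly decayed).
#' @param seed RNG seed for walks, negatives and initialization.
#' @return a list of class `walk_config`.
#' @export
walk_config <- function(p = 1, q = 1, walk_length = 80, walks_per_node = 10,
                        window = 10, dim = 128, negative_samples = 5,
                        epochs = 1, lr = 0.025, seed = 1) {
  stopifnot(p > 0, q > 0, walk_length >= 2, walks_per_node >= 1,
            window >= 1, dim >= 2, negative_samples >= 1, epochs >= 1,
            lr > 0)
  structure(list(p = p, q = q, walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 window = as.integer(window), dim = as.integer(dim),
                 negative_samples = as.integer(negative_samples),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Second-order transition distribution of the biased walk
#'
#' Given the previous node and the current node, the unnormalized weight
#' toward each neighbor `v` of the current node is `1/p` when `v` is the
#' previous node itself (shortest-path distance 0), `1` when `v` is also a
#' neighbor of the previous node (distance 1), and `1/q` otherwise
#' (distance 2). Weights are normalized to a probability vector.
#'
#' @param g a [parse_edge_list()] gene graph.
#' @param prev previous node (name or ordinal); pass `cur` itself for the
#'   first step, which falls back to the uniform distribution.
#' @param cur current node (name or ordinal); must not be isolated.
#' @param cfg a [walk_config()] supplying `p` and `q`.
#' @return named numeric vector of probabilities over the neighbors of
#'   `cur`, summing to 1.
#' @export
transition_distribution <- function(g, prev, cur, cfg) {
  cur_i <- if (is.character(cur)) g$index[[cur]] else as.integer(cur)
  prev_i <- if (is.character(prev)) g$index[[prev]] else as.integer(prev)
  nb <- g$neighbors[[cur_i]]
  if (length(nb) == 0) {
    stop("transition_distribution: node '", g$nodes[cur_i], "' is isolated")
  }
  if (prev_i == cur_i) {
    w <- rep(1, length(nb))                      # first step: uniform
  } else {
    prev_nb <- g$neighbors[[prev_i]]
    w <- ifelse(nb == prev_i, 1 / cfg$p,
                ifelse(nb %in% prev_nb, 1, 1 / cfg$q))
  }
  stats::setNames(w / sum(w), g$nodes[nb])
}

#' Generate biased second-order random walks
#'
#' Starts `walks_per_node` walks of length `walk_length` from every
#' non-isolated node; the first step is uniform over neighbors, later
#' steps sample from [transition_distribution()]. Isolated nodes yield no
#' walks. Fully reproducible from `cfg$seed`.
#'
#' @param g a [parse_edge_list()] gene graph.
#' @param cfg a [walk_config()].
#' @return list of integer vectors of node ordinals (use `g$nodes` to map
#'   back to names).
#' @export
generate_walks <- function(g, cfg) {
  deg <- vapply(g$neighbors, length, 1L)
  sources <- which(deg > 0)
  if (length(sources) == 0) return(list())
  with_seed(derive_seed(cfg$seed, "walks"), {
    walks <- vector("list", length(sources) * cfg$walks_per_node)
    idx <- 0L
    for (rep_i in seq_len(cfg$walks_per_node)) {
      for (s in sources) {
        walk <- integer(cfg$walk_length)
        walk[1] <- s
        nb <- g$neighbors[[s]]
        walk[2] <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1)]
        if (cfg$walk_length > 2) {
          for (t in 3:cfg$walk_length) {
            cur <- walk[t - 1]; prev <- walk[t - 2]
            nb <- g$neighbors[[cur]]
            if (length(nb) == 1L) { walk[t] <- nb; next }
            prev_nb <- g$neighbors[[prev]]
            w <- ifelse(nb == prev, 1 / cfg$p,
                        ifelse(nb %in% prev_nb, 1, 1 / cfg$q))
            walk[t] <- nb[sample.int(length(nb), 1, prob = w)]
          }
        }
        idx <- idx + 1L
        walks[[idx]] <- walk
      }
    }
    walks
  })
}
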