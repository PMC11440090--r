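#' Pipeline configuration
#'
#' One nested record resolving every knob of the four-stage pipeline with
#' defaults, so a run needs nothing but input paths (or in-memory
#' objects). Unknown keys in `overrides` are rejected.
#'
#' @param seed master seed; every stochastic stage derives its own child
#'   seed from it.
#' @param overrides named list of section overrides, e.g.
#'   `list(train = list(lambda = 0), walk = list(dim = 32))`.
#' @return nested list of class `pipeline_config` with sections
#'   `preprocess`, `cell_graph`, `walk`, `model`, `train`, `ablation`.
#' @export
pipeline_config <- function(seed = 1, overrides = list()) {
  cfg <- list(
    seed = as.integer(seed),
    preprocess = list(n_top = 500, upper_mult = 3, lower_mult = 1,
                      qc_covariate = "total_counts"),
    cell_graph = list(k = 15),
    walk = list(p = 1, q = 1, walk_length = 80, walks_per_node = 10,
                window = 10, dim = 128, negative_samples = 5, epochs = 1,
                min_confidence = 0.4),
    model = list(hidden = 512, d_m = 256),
    train = list(k = NULL, total_epochs = 500, lr = 1e-5, lambda = 100,
                 warmup_epochs = 100, p_update_interval = 1),
    ablation = list(gene_branch = TRUE, clustering_loss = TRUE)
  )
  cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(base, overrides) {
  for (sec in names(overrides)) {
    if (!sec %in% names(base)) stop("unknown config section: ", sec)
    if (is.list(base[[sec]])) {
      for (key in names(overrides[[sec]])) {
        if (!key %in% names(base[[sec]])) {
          stop("unknown config key: ", sec, ".", key)
        }
        base[[sec]][[key]] <- overrides[[sec]][[key]]
      }
    } else {
      base[[sec]] <- overrides[[sec]]
    }
  }
  base
}

#' Desk-scale pipeline profile
#'
#' Shrinks the walk corpus, architecture and training schedule to sizes
#' appropriate for few-hundred-cell fixtures: embedding dim 32, walks of
#' length 30 (5 per node, window 5), hidden width 64, bottleneck 32,
#' learning rate 1e-3 with 50 warm-up + 150 joint epochs.
#'
#' @inheritParams pipeline_config
#' @return a `pipeline_config`.
#' @export
desk_pipeline_config <- function(seed = 1, overrides = list()) {
  base <- list(
    walk = list(walk_length = 30, walks_per_node = 5, window = 5, dim = 32),
    model = list(hidden = 64, d_m = 32),
    train = list(total_epochs = 200, lr = 1e-3, warmup_epochs = 50)
  )
  cfg <- pipeline_config(seed, base)
  structure(merge_config(unclass(cfg), overrides), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Preprocess, build the cell graph, embed genes on the interaction
#' graph, fit the cooperative model, cluster the refined embedding with
#' k-means, and (when labels are available) evaluate ARI/NMI. Every
#' intermediate artifact, the training history, the predicted labels, a
#' metrics file and a manifest (config, config hash, seed, variant) are
#' written into `out_dir`.
#'
#' @param raw a [raw_expression()], or a path readable by
#'   [read_expression()].
#' @param gene_edges data.frame of interaction edges, or a path readable
#'   by [parse_edge_list()].
#' @param cfg a [pipeline_config()].
#' @param out_dir run directory (created); `NULL` skips all file output.
#' @param k_clusters number of clusters; defaults to the number of
#'   distinct labels when labels are present.
#' @param verbose emit one structured log line per stage.
#' @return list with `processed`, `adjacency`, `embeddings`, `fitres`,
#'   `partition` (predicted labels), `metrics` (ARI/NMI on the 0-1
#'   scale, or NULL), `out_dir`.
#' @export
run_pipeline <- function(raw, gene_edges, cfg = pipeline_config(),
                         out_dir = NULL, k_clusters = NULL,
                         verbose = FALSE) {
  t0 <- Sys.time()
  if (is.character(raw)) raw <- read_expression(raw)
  stopifnot(inherits(raw, "raw_expression"))

  pp <- cfg$preprocess
  x <- preprocess(raw, n_top = pp$n_top, upper_mult = pp$upper_mult,
                  lower_mult = pp$lower_mult,
                  qc_covariate = pp$qc_covariate)
  log_stage("preprocess", sprintf("n=%d d_g=%d seed=%d", x$n, x$d_g,
                                  cfg$seed), verbose = verbose)

  adj <- build_cell_graph(x, k = cfg$cell_graph$k)
  log_stage("cell_graph", sprintf("k=%d edges=%d", adj$k, sum(adj$A_c) / 2),
            verbose = verbose)

  wc <- walk_config(p = cfg$walk$p, q = cfg$walk$q,
                    walk_length = cfg$walk$walk_length,
                    walks_per_node = cfg$walk$walks_per_node,
                    window = cfg$walk$window, dim = cfg$walk$dim,
                    negative_samples = cfg$walk$negative_samples,
                    epochs = cfg$walk$epochs, seed = cfg$seed)
  g <- parse_edge_list(gene_edges, x$hvg_names,
                       min_confidence = cfg$walk$min_confidence)
  variant <- list(gene_branch = isTRUE(cfg$ablation$gene_branch),
                  clustering_loss = isTRUE(cfg$ablation$clustering_loss))
  if (variant$gene_branch) {
    emb <- embed_genes(g, wc)
  } else {
    # ablated gene branch: frozen seeded random embedding of the same shape
    emb <- structure(list(
      X_g = with_seed(derive_seed(cfg$seed, "ablate"),
                      matrix(stats::rnorm(x$d_g * wc$dim, 0, 0.01),
                             ncol = wc$dim,
                             dimnames = list(x$hvg_names, NULL))),
      matched_mask = rep(FALSE, x$d_g), hvg_names = x$hvg_names),
      class = "gene_embeddings")
  }
  log_stage("gene_embedding",
            sprintf("d_e=%d matched=%d/%d", wc$dim, sum(emb$matched_mask),
                    x$d_g), verbose = verbose)

  if (is.null(k_clusters)) {
    if (is.null(x$labels)) stop("k_clusters is required when no labels are present")
    k_clusters <- length(unique(x$labels))
  }
  tc <- train_config(
    k = k_clusters, total_epochs = cfg$train$total_epochs, lr = cfg$train$lr,
    lambda = if (variant$clustering_loss) cfg$train$lambda else 0,
    warmup_epochs = cfg$train$warmup_epochs,
    p_update_interval = cfg$train$p_update_interval, seed = cfg$seed)
  model <- coop_model(d_g = x$d_g, d_e = wc$dim, hidden = cfg$model$hidden,
                      d_m = cfg$model$d_m, seed = cfg$seed)
  fitres <- fit(model, x, adj, emb, tc,
                gene_branch = variant$gene_branch, labels = x$labels)
  log_stage("training",
            sprintf("epochs=%d final L=%s", tc$total_epochs,
                    fmt_num(utils::tail(fitres$history$L_total, 1))),
            verbose = verbose)

  km <- kmeans_cluster(fitres$Z_c, k_clusters, seed = cfg$seed)
  metrics <- NULL
  if (!is.null(x$labels)) {
    metrics <- list(ari = ari(x$labels, km$labels),
                    nmi = nmi(x$labels, km$labels))
    log_stage("evaluate", sprintf("ARI=%.1f%% NMI=%.1f%%",
                                  100 * metrics$ari, 100 * metrics$nmi),
              verbose = verbose)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression(file.path(out_dir, "processed.tsv"), x)
    write_adjacency(file.path(out_dir, "cell_graph.mtx"), adj)
    write_embeddings(file.path(out_dir, "gene_embeddings.tsv"), emb)
    data.table::fwrite(fitres$history, file.path(out_dir, "history.tsv"),
                       sep = "\t", quote = FALSE)
    write_labels(file.path(out_dir, "predicted_labels.tsv"), km$labels,
                 x$cell_ids)
    if (!is.null(metrics)) {
      jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    manifest <- list(
      seed = cfg$seed,
      config = unclass(cfg),
      config_hash = rlang::hash(unclass(cfg)),
      variant = variant,
      k_clusters = k_clusters,
      n = x$n, d_g = x$d_g,
      events = fitres$events,
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(processed = x, adjacency = adj, embeddings = emb, fitres = fitres,
       partition = km$labels, metrics = metrics, out_dir = out_dir)
}

#' Run the four-variant ablation grid
#'
#' Crosses the gene branch (on / frozen-random) with the clustering loss
#' (on / lambda = 0) and runs the full pipeline for each of the four
#' variants, reusing one seed. Returns the 2x2 ARI/NMI table; each
#' variant's manifest records its identity.
#'
#' @inheritParams run_pipeline
#' @return data.frame with columns `gene_branch`, `clustering_loss`,
#'   `ari`, `nmi` (percent scale).
#' @export
run_ablation <- function(raw, gene_edges, cfg = pipeline_config(),
                         out_dir = NULL, k_clusters = NULL,
                         verbose = FALSE) {
  grid <- expand.grid(gene_branch = c(FALSE, TRUE),
                      clustering_loss = c(FALSE, TRUE))
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    vcfg <- structure(merge_config(unclass(cfg), list(
      ablation = list(gene_branch = grid$gene_branch[i],
                      clustering_loss = grid$clustering_loss[i])
    )), class = "pipeline_config")
    vdir <- if (is.null(out_dir)) NULL else
      file.path(out_dir, sprintf("EG_%s_Lc_%s",
                                 ifelse(grid$gene_branch[i], "on", "off"),
                                 ifelse(grid$clustering_loss[i], "on", "off")))
    r <- run_pipeline(raw, gene_edges, vcfg, out_dir = vdir,
                      k_clusters = k_clusters, verbose = verbose)
    res[[i]] <- data.frame(
      gene_branch = grid$gene_branch[i],
      clustering_loss = grid$clustering_loss[i],
      ari = if (is.null(r$metrics)) NA_real_ else 100 * r$metrics$ari,
      nmi = if (is.null(r$metrics)) NA_real_ else 100 * r$metrics$nmi
    )
  }
  out <- do.call(rbind, res)
  if (!is.null(out_dir)) {
    data.table::fwrite(out, file.path(out_dir, "ablation.tsv"), sep = "\t",
                       quote = FALSE)
  }
  out
}
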