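#' Fit the full ICA-network model to multi-batch scRNA-seq data
#'
#' End-to-end pipeline: log-normalization, shared variable-gene selection,
#' optional random-matrix denoising, per-batch ICA into expression
#' programs, cross-batch program grouping into basal programs (skipped for
#' a single batch, whose components pass through directly), ICA-statistic
#' weighting of the interaction network per basal program, walktrap module
#' detection, per-cell module-activity scoring, SNN + Louvain clustering,
#' and (when cell-type labels are present) integration evaluation. Cell
#' type labels are never consulted before the evaluation step.
#'
#' @param batches a single [expression_matrix()] or a list of them (counts
#'   or log-normalized), one per batch.
#' @param ppi interaction network: a [load_ppi()] object, or a path /
#'   data.frame in the STRING links dialect.
#' @param top_k variable genes per batch before intersection (default 5000).
#' @param denoise apply [rmt_denoise()] per batch (default FALSE).
#' @param n_components `"auto"` (RMT estimate per batch) or an integer.
#' @param ica_method `"jade"` or `"fastica_icasso"`.
#' @param activation_sd program-activation threshold in SDs (default 2.5).
#' @param edge_sd edge-weight endpoint threshold in SDs (default 2.5).
#' @param walk_lengths walktrap random-walk lengths (default `2:5`).
#' @param min_module_size minimum module size (default 4).
#' @param auc_max_rank AUCell integration depth (default 5% of genes).
#' @param score_threshold STRING combined-score filter when `ppi` is a path
#'   or data.frame (default 600).
#' @param k_neighbors,prune,resolution SNN/Louvain parameters
#'   (defaults 20, 1/15, 1).
#' @param evaluate compute the [integration_report()] when cell-type labels
#'   are available (default TRUE).
#' @param seed root seed; stage seeds are derived as
#'   `seed + <fixed stage offset>` (offsets 11 ica, 23 aucell, 31 louvain).
#' @return object of class `"icanet"`: list with `programs` (per batch),
#'   `basal` (`BasalProgramSet` or `NULL` for one batch), `networks`
#'   (weighted networks per basal program), `modules` (`ModuleSet`),
#'   `activity` (`ModuleActivityMatrix`, binarized), `clusters`
#'   (`ClusterAssignment`), `evaluation` (`IntegrationReport` or `NULL`),
#'   `variable_genes`, `config`, `call`.
#' @seealso [find_celltype_modules()] for marker modules on the fitted
#'   object's activity and clusters.
#' @export
icanet <- function(batches, ppi, top_k = 5000, denoise = FALSE,
                   n_components = "auto",
                   ica_method = c("jade", "fastica_icasso"),
                   activation_sd = 2.5, edge_sd = 2.5, walk_lengths = 2:5,
                   min_module_size = 4, auc_max_rank = NULL,
                   score_threshold = 600, k_neighbors = 20, prune = 1 / 15,
                   resolution = 1.0, evaluate = TRUE, seed = 0) {
  cl <- match.call()
  ica_method <- match.arg(ica_method)
  if (inherits(batches, "ExpressionMatrix")) batches <- list(batches)
  stopifnot(length(batches) >= 1,
            all(vapply(batches, inherits, TRUE, "ExpressionMatrix")))
  norm <- lapply(batches, function(b) if (b$normalized) b else lognormalize(b))
  genes <- select_variable_genes(norm, top_k = top_k)
  sub <- lapply(norm, function(b) {
    out <- b
    out$values <- b$values[genes, , drop = FALSE]
    out$gene_ids <- genes
    out
  })
  if (denoise) sub <- lapply(sub, rmt_denoise)
  programs <- lapply(sub, function(b) {
    K <- if (identical(n_components, "auto")) estimate_component_count(b)
    else as.integer(n_components)
    run_ica(b, K = K, method = ica_method, seed = seed + 11L)
  })
  basal <- NULL
  if (length(programs) > 1) {
    basal <- group_programs(programs, sd_threshold = activation_sd)
    basal_mat <- basal$medoids
  } else {
    basal_mat <- programs[[1]]$source
  }
  if (!inherits(ppi, "PPINetwork"))
    ppi <- load_ppi(ppi, score_threshold = score_threshold,
                    gene_universe = genes)
  networks <- lapply(seq_len(ncol(basal_mat)), function(k)
    suppressWarnings(
      weight_network(ppi, basal_mat[, k], weight_threshold_sd = edge_sd,
                     program_id = colnames(basal_mat)[k])))
  active <- vapply(networks, function(n) any(n$edges$weight > 0), TRUE)
  if (!any(active))
    stop("stage network_weighting: no basal program activates any edge")
  modules <- detect_modules(networks[active], walk_lengths = walk_lengths,
                            min_size = min_module_size)
  if (length(modules$modules) == 0)
    stop("stage module_detection: no module found")
  merged <- merge_batches(norm)            # full shared gene universe
  activity <- aucell_score(merged, modules, auc_max_rank = auc_max_rank,
                           seed = seed + 23L)
  activity <- binarize_activity(activity)
  snn <- build_snn(activity, k_neighbors = k_neighbors, prune = prune)
  clusters <- louvain_cluster(snn, resolution = resolution,
                              seed = seed + 31L)
  evaluation <- NULL
  if (evaluate && !is.null(merged$cell_type))
    evaluation <- integration_report(clusters$labels, merged$cell_type,
                                     merged$batch, embedding = t(activity$auc))
  structure(
    list(programs = programs, basal = basal, networks = networks,
         modules = modules, activity = activity, clusters = clusters,
         evaluation = evaluation, variable_genes = genes,
         batch = merged$batch, cell_type = merged$cell_type,
         config = list(top_k = top_k, denoise = denoise,
                       n_components = n_components, ica_method = ica_method,
                       activation_sd = activation_sd, edge_sd = edge_sd,
                       walk_lengths = walk_lengths,
                       min_module_size = min_module_size,
                       auc_max_rank = activity$auc_max_rank,
                       score_threshold = score_threshold,
                       k_neighbors = k_neighbors, prune = prune,
                       resolution = resolution, seed = seed),
         call = cl),
    class = "icanet")
}

#' @export
print.icanet <- function(x, ...) {
  cat("ICA co-expression network fit\n")
  cat(sprintf("  %d batch(es), %d variable genes, %d cells\n",
              length(x$programs), length(x$variable_genes), length(x$batch)))
  ks <- vapply(x$programs, `[[`, 1L, "K")
  cat(sprintf("  components per batch: %s (%s)\n",
              paste(ks, collapse = ", "), x$config$ica_method))
  if (!is.null(x$basal))
    cat(sprintf("  basal programs (k_star): %d\n", x$basal$k_star))
  cat(sprintf("  modules: %d; clusters: %d\n", length(x$modules$modules),
              length(unique(x$clusters$labels))))
  if (!is.null(x$evaluation))
    cat(sprintf("  ARI cell type %.3f, ARI batch %.3f, F1_ARI %.3f\n",
                x$evaluation$ari_cell_type, x$evaluation$ari_batch,
                x$evaluation$f1_ari))
  invisible(x)
}

#' @export
summary.icanet <- function(object, ...) {
  print(object)
  sz <- vapply(object$modules$modules, length, 1L)
  cat("\nModule sizes:\n")
  print(summary(sz))
  cat("\nCells per cluster:\n")
  print(table(object$clusters$labels))
  if (!is.null(object$cell_type)) {
    cat("\nCluster x cell type:\n")
    print(table(cluster = object$clusters$labels, type = object$cell_type))
  }
  if (!is.null(object$evaluation)) {
    cat("\n")
    print(object$evaluation)
  }
  invisible(object)
}

#' Plot module activity by cluster
#'
#' Image of the module x cell AUC matrix with cells ordered by cluster,
#' the package's quick visual check that clusters correspond to distinct
#' activity profiles.
#'
#' @param x an [icanet()] fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.icanet <- function(x, ...) {
  ord <- order(x$clusters$labels)
  a <- x$activity$auc[, ord, drop = FALSE]
  graphics::image(seq_len(ncol(a)), seq_len(nrow(a)), t(a),
                  xlab = "cells (ordered by cluster)", ylab = "module",
                  main = "Module activity", ...)
  br <- cumsum(table(x$clusters$labels[ord]))
  graphics::abline(v = br[-length(br)] + 0.5, col = "white", lwd = 2)
  invisible(x)
}
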