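#' Build a shared-nearest-neighbor cell graph
#'
#' k-nearest neighbors in Euclidean module-activity space (neighbor sets
#' include the cell itself); candidate edges are all kNN pairs and each edge
#' is weighted by the Jaccard overlap of the two neighbor sets. Edges with
#' weight below `prune` are removed.
#'
#' @param mam a [aucell_score()] result, or a cells x features matrix.
#' @param k_neighbors neighborhood size (default 20).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @return an igraph graph on the cells with `weight` edge attributes.
#' @export
build_snn <- function(mam, k_neighbors = 20, prune = 1 / 15) {
  feat <- if (inherits(mam, "ModuleActivityMatrix")) t(mam$auc) else
    as.matrix(mam)
  n <- nrow(feat)
  if (k_neighbors >= n)
    stop("k_neighbors must be smaller than the number of cells")
  d <- as.matrix(stats::dist(feat))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors + 1)]))
  # nn[i, ] includes i itself (distance 0 ranks first, ties harmless)
  nnsets <- lapply(seq_len(n), function(i) nn[i, ])
  pairs <- unique(do.call(rbind, lapply(seq_len(n), function(i) {
    js <- setdiff(nn[i, ], i)
    cbind(pmin(i, js), pmax(i, js))
  })))
  w <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- nnsets[[pairs[r, 1]]]; b <- nnsets[[pairs[r, 2]]]
    length(intersect(a, b)) / length(union(a, b))
  }, 1)
  keep <- w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[keep, 1], to = pairs[keep, 2], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  ids <- if (!is.null(rownames(feat))) rownames(feat) else as.character(seq_len(n))
  igraph::V(g)$cell_id <- ids
  g
}

#' Louvain clustering of the SNN graph
#'
#' Multi-level modularity optimization (Louvain with refinement) on the
#' weighted SNN graph. The assignment is deterministic given the seed.
#'
#' @param snn graph from [build_snn()].
#' @param resolution modularity resolution (default 1).
#' @param seed RNG seed (default 0).
#' @return object of class `"ClusterAssignment"`: list with `labels`
#'   (integer cluster ids, contiguous from 0, named by cell id), `snn`,
#'   `resolution`, `k_neighbors` (if recorded).
#' @export
louvain_cluster <- function(snn, resolution = 1.0, seed = 0) {
  if (igraph::vcount(snn) == 0) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(snn, weights = igraph::E(snn)$weight,
                                resolution = resolution)
  lab <- igraph::membership(cl)
  lab <- as.integer(factor(lab, levels = unique(lab))) - 1L
  names(lab) <- igraph::V(snn)$cell_id
  structure(list(labels = lab, snn = snn, resolution = resolution),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d cells in %d clusters (resolution %g)\n",
              length(x$labels), length(unique(x$labels)), x$resolution))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Cell-type-specific activated modules
#'
#' Screens every (module, cluster) pair in three steps: (1) the module's
#' continuous AUC as a one-vs-rest classifier of the cluster must reach
#' ROC AUC > `auc_cut`; (2) the Spearman correlation between the binarized
#' module vector and the cluster indicator must reach `rho_cut`; (3) a
#' permutation P-value for that correlation (label shuffles), BH-adjusted
#' across all tested pairs, must fall below `alpha`.
#'
#' @param mam a binarized [aucell_score()] result (see
#'   [binarize_activity()]).
#' @param labels per-cell cluster labels (vector or `ClusterAssignment`).
#' @param auc_cut ROC AUC threshold (default 0.75, exclusive).
#' @param rho_cut Spearman threshold (default 0.3; pairs below are dropped).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return data.frame with columns `module`, `cluster`, `roc_auc`, `rho`,
#'   `p`, `p_adj`, one row per surviving pair; the full screen (before the
#'   significance filter) is attached as attribute `"tested"`.
#' @export
find_celltype_modules <- function(mam, labels, auc_cut = 0.75, rho_cut = 0.3,
                                  alpha = 0.05, n_perm = 1000, seed = 0) {
  stopifnot(inherits(mam, "ModuleActivityMatrix"))
  if (is.null(mam$binary)) stop("run binarize_activity() first")
  if (inherits(labels, "ClusterAssignment")) labels <- labels$labels
  labels <- as.character(labels)
  n <- ncol(mam$auc)
  stopifnot(length(labels) == n)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  rows <- list()
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  for (cl in clusters) {
    ind <- as.numeric(labels == cl)
    if (sum(ind) < 3) {
      warning("cluster '", cl, "' has fewer than 3 cells; skipped")
      next
    }
    for (m in rownames(mam$auc)) {
      a <- .roc_auc(mam$auc[m, ], ind)
      if (is.na(a) || a <= auc_cut) next
      b <- mam$binary[m, ]
      rho <- suppressWarnings(stats::cor(b, ind, method = "spearman"))
      if (is.na(rho) || rho < rho_cut) next
      rb <- rank(b); ri <- rank(ind)
      rperm <- vapply(seq_len(n_perm), function(k)
        stats::cor(rb, ri[perms[, k]]), 1)
      p <- (1 + sum(rperm >= rho)) / (n_perm + 1)
      rows[[length(rows) + 1L]] <-
        data.frame(module = m, cluster = cl, roc_auc = a, rho = rho, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  tested <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(), cluster = character(),
               roc_auc = numeric(), rho = numeric(), p = numeric())
  tested$p_adj <- stats::p.adjust(tested$p, method = "BH")
  out <- tested[tested$p_adj < alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  out
}

# Mann-Whitney identity: AUC = (mean rank of positives - (n1+1)/2) / n0
.roc_auc <- function(score, positive) {
  n1 <- sum(positive == 1); n0 <- sum(positive == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive == 1]) / n1 - (n1 + 1) / 2) / n0
}
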