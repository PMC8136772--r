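#' Module recovery score by edge-weight permutation
#'
#' Measures whether a module's internal edge-weight density on a validation
#' network could arise by chance: zero weights are first replaced by the
#' smallest positive weight observed on the network (0.001 when there is
#' none), the module's modularity is its mean induced edge weight, and the
#' weight multiset is shuffled over the fixed topology `n_perm` times. The
#' score is the fraction of permutations whose modularity exceeds the
#' observed one; low scores mean the module is reproducibly heavy.
#'
#' @param module character vector of gene ids; must induce at least one
#'   edge in the network.
#' @param validation_network a [weight_network()] result (when a pipeline
#'   provides several weighted networks, validation conventionally uses the
#'   first program's).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param denominator divisor of the exceedance count; defaults to
#'   `n_perm`, giving an empirical probability.
#' @return object of class `"RecoveryResult"`: list with `module`,
#'   `modularity_inferred`, `modularity_perm`, `mrs`, `n_perm`.
#' @export
module_recovery_score <- function(module, validation_network, n_perm = 1000,
                                  seed = 0, denominator = n_perm) {
  stopifnot(inherits(validation_network, "WeightedNetwork"))
  ed <- validation_network$edges
  w <- ed$weight
  if (any(w > 0)) w[w == 0] <- min(w[w > 0]) else w[] <- 0.001
  idx <- which(ed$from %in% module & ed$to %in% module)
  if (length(idx) == 0) stop("module induces no edge in the network")
  observed <- mean(w[idx])
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(k) mean(sample(w)[seq_along(idx)]),
                 1)
  # sampling idx-many weights without replacement == reading the shuffled
  # vector at the module's edge positions
  mrs <- sum(perm > observed) / denominator
  structure(list(module = module, modularity_inferred = observed,
                 modularity_perm = perm, mrs = mrs, n_perm = n_perm),
            class = "RecoveryResult")
}

#' @export
print.RecoveryResult <- function(x, ...) {
  cat(sprintf(
    "RecoveryResult: %d genes, modularity %.4f, MRS %.4f (%d permutations)\n",
    length(x$module), x$modularity_inferred, x$mrs, x$n_perm))
  invisible(x)
}

#' Smooth a binary cell-label signal over the cell kNN graph
#'
#' Solves the Laplacian-regularized reconstruction
#' `y = argmin_z ||x - z||^2 + beta * z' L z`, whose closed form is
#' `y = (I + beta * L)^{-1} x`, by a sparse linear solve (never an explicit
#' inverse). `L` is the unnormalized Laplacian of the union-symmetrized kNN
#' graph built on `cell_graph_features`. Because Laplacian rows sum to
#' zero, `sum(y) = sum(x)`.
#'
#' @param x per-cell numeric vector (typically a 0/1 cell-type indicator).
#' @param cell_graph_features cells x features matrix the kNN graph is
#'   built on, or a precomputed Laplacian from [cell_graph_laplacian()].
#' @param beta regularization strength, >= 0 (default 0.8).
#' @param k neighbors (default 30).
#' @return numeric vector `y`, same length as `x`.
#' @export
smooth_labels <- function(x, cell_graph_features, beta = 0.8, k = 30) {
  stopifnot(beta >= 0)
  L <- if (methods::is(cell_graph_features, "Matrix") &&
           isTRUE(attr(cell_graph_features, "laplacian")))
    cell_graph_features else cell_graph_laplacian(cell_graph_features, k)
  n <- nrow(L)
  stopifnot(length(x) == n)
  A <- Matrix::Diagonal(n) + beta * L
  as.numeric(Matrix::solve(A, x))
}

#' Unnormalized Laplacian of the union-symmetrized kNN cell graph
#'
#' @param features cells x features matrix.
#' @param k neighbors (default 30); must be below the cell count.
#' @return sparse symmetric Laplacian `D - A` with attribute
#'   `laplacian = TRUE`.
#' @export
cell_graph_laplacian <- function(features, k = 30) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n <= k) stop("need more cells than k")
  d <- as.matrix(stats::dist(features))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(nn))
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  A <- (A + Matrix::t(A) > 0) * 1          # union symmetrization
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  attr(L, "laplacian") <- TRUE
  L
}

#' Cross-annotation label association by graph-signal smoothing
#'
#' Smooths every cell type's 0/1 indicator from two annotation sets over
#' the shared cell kNN graph ([smooth_labels()]), correlates every (a, b)
#' pair of smoothed signals, rescales to `cor' = (1 + cor) / 2`, and calls
#' a pair significant when `cor' > cor_prime_cut` (strictly) and the
#' BH-adjusted correlation-test P-value is below `fdr_cut`.
#'
#' @param annotations_a,annotations_b per-cell labels over the same cells.
#' @param cell_graph_features cells x features matrix (or precomputed
#'   Laplacian).
#' @param beta smoothing strength (default 0.8).
#' @param k kNN neighbors (default 30).
#' @param cor_prime_cut threshold on `cor'` (default 0.6, i.e. cor > 0.2).
#' @param fdr_cut BH FDR threshold (default 0.05).
#' @return data.frame `type_a`, `type_b`, `cor`, `cor_prime`, `p`, `p_adj`,
#'   `significant`.
#' @export
label_association <- function(annotations_a, annotations_b,
                              cell_graph_features, beta = 0.8, k = 30,
                              cor_prime_cut = 0.6, fdr_cut = 0.05) {
  annotations_a <- as.character(annotations_a)
  annotations_b <- as.character(annotations_b)
  n <- length(annotations_a)
  stopifnot(length(annotations_b) == n)
  L <- if (methods::is(cell_graph_features, "Matrix") &&
           isTRUE(attr(cell_graph_features, "laplacian")))
    cell_graph_features else cell_graph_laplacian(cell_graph_features, k)
  smooth_set <- function(ann) {
    types <- unique(ann)
    keep <- vapply(types, function(t) sum(ann == t) > 0, TRUE)
    if (any(!keep)) warning("cell types with zero members skipped: ",
                            paste(types[!keep], collapse = ", "))
    types <- types[keep]
    ys <- vapply(types, function(t)
      smooth_labels(as.numeric(ann == t), L, beta = beta), numeric(n))
    colnames(ys) <- types
    ys
  }
  ya <- smooth_set(annotations_a)
  yb <- smooth_set(annotations_b)
  rows <- list()
  for (a in colnames(ya)) for (b in colnames(yb)) {
    ct <- stats::cor.test(ya[, a], yb[, b])
    rows[[length(rows) + 1L]] <- data.frame(
      type_a = a, type_b = b, cor = unname(ct$estimate),
      cor_prime = (1 + unname(ct$estimate)) / 2, p = ct$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$cor_prime > cor_prime_cut & out$p_adj < fdr_cut
  rownames(out) <- NULL
  out
}
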