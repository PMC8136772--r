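#' Score module activity per cell (recovery-curve AUC)
#'
#' For every cell, all genes are ranked by decreasing expression (ties
#' broken by a seeded random gene permutation, so that gene file order
#' cannot bias the ranking). The recovery curve `R(i)` counts module genes
#' among the top `i` ranks for `i = 1 .. auc_max_rank`; the module's score
#' in that cell is `sum(R)` divided by its maximum attainable value (the
#' module occupying the very top ranks), giving a value in `[0, 1]`.
#'
#' @param em an [expression_matrix()] (any normalization state; the scoring
#'   is rank-based and therefore invariant to monotone transforms per cell).
#' @param modules a [detect_modules()] `ModuleSet`, or a named list of gene
#'   id vectors.
#' @param auc_max_rank integration depth; default `ceiling(0.05 * n_genes)`.
#' @param seed seed for the tie-breaking permutation.
#' @return object of class `"ModuleActivityMatrix"`: list with `auc`
#'   (modules x cells), `binary` (`NULL` until [binarize_activity()]),
#'   `auc_max_rank`, `thresholds`, `seed`, plus the cells' `batch` and
#'   `cell_type` carried over from `em`.
#' @export
aucell_score <- function(em, modules, auc_max_rank = NULL, seed = 0) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (inherits(modules, "ModuleSet")) modules <- modules$modules
  stopifnot(is.list(modules), length(modules) > 0)
  if (is.null(names(modules)))
    names(modules) <- paste0("module_", seq_along(modules))
  p <- nrow(em$values)
  if (is.null(auc_max_rank)) auc_max_rank <- ceiling(0.05 * p)
  if (auc_max_rank < 1 || auc_max_rank > p)
    stop("auc_max_rank must lie in [1, n_genes]")
  set.seed(seed)
  perm <- sample.int(p)                    # tie-break order, one per run
  vperm <- em$values[perm, , drop = FALSE]
  ranks <- apply(vperm, 2, function(x) rank(-x, ties.method = "first"))
  ranks <- ranks[order(perm), , drop = FALSE]   # back to original gene order
  rownames(ranks) <- em$gene_ids
  L <- auc_max_rank
  auc <- matrix(0, length(modules), ncol(em$values),
                dimnames = list(names(modules), em$cell_ids))
  for (i in seq_along(modules)) {
    genes <- intersect(modules[[i]], em$gene_ids)
    if (length(genes) == 0) {
      warning("module '", names(modules)[i], "' has no gene in the matrix; ",
              "scored 0")
      next
    }
    rm_ <- ranks[genes, , drop = FALSE]
    contrib <- pmax(L - rm_ + 1, 0)          # per gene: L - rank + 1 if <= L
    m_eff <- min(length(genes), L)
    max_sum <- m_eff * (m_eff + 1) / 2 + (L - m_eff) * m_eff
    auc[i, ] <- colSums(contrib) / max_sum
  }
  structure(list(auc = auc, binary = NULL, auc_max_rank = auc_max_rank,
                 thresholds = NULL, seed = seed,
                 batch = em$batch, cell_type = em$cell_type),
            class = "ModuleActivityMatrix")
}

#' Binarize module activity
#'
#' Fits a two-component Gaussian mixture to every module's AUC distribution
#' and thresholds where the posterior responsibility of the high-mean
#' component crosses 0.5. When the fit is degenerate (a component weight
#' below 0.05, or means closer than half the pooled SD, or the fit fails)
#' the threshold falls back to `mean + 1 SD`. Constant rows binarize to all
#' zeros with a warning.
#'
#' @param mam a [aucell_score()] result.
#' @return the same object with `binary` (0/1 matrix, `binary >= threshold`)
#'   and per-module `thresholds` filled in.
#' @export
binarize_activity <- function(mam) {
  stopifnot(inherits(mam, "ModuleActivityMatrix"))
  auc <- mam$auc
  thr <- stats::setNames(rep(NA_real_, nrow(auc)), rownames(auc))
  bin <- auc * 0
  for (i in seq_len(nrow(auc))) {
    x <- auc[i, ]
    if (stats::sd(x) == 0) {
      warning("constant activity for '", rownames(auc)[i],
              "'; binarized to all zeros")
      thr[i] <- Inf
      next
    }
    thr[i] <- .mixture_threshold(x)
    bin[i, ] <- as.numeric(x >= thr[i])
  }
  mam$binary <- bin
  mam$thresholds <- thr
  mam
}

# two-component GMM threshold with mean+sd fallback
.mixture_threshold <- function(x) {
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  fallback <- mean(x) + stats::sd(x)
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  par <- fit$parameters
  mu <- par$mean
  sd_ <- sqrt(par$variance$sigmasq)
  if (length(sd_) == 1) sd_ <- rep(sd_, 2)
  pro <- par$pro
  hi <- which.max(mu); lo <- which.min(mu)
  pooled <- sqrt(mean(sd_^2))
  if (min(pro) < 0.05 || abs(mu[hi] - mu[lo]) < 0.5 * pooled)
    return(fallback)
  grid <- seq(mu[lo], mu[hi], length.out = 512)
  post_hi <- pro[hi] * stats::dnorm(grid, mu[hi], sd_[hi]) /
    (pro[hi] * stats::dnorm(grid, mu[hi], sd_[hi]) +
       pro[lo] * stats::dnorm(grid, mu[lo], sd_[lo]))
  cross <- which(post_hi >= 0.5)
  if (length(cross) == 0) return(fallback)
  grid[cross[1]]
}

#' @export
print.ModuleActivityMatrix <- function(x, ...) {
  cat(sprintf("ModuleActivityMatrix: %d modules x %d cells (aucMaxRank %d%s)\n",
              nrow(x$auc), ncol(x$auc), x$auc_max_rank,
              if (is.null(x$binary)) "" else ", binarized"))
  invisible(x)
}
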