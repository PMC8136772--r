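#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency table with the standard permutation-model
#' correction.
#'
#' @param labels_a,labels_b vectors of equal length (>= 2 items).
#' @return ARI in `[-1, 1]`; 1 for identical partitions, ~0 at chance.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 items")
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' F1 score of cell-type and batch ARI
#'
#' Harmonic combination of clustering agreement with cell types and
#' disagreement with batches:
#' `F1 = 2 * ARI_cell * (1 - ARI_batch) / (1 - ARI_batch + ARI_cell)`.
#' Negative inputs are clipped to 0 with a warning (ARI can dip below 0 by
#' chance).
#'
#' @param ari_cell ARI against cell-type labels.
#' @param ari_batch ARI against batch labels.
#' @return value in `[0, 1]`; 0 when the denominator vanishes.
#' @export
f1_ari <- function(ari_cell, ari_batch) {
  if (ari_cell < 0 || ari_batch < 0) {
    warning("negative ARI clipped to 0")
    ari_cell <- max(0, ari_cell); ari_batch <- max(0, ari_batch)
  }
  den <- 1 - ari_batch + ari_cell
  if (den == 0) return(0)
  2 * ari_cell * (1 - ari_batch) / den
}

#' Local inverse Simpson's index (LISI)
#'
#' For every cell, neighbor weights over all other cells are calibrated by
#' entropy bisection of a Gaussian kernel to the requested perplexity (as in
#' the LISI method adopted from the Harmony line of work); the index is the
#' inverse Simpson concentration `1 / sum(p_l^2)` of the weighted label
#' distribution. Values range from 1 (all effective neighbors share the
#' cell's label context) to the number of labels (perfect local mixing).
#' Computed with batch labels it is iLISI, with cell-type labels cLISI.
#'
#' @param embedding cells x features numeric matrix.
#' @param labels per-cell labels.
#' @param perplexity effective neighborhood size (default 30).
#' @return numeric vector, one value per cell, in `[1, n_labels]`.
#' @export
lisi <- function(embedding, labels, perplexity = 30) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  if (n <= perplexity) stop("need more cells than the perplexity")
  lev <- unique(labels)
  if (length(lev) == 1) return(rep(1, n))
  d2 <- as.matrix(stats::dist(embedding))^2
  target <- log(perplexity)
  out <- numeric(n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    li <- labels[-i]
    w <- .perplexity_weights(di, target)
    pl <- vapply(lev, function(l) sum(w[li == l]), 1)
    out[i] <- 1 / sum(pl^2)
  }
  out
}

# bisection on the Gaussian precision so that the entropy of the normalized
# weights matches log(perplexity)
.perplexity_weights <- function(d2, target, tol = 1e-5, max_iter = 64) {
  beta <- 1; lo <- -Inf; hi <- Inf
  for (it in seq_len(max_iter)) {
    w <- exp(-d2 * beta)
    sw <- sum(w)
    if (sw == 0) { hi <- beta; beta <- beta / 2; next }
    h <- log(sw) + beta * sum(d2 * w) / sw
    if (abs(h - target) < tol) break
    if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  w / sum(w)
}

#' Area under the empirical CDF of LISI values
#'
#' Integrates the empirical CDF of per-cell LISI values from 1 to
#' `n_labels` and normalizes by `n_labels - 1` so the result lies in
#' `[0, 1]`. Values near 1 mean the distribution piles up at 1 (no local
#' mixing); values near 0 mean it piles up at `n_labels` (ideal mixing).
#'
#' @param lisi_values vector of LISI values in `[1, n_labels]`.
#' @param n_labels number of batches (iLISI) or cell types (cLISI), >= 2.
#' @param normalize divide by `n_labels - 1` (default TRUE; disable for the
#'   raw integral).
#' @return scalar in `[0, 1]` (or `[0, n_labels - 1]` unnormalized).
#' @export
aucdf <- function(lisi_values, n_labels, normalize = TRUE) {
  if (n_labels < 2) stop("n_labels must be >= 2")
  v <- lisi_values
  if (any(v < 1 - 1e-8 | v > n_labels + 1e-8))
    stop("LISI values outside [1, n_labels]")
  v <- pmin(pmax(v, 1), n_labels)
  knots <- sort(unique(c(1, v, n_labels)))
  cdf <- vapply(knots, function(x) mean(v <= x), 1)
  area <- sum(diff(knots) * cdf[-length(cdf)])
  if (normalize) area / (n_labels - 1) else area
}

#' F1 score of the LISI AUCDF pair
#'
#' Harmonic combination of cell-type purity (large `AUCDF_cLISI`) and batch
#' mixing (small `AUCDF_iLISI`):
#' `F1 = 2 * a_c * (1 - a_i) / (a_c + (1 - a_i))`.
#'
#' @param aucdf_clisi AUCDF of the cell-type LISI values, in `[0, 1]`.
#' @param aucdf_ilisi AUCDF of the batch LISI values, in `[0, 1]`.
#' @return value in `[0, 1]`; 0 when the denominator vanishes.
#' @export
f1_lisi <- function(aucdf_clisi, aucdf_ilisi) {
  stopifnot(aucdf_clisi >= 0, aucdf_clisi <= 1,
            aucdf_ilisi >= 0, aucdf_ilisi <= 1)
  den <- aucdf_clisi + (1 - aucdf_ilisi)
  if (den == 0) return(0)
  2 * aucdf_clisi * (1 - aucdf_ilisi) / den
}

#' Full integration report
#'
#' Bundles the clustering-vs-annotation statistics: ARI against cell types
#' and batches, their F1 combination, per-cell iLISI/cLISI on a given
#' embedding, the AUCDF summaries and their F1 combination.
#'
#' @param cluster_labels predicted cluster per cell.
#' @param cell_type known cell type per cell.
#' @param batch batch per cell.
#' @param embedding cells x features matrix for the LISI neighborhoods
#'   (e.g. `t(mam$auc)`); skipped (with `NA` LISI fields) when `NULL`.
#' @param perplexity LISI perplexity (default 30).
#' @return object of class `"IntegrationReport"` (a list of the named
#'   statistics).
#' @export
integration_report <- function(cluster_labels, cell_type, batch,
                               embedding = NULL, perplexity = 30) {
  ari_ct <- adjusted_rand_index(cluster_labels, cell_type)
  ari_b <- adjusted_rand_index(cluster_labels, batch)
  rep_ <- list(
    ari_cell_type = ari_ct, ari_batch = ari_b,
    f1_ari = f1_ari(max(0, ari_ct), max(0, ari_b)),
    n_cell_type = length(unique(cell_type)),
    n_batch = length(unique(batch)),
    ilisi = NA, clisi = NA, aucdf_ilisi = NA_real_, aucdf_clisi = NA_real_,
    f1_lisi = NA_real_)
  if (!is.null(embedding)) {
    il <- lisi(embedding, batch, perplexity)
    cl <- lisi(embedding, cell_type, perplexity)
    rep_$ilisi <- il; rep_$clisi <- cl
    if (rep_$n_batch >= 2) rep_$aucdf_ilisi <- aucdf(il, rep_$n_batch)
    if (rep_$n_cell_type >= 2) rep_$aucdf_clisi <- aucdf(cl, rep_$n_cell_type)
    if (is.finite(rep_$aucdf_ilisi) && is.finite(rep_$aucdf_clisi))
      rep_$f1_lisi <- f1_lisi(rep_$aucdf_clisi, rep_$aucdf_ilisi)
  }
  structure(rep_, class = "IntegrationReport")
}

#' @export
print.IntegrationReport <- function(x, ...) {
  cat("Integration report\n")
  cat(sprintf("  ARI cell type: %.4f   ARI batch: %.4f   F1_ARI: %.4f\n",
              x$ari_cell_type, x$ari_batch, x$f1_ari))
  if (is.finite(x$aucdf_ilisi) || is.finite(x$aucdf_clisi))
    cat(sprintf("  AUCDF iLISI: %.4f   AUCDF cLISI: %.4f   F1_LISI: %.4f\n",
                x$aucdf_ilisi, x$aucdf_clisi, x$f1_lisi))
  invisible(x)
}
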