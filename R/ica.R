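#' Estimate the number of expression programs by random matrix theory
#'
#' Standardizes every gene (mean 0, variance 1; constant genes dropped),
#' forms the cell-space sample covariance `t(X) %*% X / n_genes`, and counts
#' the eigenvalues exceeding the Marchenko--Pastur upper edge
#' `(1 + sqrt(gamma))^2` with `gamma = min(n, p) / max(n, p)`. Under a pure
#' noise model all eigenvalues fall below the edge, so the count estimates
#' the rank of the biological signal. The result is floored at 2 so
#' downstream program grouping always has material to work with.
#'
#' @param em log-normalized [expression_matrix()] with at least 3 genes and
#'   3 cells.
#' @return integer number of components (>= 2).
#' @export
estimate_component_count <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (!em$normalized) stop("estimate_component_count needs log-normalized input")
  if (nrow(em$values) < 3 || ncol(em$values) < 3)
    stop("need at least 3 genes and 3 cells")
  xs <- .standardize_genes(em$values)
  p <- nrow(xs); n <- ncol(xs)
  # Gram spectrum scaled by the sample count (the larger dimension), the
  # normalization under which the Marchenko-Pastur edge applies
  ev <- svd(xs, nu = 0, nv = 0)$d^2 / max(p, n)
  gamma <- min(n, p) / max(n, p)
  edge <- (1 + sqrt(gamma))^2
  max(2L, sum(ev > edge))
}

#' Denoise an expression matrix by signal-subspace projection
#'
#' Standardizes genes, keeps only the eigencomponents of the cell-space
#' covariance whose eigenvalues exceed the Marchenko--Pastur upper edge,
#' reconstructs the standardized matrix from that signal subspace, and
#' de-standardizes. Intended as an optional pre-processing stage for
#' datasets whose sparsity structure differs strongly between batches;
#' disabled by default in [icanet()].
#'
#' @param em log-normalized [expression_matrix()].
#' @return the denoised `ExpressionMatrix`; when no eigenvalue clears the
#'   edge the input is returned unchanged with a warning.
#' @export
rmt_denoise <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (!em$normalized) stop("rmt_denoise needs log-normalized input")
  x <- em$values
  mu <- rowMeans(x)
  sd_ <- apply(x, 1, stats::sd)
  keep <- sd_ > 0
  xs <- (x[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  p <- nrow(xs); n <- ncol(xs)
  sv <- svd(xs)
  ev <- sv$d^2 / max(p, n)
  gamma <- min(n, p) / max(n, p)
  edge <- (1 + sqrt(gamma))^2
  ns <- sum(ev > edge)
  if (ns == 0) {
    warning("no eigenvalue above the Marchenko-Pastur edge; returning input")
    return(em)
  }
  proj <- sv$u[, seq_len(ns), drop = FALSE] %*%
    (sv$d[seq_len(ns)] * t(sv$v[, seq_len(ns), drop = FALSE]))
  out <- em
  out$values[keep, ] <- proj * sd_[keep] + mu[keep]
  out
}

#' Decompose a batch into independent expression programs
#'
#' Runs ICA on the genes x cells matrix, treating genes as observations, so
#' that each recovered component ("expression program") is a gene-weight
#' vector. The matrix is centered per gene internally and whitened to `K`
#' dimensions by SVD. Two estimators are available: JADE (joint approximate
#' diagonalization of fourth-order cumulant eigen-matrices), which is
#' deterministic given the input, and Icasso-stabilised FastICA, which runs
#' several randomly restarted symmetric FastICA fits, pools all component
#' estimates, clusters them by absolute correlation and returns the cluster
#' centroids. Every returned column is re-standardized to mean 0, variance 1
#' over genes and sign-oriented so its skewness is non-negative.
#'
#' @param em log-normalized [expression_matrix()].
#' @param K number of components, `1 <= K < min(dim)`.
#' @param method `"jade"` (default) or `"fastica_icasso"`.
#' @param seed integer seed (used by the FastICA restarts; JADE ignores it).
#' @param n_restarts restarts for `fastica_icasso` (default 10).
#' @return object of class `"ExpressionProgramSet"`: list with `batch_id`,
#'   `source` (genes x K matrix), `K`, `method`.
#' @export
run_ica <- function(em, K, method = c("jade", "fastica_icasso"), seed = 0,
                    n_restarts = 10) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (!em$normalized) stop("run_ica needs log-normalized input")
  method <- match.arg(method)
  x <- em$values
  if (K < 1 || K >= min(dim(x)))
    stop("K must satisfy 1 <= K < min(n_genes, n_cells)")
  xc <- x - rowMeans(x)
  p <- nrow(xc)
  sv <- svd(xc, nu = K, nv = 0)
  if (sv$d[K] < 1e-12 * sv$d[1])
    stop("matrix rank below K; reduce the number of components")
  z <- sv$u[, seq_len(K), drop = FALSE] * sqrt(p)  # whitened: crossprod(z)/p = I
  s <- if (method == "jade") {
    z %*% .jade_rotation(z)
  } else {
    .fastica_icasso(z, K, seed = seed, n_restarts = n_restarts)
  }
  s <- .standardize_columns(s)
  s <- .orient_skewness(s)
  rownames(s) <- em$gene_ids
  colnames(s) <- paste0("IC", seq_len(ncol(s)))
  structure(list(batch_id = em$batch[1], source = s, K = ncol(s),
                 method = method),
            class = "ExpressionProgramSet")
}

#' @export
print.ExpressionProgramSet <- function(x, ...) {
  cat(sprintf("ExpressionProgramSet: batch '%s', %d programs over %d genes (%s)\n",
              x$batch_id, x$K, nrow(x$source), x$method))
  invisible(x)
}

# ---- internals --------------------------------------------------------------

.standardize_genes <- function(x) {
  mu <- rowMeans(x)
  sd_ <- apply(x, 1, stats::sd)
  keep <- sd_ > 0
  (x[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
}

.standardize_columns <- function(s) {
  s <- sweep(s, 2, colMeans(s), "-")
  sd_ <- apply(s, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  sweep(s, 2, sd_, "/")
}

.orient_skewness <- function(s) {
  sk <- colMeans(s^3)
  sweep(s, 2, ifelse(sk < 0, -1, 1), "*")
}

# JADE on a whitened matrix z (samples x K): returns the K x K rotation.
# Fourth-order cumulant matrices are jointly diagonalized by Jacobi (Givens)
# rotations; tolerance 1e-6 on the rotation sine, at most 100 sweeps.
.jade_rotation <- function(z, tol = 1e-6, max_sweeps = 100) {
  p <- nrow(z); K <- ncol(z)
  nmat <- K * (K + 1) / 2
  # cumulant set: Q_ij = E[z_i z_j z z^T] - I*delta_ij - e_i e_j^T - e_j e_i^T
  cm <- array(0, dim = c(K, K, nmat))
  m <- 0L
  for (i in seq_len(K)) for (j in seq_len(i)) {
    m <- m + 1L
    q <- crossprod(z * (z[, i] * z[, j]), z) / p
    if (i == j) q <- q - diag(K)
    q[i, j] <- q[i, j] - 1
    q[j, i] <- q[j, i] - 1
    cm[, , m] <- if (i == j) q else q * sqrt(2)
  }
  v <- diag(K)
  for (sweep_i in seq_len(max_sweeps)) {
    rotated <- FALSE
    for (a in seq_len(K - 1)) for (b in (a + 1):K) {
      ton <- cm[a, a, ] - cm[b, b, ]
      toff <- cm[a, b, ] + cm[b, a, ]
      g11 <- sum(ton * ton); g12 <- sum(ton * toff); g22 <- sum(toff * toff)
      t_on <- g11 - g22; t_off <- 2 * g12
      theta <- 0.5 * atan2(t_off, t_on + sqrt(t_on^2 + t_off^2))
      cs <- cos(theta); sn <- sin(theta)
      if (abs(sn) > tol) {
        rotated <- TRUE
        rows_a <- cm[a, , ]; rows_b <- cm[b, , ]
        cm[a, , ] <- cs * rows_a + sn * rows_b
        cm[b, , ] <- -sn * rows_a + cs * rows_b
        cols_a <- cm[, a, ]; cols_b <- cm[, b, ]
        cm[, a, ] <- cs * cols_a + sn * cols_b
        cm[, b, ] <- -sn * cols_a + cs * cols_b
        va <- v[, a]; vb <- v[, b]
        v[, a] <- cs * va + sn * vb
        v[, b] <- -sn * va + cs * vb
      }
    }
    if (!rotated) break
  }
  v
}

# symmetric FastICA (logcosh nonlinearity) on whitened z; returns samples x K
.fastica_once <- function(z, K, w0, tol = 1e-6, max_iter = 200) {
  p <- nrow(z)
  w <- .orthonormalize(w0)
  for (it in seq_len(max_iter)) {
    wx <- z %*% w                       # p x K
    gwx <- tanh(wx)
    w_new <- crossprod(z, gwx) / p - w %*% diag(colMeans(1 - gwx^2), K, K)
    w_new <- .orthonormalize(w_new)
    delta <- 1 - abs(colSums(w_new * w))
    w <- w_new
    if (max(delta) < tol) return(list(w = w, converged = TRUE))
  }
  list(w = w, converged = FALSE)
}

.orthonormalize <- function(w) {
  s <- svd(w)
  s$u %*% t(s$v)
}

# Icasso-style stabilisation: restart, pool all R*K estimates, cluster by
# absolute correlation, average within clusters.
.fastica_icasso <- function(z, K, seed, n_restarts) {
  est <- vector("list", n_restarts)
  failed <- integer(0)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    w0 <- matrix(stats::rnorm(ncol(z) * K), ncol(z), K)
    fit <- .fastica_once(z, K, w0)
    if (!fit$converged) failed <- c(failed, r)
    est[[r]] <- z %*% fit$w
  }
  if (length(failed) == n_restarts)
    stop("FastICA failed to converge in all restarts: ",
         paste(failed, collapse = ", "))
  if (length(failed) > 0)
    warning("FastICA restarts not converged: ", paste(failed, collapse = ", "))
  pool <- do.call(cbind, est)                 # p x (R*K)
  d <- stats::as.dist(1 - abs(stats::cor(pool)))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = K)
  cent <- sapply(seq_len(K), function(g) {
    cols <- pool[, cl == g, drop = FALSE]
    ref <- cols[, 1]
    signs <- sign(as.numeric(stats::cor(ref, cols)))
    signs[signs == 0] <- 1
    rowMeans(sweep(cols, 2, signs, "*"))
  })
  cent
}
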