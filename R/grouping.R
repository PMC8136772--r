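#' Genes activated in an expression program
#'
#' A program's activated genes are those whose standardized weight exceeds
#' `sd_threshold` in absolute value (strictly): ICA components are two-tailed
#' so both strongly positive and strongly negative weights mark membership.
#'
#' @param program named numeric vector of standardized gene weights.
#' @param sd_threshold threshold in standard deviations (default 2.5).
#' @return character vector of gene ids (possibly empty).
#' @export
select_activated_genes <- function(program, sd_threshold = 2.5) {
  stopifnot(is.numeric(program))
  names(program)[abs(program) > sd_threshold]
}

#' Pairwise similarity of expression programs
#'
#' `s(i, j)` is the absolute Pearson correlation of the two programs' weight
#' vectors restricted to the genes activated in both programs; the absolute
#' value absorbs ICA's sign ambiguity. Restricting to the shared activated
#' genes (rather than their union) matters: two programs over disjoint gene
#' sets are strongly anti-correlated across the union of their signatures —
#' each is high exactly where the other is low — so a union-based |r| would
#' score unrelated programs as near-identical. Pairs sharing fewer than 3
#' activated genes get similarity 0; the diagonal is 1.
#'
#' @param programs genes x m matrix of standardized program weights (pooled
#'   across batches), or a list of `ExpressionProgramSet` objects.
#' @param sd_threshold activation threshold passed to
#'   [select_activated_genes()].
#' @return m x m symmetric similarity matrix in `[0, 1]`.
#' @export
program_similarity_matrix <- function(programs, sd_threshold = 2.5) {
  programs <- .pool_programs(programs)
  m <- ncol(programs)
  if (m < 2) stop("need at least 2 programs")
  act <- lapply(seq_len(m), function(i)
    which(abs(programs[, i]) > sd_threshold))
  s <- diag(1, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    u <- intersect(act[[i]], act[[j]])
    s[i, j] <- s[j, i] <- if (length(u) < 3) 0 else {
      r <- suppressWarnings(stats::cor(programs[u, i], programs[u, j]))
      if (is.na(r)) 0 else abs(r)
    }
  }
  dimnames(s) <- list(colnames(programs), colnames(programs))
  s
}

#' Group expression programs across batches into basal programs
#'
#' Clusters the pooled programs by partitioning around medoids (PAM) on the
#' distance `1 - s` for every `k` in `k_range`, picks the `k` with the
#' largest average silhouette width (ties toward the smaller `k`), and
#' returns the medoid programs as the "basal programs" shared across
#' batches.
#'
#' @param programs pooled program matrix (genes x m) or list of
#'   `ExpressionProgramSet` objects; m >= 3.
#' @param k_range candidate numbers of groups, a subset of
#'   `2:(m - 1)`; default `2:min(15, m - 1)`.
#' @param sd_threshold activation threshold used for the similarity matrix.
#' @return object of class `"BasalProgramSet"`: list with `programs`,
#'   `batch_of`, `similarity`, `clusters`, `k_star`, `silhouette`
#'   (named by k), `medoids` (genes x k_star matrix), `medoid_ids`.
#' @export
group_programs <- function(programs, k_range = NULL, sd_threshold = 2.5) {
  batch_of <- .pooled_batches(programs)
  programs <- .pool_programs(programs)
  m <- ncol(programs)
  if (m < 3) stop("need at least 3 programs to group")
  if (is.null(k_range)) k_range <- 2:min(15, m - 1)
  k_range <- as.integer(k_range)
  if (any(k_range < 2 | k_range > m - 1))
    stop("k_range must lie within [2, n_programs - 1]")
  s <- program_similarity_matrix(programs, sd_threshold = sd_threshold)
  d <- 1 - s
  degenerate <- all(d[upper.tri(d)] == 0)
  if (degenerate) {
    warning("degenerate program distance matrix (all zero); using k_star = 2")
    k_range <- 2L
  }
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- cluster::pam(stats::as.dist(d), k = k_range[i],
                              diss = TRUE, cluster.only = FALSE)
    sil[i] <- if (degenerate) NA_real_ else fits[[i]]$silinfo$avg.width
  }
  best <- if (degenerate) 1L else which.max(sil)  # which.max: first max = smallest k
  fit <- fits[[best]]
  medoid_ids <- fit$medoids
  structure(
    list(programs = programs, batch_of = batch_of, similarity = s,
         clusters = fit$clustering, k_star = k_range[best],
         silhouette = sil,
         medoids = programs[, medoid_ids, drop = FALSE],
         medoid_ids = medoid_ids),
    class = "BasalProgramSet")
}

#' @export
print.BasalProgramSet <- function(x, ...) {
  cat(sprintf("BasalProgramSet: %d programs -> %d basal programs (k_star)\n",
              ncol(x$programs), x$k_star))
  cat("  medoids:", paste(x$medoid_ids, collapse = ", "), "\n")
  invisible(x)
}

# pool a list of ExpressionProgramSet (or a single matrix) to genes x m,
# with unique column names batch.IC
.pool_programs <- function(programs) {
  if (is.matrix(programs)) {
    if (is.null(colnames(programs)))
      colnames(programs) <- paste0("P", seq_len(ncol(programs)))
    return(programs)
  }
  if (inherits(programs, "ExpressionProgramSet")) programs <- list(programs)
  stopifnot(all(vapply(programs, inherits, TRUE, "ExpressionProgramSet")))
  genes <- Reduce(intersect, lapply(programs, function(p) rownames(p$source)))
  if (length(genes) == 0) stop("program sets share no genes")
  mats <- lapply(programs, function(p) {
    s <- p$source[genes, , drop = FALSE]
    colnames(s) <- paste0(p$batch_id, ".", colnames(s))
    s
  })
  do.call(cbind, mats)
}

.pooled_batches <- function(programs) {
  if (is.matrix(programs)) return(rep(NA_character_, ncol(programs)))
  if (inherits(programs, "ExpressionProgramSet")) programs <- list(programs)
  unlist(lapply(programs, function(p) rep(p$batch_id, p$K)))
}
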