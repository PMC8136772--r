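#' Define a synthetic multi-batch scRNA-seq scenario
#'
#' Fixes every parameter of the generative model used by
#' [simulate_multibatch()] and [simulate_ppi()]. Cells belong to
#' `n_cell_types` types, each driven by its own planted expression program
#' (a sparse gene-weight vector); the last type is rare, occupying
#' `rare_fraction` of cells with an exclusive program. Gene means follow
#' `baseline(g) * exp(loading(type, k) * program_k(g)) * batch_effect(b, g)`
#' with log-normal baselines, gene-wise multiplicative (log-additive) batch
#' effects, Poisson counts at a log-normal library size, and gene-wise
#' Bernoulli dropout.
#'
#' @param n_genes,n_cells_per_batch,n_batches,n_cell_types scenario sizes
#'   (defaults 2000 genes, 500 cells x 2 batches, 3 types; 2000 genes is
#'   the order of a post-filter variable-gene universe, and keeps the
#'   5-percent AUCell window comfortably wider than a program signature).
#' @param rare_fraction fraction of cells in the rare type, in `[0, 0.5)`
#'   (default 0.05); 0 disables the rare type (the last type becomes an
#'   ordinary equal-share type).
#' @param program_size signature genes per planted program (default 40).
#' @param loading_strength log-fold activity of a type on its own program
#'   (default 1).
#' @param loading_jitter_sd SD of an optional per-cell log-normal jitter on
#'   program activity (default 0): positive values let cells of a type vary
#'   continuously in how strongly they express the type's program, as real
#'   pathway activity does, at the cost of blurring the type structure.
#' @param batch_effect_sd SD of the per-gene log batch effect (default 0.2,
#'   calibrated so that naive concatenation of the batches is visibly
#'   confounded while the effect stays within reach of module-level
#'   integration at this gene-count scale).
#' @param library_size median library size (default 5000).
#' @param dropout_scale expected-count scale of the detection curve: gene g
#'   is detected per cell with probability
#'   `1 - exp(-expected_count(g) / dropout_scale)`, so sparsity concentrates
#'   in lowly expressed genes as in real droplet data (default 2).
#' @param seed scenario seed; the same seed reproduces the scenario
#'   bit-identically.
#' @return object of class `"SyntheticScenario"`.
#' @export
synthetic_scenario <- function(n_genes = 2000, n_cells_per_batch = 500,
                               n_batches = 2, n_cell_types = 3,
                               rare_fraction = 0.05, program_size = 40,
                               loading_strength = 1.0, loading_jitter_sd = 0,
                               batch_effect_sd = 0.2,
                               library_size = 5000,
                               dropout_scale = 2, seed = 1) {
  stopifnot(n_genes > 0, n_cells_per_batch > 0, n_batches > 0,
            n_cell_types >= 1, rare_fraction >= 0, rare_fraction < 0.5,
            program_size * n_cell_types <= n_genes)
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  types <- paste0("type", seq_len(n_cell_types))
  # disjoint sparse programs, one per type; positive weights (marker-like)
  picked <- sample(n_genes, program_size * n_cell_types)
  programs <- matrix(0, n_genes, n_cell_types,
                     dimnames = list(genes, paste0("prog", seq_len(n_cell_types))))
  for (k in seq_len(n_cell_types)) {
    gs <- picked[((k - 1) * program_size + 1):(k * program_size)]
    programs[gs, k] <- stats::runif(program_size, 1.5, 3)
  }
  loadings <- diag(loading_strength, n_cell_types)
  dimnames(loadings) <- list(types, colnames(programs))
  baseline <- stats::setNames(exp(stats::rnorm(n_genes, 0, 1)), genes)
  batch_effect <- matrix(exp(stats::rnorm(n_batches * n_genes, 0,
                                          batch_effect_sd)),
                         n_batches, n_genes,
                         dimnames = list(paste0("batch", seq_len(n_batches)),
                                         genes))
  # reference per-gene detection probabilities at baseline abundance; the
  # sampler applies the same curve at each entry's own expected count, so
  # zero inflation concentrates in lowly expressed genes (splatter-style)
  expected_count <- library_size * baseline / sum(baseline)
  dropout <- stats::setNames(1 - exp(-expected_count / dropout_scale), genes)
  structure(
    list(n_genes = n_genes, n_cells_per_batch = n_cells_per_batch,
         n_batches = n_batches, n_cell_types = n_cell_types,
         rare_fraction = rare_fraction, programs = programs,
         loadings = loadings, baseline = baseline,
         batch_effect = batch_effect, dropout = dropout,
         library_size = library_size, loading_strength = loading_strength,
         loading_jitter_sd = loading_jitter_sd, dropout_scale = dropout_scale,
         seed = seed),
    class = "SyntheticScenario")
}

#' @export
print.SyntheticScenario <- function(x, ...) {
  cat(sprintf(
    "SyntheticScenario: %d genes, %d batches x %d cells, %d types (rare %.0f%%), seed %d\n",
    x$n_genes, x$n_batches, x$n_cells_per_batch, x$n_cell_types,
    100 * x$rare_fraction, x$seed))
  invisible(x)
}

#' Simulate multi-batch count matrices with planted structure
#'
#' Draws cells for every batch under the scenario's generative model and
#' returns counts-state [expression_matrix()] objects alongside the ground
#' truth (cell types, program loadings, program gene members).
#'
#' @param sc a [synthetic_scenario()].
#' @return list with `batches` (list of `ExpressionMatrix`), `truth`
#'   (list: `cell_type` per batch, `programs`, `program_genes`).
#' @export
simulate_multibatch <- function(sc) {
  stopifnot(inherits(sc, "SyntheticScenario"))
  set.seed(sc$seed + 1L)
  types <- rownames(sc$loadings)
  K <- sc$n_cell_types
  props <- if (sc$rare_fraction > 0 && K > 1)
    c(rep((1 - sc$rare_fraction) / (K - 1), K - 1), sc$rare_fraction)
  else rep(1 / K, K)
  batches <- vector("list", sc$n_batches)
  truth_ct <- vector("list", sc$n_batches)
  activity <- vector("list", sc$n_batches)
  for (b in seq_len(sc$n_batches)) {
    nc <- sc$n_cells_per_batch
    ct <- sample(types, nc, replace = TRUE, prob = props)
    act <- t(sc$loadings[ct, , drop = FALSE]) *
      matrix(exp(stats::rnorm(K * nc, 0, sc$loading_jitter_sd)), K, nc)
    activity[[b]] <- act
    mu <- sc$baseline * exp(sc$programs %*% act) * sc$batch_effect[b, ]
    mu <- sweep(mu, 2, colSums(mu), "/")
    lib <- exp(stats::rnorm(nc, log(sc$library_size), 0.3))
    lambda <- sweep(mu, 2, lib, "*")
    counts <- matrix(stats::rpois(sc$n_genes * nc, lambda = lambda),
                     sc$n_genes, nc)
    scale_ <- -log(1 - sc$dropout) / (sc$library_size * sc$baseline /
                                        sum(sc$baseline))
    p_detect <- 1 - exp(-lambda * scale_)   # detection curve at each entry
    detected <- matrix(stats::rbinom(sc$n_genes * nc, 1, p_detect),
                       sc$n_genes, nc)
    counts <- counts * detected
    dead <- colSums(counts) == 0
    counts[1, dead] <- 1                     # keep every cell non-empty
    dimnames(counts) <- list(names(sc$baseline),
                             sprintf("b%d_c%03d", b, seq_len(nc)))
    batches[[b]] <- expression_matrix(
      counts, batch = rownames(sc$batch_effect)[b],
      cell_type = ct, normalized = FALSE)
    truth_ct[[b]] <- ct
  }
  program_genes <- apply(sc$programs, 2, function(w)
    names(w)[w > 0], simplify = FALSE)
  list(batches = batches,
       truth = list(cell_type = truth_ct, programs = sc$programs,
                    program_genes = program_genes,
                    program_activity = activity,
                    rare_type = if (sc$rare_fraction > 0)
                      types[K] else NULL))
}

#' Simulate a matched interaction network
#'
#' Builds a STRING-dialect edge table whose dense subgraphs coincide with
#' the planted programs: the top `module_size` genes of every program are
#' wired at `planted_density` with scores in (700, 999]; background
#' Erdos-Renyi edges at `background_density` carry scores in (300, 999], so
#' only part of the background survives the standard score filter.
#'
#' @param sc a [synthetic_scenario()].
#' @param background_density background edge probability, in `(0, 0.2)`
#'   (default 0.01).
#' @param module_size genes per planted module (default 25).
#' @param planted_density within-module edge probability (default 0.8).
#' @return list with `edges` (data.frame `protein1`, `protein2`,
#'   `combined_score`) and `truth_modules` (named list of gene sets).
#' @export
simulate_ppi <- function(sc, background_density = 0.01, module_size = 25,
                         planted_density = 0.8) {
  stopifnot(inherits(sc, "SyntheticScenario"),
            background_density > 0, background_density < 0.2)
  set.seed(sc$seed + 2L)
  genes <- rownames(sc$programs)
  truth <- list()
  from <- character(0); to <- character(0); score <- integer(0)
  for (k in seq_len(ncol(sc$programs))) {
    w <- sc$programs[, k]
    top <- names(sort(w, decreasing = TRUE))[seq_len(module_size)]
    truth[[colnames(sc$programs)[k]]] <- sort(top)
    pairs <- utils::combn(top, 2)
    keep <- stats::runif(ncol(pairs)) < planted_density
    from <- c(from, pairs[1, keep]); to <- c(to, pairs[2, keep])
    score <- c(score, sample(701:999, sum(keep), replace = TRUE))
  }
  n <- length(genes)
  n_bg <- stats::rbinom(1, n * (n - 1) / 2, background_density)
  i <- sample(n, n_bg, replace = TRUE)
  j <- sample(n, n_bg, replace = TRUE)
  ok <- i != j
  from <- c(from, genes[pmin(i, j)[ok]])
  to <- c(to, genes[pmax(i, j)[ok]])
  score <- c(score, sample(301:999, sum(ok), replace = TRUE))
  edges <- data.frame(protein1 = from, protein2 = to,
                      combined_score = score, stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(pmin(edges$protein1, edges$protein2),
                                   pmax(edges$protein1, edges$protein2))), ]
  rownames(edges) <- NULL
  list(edges = edges, truth_modules = truth)
}

#' Binomial thinning of counts
#'
#' Simulates a shallower sequencing run by keeping every read independently
#' with probability `keep`.
#'
#' @param em counts-state [expression_matrix()].
#' @param keep retention probability in `(0, 1]` (default 0.2, i.e.
#'   one-fifth of the original depth).
#' @param seed RNG seed.
#' @return thinned counts-state `ExpressionMatrix`.
#' @export
thin_counts <- function(em, keep = 0.2, seed = 0) {
  stopifnot(inherits(em, "ExpressionMatrix"), !em$normalized,
            keep > 0, keep <= 1)
  if (keep == 1) return(em)
  set.seed(seed)
  v <- em$values
  v[] <- stats::rbinom(length(v), size = as.integer(v), prob = keep)
  out <- em
  out$values <- v
  out
}

#' Down-sample cells
#'
#' Uniform (or cell-type-stratified) sampling of `n` cells without
#' replacement; batch and cell-type labels are carried along.
#'
#' @param em an [expression_matrix()].
#' @param n number of cells to keep, `1 <= n <= n_cells`.
#' @param stratify_by_type balance the sample across cell types (requires
#'   `em$cell_type`).
#' @param seed RNG seed.
#' @return the down-sampled `ExpressionMatrix`.
#' @export
downsample_cells <- function(em, n, stratify_by_type = FALSE, seed = 0) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  nc <- length(em$cell_ids)
  if (n < 1 || n > nc) stop("n must lie in [1, n_cells]")
  set.seed(seed)
  idx <- if (stratify_by_type) {
    if (is.null(em$cell_type)) stop("stratified sampling needs cell_type")
    types <- unique(em$cell_type)
    per <- n %/% length(types)
    extra <- n - per * length(types)
    unlist(lapply(seq_along(types), function(i) {
      pool <- which(em$cell_type == types[i])
      take <- per + (i <= extra)
      if (take > length(pool))
        stop("cell type '", types[i], "' has fewer than ", take, " cells")
      sample(pool, take)
    }))
  } else sample(nc, n)
  out <- em
  out$values <- em$values[, idx, drop = FALSE]
  out$cell_ids <- em$cell_ids[idx]
  out$batch <- em$batch[idx]
  if (!is.null(em$cell_type)) out$cell_type <- em$cell_type[idx]
  out
}
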