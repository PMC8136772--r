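# small constructors used across the suite

mk_em <- function(values, batch = "b1", normalized = FALSE, cell_type = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  expression_matrix(values, batch = batch, cell_type = cell_type,
                    normalized = normalized)
}

# gaussian noise matrix wrapped as a log-normalized ExpressionMatrix
mk_noise_em <- function(p, n, seed, sd = 1, shift = TRUE) {
  set.seed(seed)
  x <- matrix(stats::rnorm(p * n, sd = sd), p, n)
  if (shift) x <- x - min(x)
  mk_em(x, normalized = TRUE)
}

# mix k Laplace sources into a genes x cells matrix; returns sources too
mk_ica_input <- function(p, n, k, seed, noise_sd = 0.1) {
  set.seed(seed)
  s <- matrix(sample(c(-1, 1), p * k, TRUE) * stats::rexp(p * k), p, k)
  a <- matrix(stats::rnorm(k * n), k, n)
  x <- s %*% a + matrix(stats::rnorm(p * n, sd = noise_sd), p, n)
  list(em = mk_em(x - min(x), normalized = TRUE), sources = s)
}

# toy weighted network: two 5-cliques bridged by one weak edge
mk_two_clique_network <- function(w_in = 1, w_bridge = 0.01) {
  g1 <- paste0("a", 1:5); g2 <- paste0("b", 1:5)
  e1 <- t(utils::combn(g1, 2)); e2 <- t(utils::combn(g2, 2))
  edges <- data.frame(from = c(e1[, 1], e2[, 1], "a1"),
                      to = c(e1[, 2], e2[, 2], "b1"),
                      weight = c(rep(w_in, nrow(e1) + nrow(e2)), w_bridge),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges,
                 ica_stat = stats::setNames(rep(3, 10), c(g1, g2)),
                 program_id = "toy"),
            class = "WeightedNetwork")
}

# independent oracle: recovery-curve AUC by direct enumeration over ranks
brute_auc <- function(ranks_of_module, L, m_total) {
  r_curve <- vapply(seq_len(L), function(i) sum(ranks_of_module <= i), 1)
  m_eff <- min(m_total, L)
  best <- vapply(seq_len(L), function(i) min(i, m_eff), 1)
  sum(r_curve) / sum(best)
}

default_resolution_grid <- c(0.05, 0.1, 0.25, 0.5, 1)

# the evaluation protocol: recluster a fitted SNN over a resolution grid and
# keep the labels with the best cell-type agreement
sweep_resolution <- function(snn, cell_type, grid = default_resolution_grid,
                             seed = 0) {
  best <- list(ari = -Inf, labels = NULL)
  for (r in grid) {
    cl <- louvain_cluster(snn, resolution = r, seed = seed)
    a <- adjusted_rand_index(cl$labels, cell_type)
    if (a > best$ari) best <- list(ari = a, labels = cl$labels)
  }
  best
}
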