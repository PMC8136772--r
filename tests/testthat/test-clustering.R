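test_that("snn edge weights follow Jaccard overlap of neighbor sets", {
  # two identical profiles share identical neighbor sets -> weight 1
  set.seed(201)
  feat <- rbind(matrix(0, 2, 3),                       # duplicated pair
                matrix(stats::rnorm(30, mean = 10), 10, 3))
  rownames(feat) <- paste0("c", 1:12)
  g <- build_snn(feat, k_neighbors = 3, prune = 0)
  w12 <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("1", "2"))]
  expect_equal(w12, 1)
})

test_that("well-separated blobs keep no cross-blob edges after pruning", {
  set.seed(202)
  feat <- rbind(matrix(stats::rnorm(45, 0, 0.1), 15, 3),
                matrix(stats::rnorm(45, 8, 0.1), 15, 3))
  rownames(feat) <- paste0("c", 1:30)
  g <- build_snn(feat, k_neighbors = 5)
  ends <- igraph::ends(g, igraph::E(g))
  blob <- function(id) (as.integer(id) - 1) %/% 15
  cross <- sum(blob(ends[, 1]) != blob(ends[, 2]))
  expect_identical(cross, 0L)
  expect_error(build_snn(feat, k_neighbors = 30), "smaller")
})

test_that("louvain separates disconnected cliques and respects resolution", {
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(6))
  igraph::E(g)$weight <- 1
  igraph::V(g)$cell_id <- paste0("c", 1:12)
  cl <- louvain_cluster(g, resolution = 1.0, seed = 0)
  expect_identical(length(unique(cl$labels)), 2L)
  expect_identical(sort(unique(cl$labels)), c(0L, 1L))   # contiguous from 0
  # single vertex
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$cell_id <- "c1"
  expect_identical(unname(louvain_cluster(g1)$labels), 0L)
  # cluster count non-decreasing over a rising resolution sweep
  set.seed(203)
  gs <- igraph::sample_gnp(60, 0.2)
  igraph::E(gs)$weight <- stats::runif(igraph::ecount(gs))
  igraph::V(gs)$cell_id <- paste0("c", 1:60)
  ns <- vapply(c(0.2, 1, 3), function(r)
    length(unique(louvain_cluster(gs, resolution = r, seed = 1)$labels)), 1L)
  expect_true(all(diff(ns) >= 0))
})

mk_marker_mam <- function(auc, binary) {
  structure(list(auc = auc, binary = binary, auc_max_rank = 5,
                 thresholds = NULL, seed = 0,
                 batch = rep("b", ncol(auc)), cell_type = NULL),
            class = "ModuleActivityMatrix")
}

test_that("marker screening keeps perfect markers and drops flat ones", {
  set.seed(204)
  n <- 60
  labels <- rep(c("k0", "k1"), each = n / 2)
  perfect <- as.numeric(labels == "k1")
  auc <- rbind(perfect = perfect * 0.6 + stats::runif(n, 0, 0.01),
               flat = rep(0.4, n))
  colnames(auc) <- paste0("c", 1:n)
  mam <- mk_marker_mam(auc, rbind(perfect = perfect, flat = rep(0, n)))
  out <- find_celltype_modules(mam, labels, n_perm = 200, seed = 1)
  expect_true(any(out$module == "perfect" & out$cluster == "k1"))
  expect_false(any(out$module == "flat"))
  tested <- attr(out, "tested")
  expect_equal(tested$roc_auc[tested$module == "perfect" &
                                tested$cluster == "k1"], 1)
  # a perfect marker of k1 is never simultaneously kept for disjoint k0
  expect_false(any(out$module == "perfect" & out$cluster == "k0"))
})

test_that("marker statistics match brute-force oracles", {
  # spearman on a 20-cell toy equals cor of ranks
  set.seed(205)
  b <- sample(0:1, 20, TRUE)
  ind <- sample(0:1, 20, TRUE)
  expect_equal(stats::cor(b, ind, method = "spearman"),
               stats::cor(rank(b), rank(ind)))
  # roc auc agrees with pROC on a random instance
  skip_if_not_installed("pROC")
  score <- stats::runif(40)
  pos <- sample(0:1, 40, TRUE)
  expect_equal(icanet:::.roc_auc(score, pos),
               as.numeric(pROC::auc(pROC::roc(pos, score,
                                              direction = "<",
                                              quiet = TRUE))))
})

test_that("marker screening is invariant to cluster relabeling", {
  set.seed(206)
  n <- 45
  labels <- rep(c("a", "b", "c"), each = 15)
  auc <- rbind(m1 = as.numeric(labels == "a") * 0.5 + stats::runif(n, 0, 0.02),
               m2 = as.numeric(labels == "c") * 0.5 + stats::runif(n, 0, 0.02))
  colnames(auc) <- paste0("c", 1:n)
  bin <- rbind(m1 = as.numeric(labels == "a"), m2 = as.numeric(labels == "c"))
  mam <- mk_marker_mam(auc, bin)
  out1 <- find_celltype_modules(mam, labels, n_perm = 200, seed = 2)
  relab <- c(a = "z", b = "y", c = "x")[labels]
  out2 <- find_celltype_modules(mam, relab, n_perm = 200, seed = 2)
  key1 <- sort(paste(out1$module, c(a = "z", b = "y", c = "x")[out1$cluster]))
  key2 <- sort(paste(out2$module, out2$cluster))
  expect_identical(key1, key2)
})
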