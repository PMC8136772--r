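test_that("scenarios are bit-reproducible from their seed", {
  s1 <- simulate_multibatch(synthetic_scenario(n_genes = 300,
                                               n_cells_per_batch = 60,
                                               seed = 5))
  s2 <- simulate_multibatch(synthetic_scenario(n_genes = 300,
                                               n_cells_per_batch = 60,
                                               seed = 5))
  expect_identical(s1$batches[[1]]$values, s2$batches[[1]]$values)
  expect_identical(s1$truth$cell_type, s2$truth$cell_type)
  p1 <- simulate_ppi(synthetic_scenario(n_genes = 300, seed = 5))
  p2 <- simulate_ppi(synthetic_scenario(n_genes = 300, seed = 5))
  expect_identical(p1$edges, p2$edges)
})

test_that("without batch effects the batches share their mean profile", {
  sc <- synthetic_scenario(n_genes = 500, n_cells_per_batch = 500,
                           batch_effect_sd = 0, seed = 6)
  expect_true(all(sc$batch_effect == 1))
  sim <- simulate_multibatch(sc)
  m1 <- rowMeans(sim$batches[[1]]$values)
  m2 <- rowMeans(sim$batches[[2]]$values)
  expect_gt(stats::cor(m1, m2), 0.95)
})

test_that("the rare-type switch and truth tables behave", {
  sc0 <- synthetic_scenario(n_genes = 300, n_cells_per_batch = 90,
                            rare_fraction = 0, seed = 7)
  sim0 <- simulate_multibatch(sc0)
  expect_null(sim0$truth$rare_type)
  tt <- table(sim0$batches[[1]]$cell_type)
  expect_gt(min(tt) / max(tt), 0.3)          # roughly equal shares
  sc <- synthetic_scenario(n_genes = 300, n_cells_per_batch = 200,
                           rare_fraction = 0.05, seed = 7)
  sim <- simulate_multibatch(sc)
  frac <- mean(sim$batches[[1]]$cell_type == sim$truth$rare_type)
  expect_lt(frac, 0.15)
  expect_identical(sort(names(sim$truth$program_genes)),
                   sort(colnames(sc$programs)))
})

test_that("planted programs create within-module co-expression", {
  sc <- synthetic_scenario(n_genes = 400, n_cells_per_batch = 300, seed = 8)
  sim <- simulate_multibatch(sc)
  em <- lognormalize(sim$batches[[1]])
  genes1 <- sim$truth$program_genes[[1]][1:12]
  set.seed(8)
  others <- sample(setdiff(em$gene_ids, unlist(sim$truth$program_genes)), 12)
  cors <- stats::cor(t(em$values[c(genes1, others), ]))
  within <- cors[1:12, 1:12][upper.tri(diag(12))]
  cross <- cors[1:12, 13:24]
  expect_lt(stats::wilcox.test(within, c(cross),
                               alternative = "greater")$p.value, 0.01)
})

test_that("the planted ppi passes the loader and matches density arithmetic", {
  sc <- synthetic_scenario(n_genes = 400, seed = 9)
  net <- simulate_ppi(sc, module_size = 8, planted_density = 0.7)
  ppi <- load_ppi(net$edges, score_threshold = 600)
  for (m in net$truth_modules) {
    ind <- sum(ppi$edges$from %in% m & ppi$edges$to %in% m)
    expect_gte(ind, stats::qbinom(0.001, 28, 0.7))   # 0.7 * C(8,2) ~ 19.6
    expect_lte(ind, 28)
  }
  # with no background the components are exactly the planted modules
  net0 <- simulate_ppi(sc, background_density = 1e-9, module_size = 8,
                       planted_density = 1)
  g <- igraph::graph_from_data_frame(net0$edges[, 1:2], directed = FALSE)
  comps <- igraph::components(g)
  sets <- split(names(comps$membership), comps$membership)
  expect_setequal(unname(lapply(sets, sort)),
                  unname(lapply(net0$truth_modules, sort)))
})

test_that("binomial thinning scales totals and keeps zeros", {
  sc <- synthetic_scenario(n_genes = 500, n_cells_per_batch = 100, seed = 10)
  em <- simulate_multibatch(sc)$batches[[1]]
  expect_identical(thin_counts(em, keep = 1), em)
  th <- thin_counts(em, keep = 0.2, seed = 1)
  expect_equal(sum(th$values) / sum(em$values), 0.2, tolerance = 0.01)
  expect_true(all(th$values[em$values == 0] == 0))
  expect_true(all(th$values <= em$values))
})

test_that("cell down-sampling is exact, stratified and label-preserving", {
  sc <- synthetic_scenario(n_genes = 200, n_cells_per_batch = 90,
                           n_cell_types = 3, rare_fraction = 0, seed = 11)
  em <- simulate_multibatch(sc)$batches[[1]]
  full <- downsample_cells(em, n = 90, seed = 2)
  expect_setequal(full$cell_ids, em$cell_ids)
  sub <- downsample_cells(em, n = 30, seed = 2)
  expect_identical(length(sub$cell_ids), 30L)
  expect_identical(sub$cell_type,
                   em$cell_type[match(sub$cell_ids, em$cell_ids)])
  # stratified: equal take per type when n divides evenly
  strat <- downsample_cells(em, n = 30, stratify_by_type = TRUE, seed = 2)
  expect_true(all(table(strat$cell_type) == 10))
  expect_error(downsample_cells(em, n = 0), "n must")
  expect_error(downsample_cells(em, n = 91), "n must")
})

test_that("ica on a simulated batch recovers the planted signatures", {
  # cell types are mutually exclusive, so the centered activity structure is
  # near rank n_types - 1 and single components align with program
  # contrasts, not with individual gene-weight vectors; the property that
  # closes the simulator/method loop is that each planted signature is
  # captured by some component's activated-gene set
  for (s in c(12, 13, 14)) {
    sc <- synthetic_scenario(seed = s)
    sim <- simulate_multibatch(sc)
    em <- lognormalize(sim$batches[[1]])
    ps <- run_ica(em, K = estimate_component_count(em), method = "jade")
    recall <- vapply(seq_len(ncol(sc$programs)), function(k) {
      g <- sim$truth$program_genes[[k]]
      max(vapply(seq_len(ps$K), function(j)
        length(intersect(select_activated_genes(ps$source[, j]), g)) /
          length(g), 1))
    }, 1)
    expect_true(all(recall >= 0.6))
  }
})
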