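test_that("activated-gene selection is two-tailed and strictly thresholded", {
  w <- c(a = 2.5, b = -2.6, c = 3.0, d = 0.1)
  expect_identical(select_activated_genes(w), c("b", "c"))   # 2.5 excluded
  expect_identical(select_activated_genes(c(x = 1, y = -2)), character(0))
})

test_that("activated fraction of standard-normal weights matches the tail", {
  fracs <- vapply(1:5, function(s) {
    set.seed(s)
    length(select_activated_genes(stats::setNames(stats::rnorm(10000),
                                                  paste0("g", 1:10000)))) / 10000
  }, 1)
  expect_true(all(fracs > 0.008 & fracs < 0.018))  # 2*(1-pnorm(2.5)) ~ 1.24%
})

test_that("program similarity is sign-invariant and matches hand arithmetic", {
  set.seed(7)
  v <- stats::setNames(stats::rnorm(50), paste0("g", 1:50))
  v[1:4] <- c(4, -3.5, 3, 5)             # activated genes
  m <- cbind(p1 = v, p2 = -v)
  s <- program_similarity_matrix(m)
  expect_equal(unname(diag(s)), c(1, 1))
  expect_equal(s["p1", "p2"], 1)          # negation absorbed by |r|
  # 5-gene hand-written vectors: correlation over the shared activated genes
  a <- stats::setNames(c(3, 4, -3, 2.6, 0.2), paste0("h", 1:5))
  b <- stats::setNames(c(2.6, 3.1, 2.8, 2.9, 0), paste0("h", 1:5))
  u <- intersect(names(a)[abs(a) > 2.5], names(b)[abs(b) > 2.5])
  expect_length(u, 4)
  expect_equal(program_similarity_matrix(cbind(a = a, b = b))["a", "b"],
               abs(stats::cor(a[u], b[u])))
  # disjoint signatures share no activated gene -> similarity 0
  d1 <- stats::setNames(c(4, 3, 0, 0, 0, 0), paste0("q", 1:6))
  d2 <- stats::setNames(c(0, 0, 0, 0, 3, 4), paste0("q", 1:6))
  expect_equal(program_similarity_matrix(cbind(d1, d2))[1, 2], 0)
})

test_that("pam grouping finds planted cross-batch structure", {
  mk_programs <- function(seed) {
    set.seed(seed)
    base <- matrix(stats::rnorm(300 * 3, sd = 1), 300, 3)
    base[1:20, 1] <- base[1:20, 1] + 5
    base[21:40, 2] <- base[21:40, 2] + 5
    base[41:60, 3] <- base[41:60, 3] + 5
    out <- lapply(1:2, function(b) {
      s <- base + matrix(stats::rnorm(300 * 3, sd = 0.2), 300, 3)
      s <- scale(s)
      rownames(s) <- paste0("g", 1:300)
      colnames(s) <- paste0("IC", 1:3)
      structure(list(batch_id = paste0("batch", b), source = s, K = 3L,
                     method = "jade"), class = "ExpressionProgramSet")
    })
    out
  }
  hits <- 0
  for (s in 1:10) {
    bp <- group_programs(mk_programs(s))
    one_per_batch <- all(vapply(split(bp$batch_of, bp$clusters),
                                function(b) length(unique(b)) == 2, TRUE))
    if (bp$k_star == 3 && one_per_batch) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("two tight program pairs collapse to k_star = 2 medoids", {
  # synthesize 4 programs with within-pair similarity ~1, across ~0
  set.seed(21)
  g <- paste0("g", 1:200)
  a <- stats::setNames(stats::rnorm(200), g); a[1:10] <- 6
  b <- stats::setNames(stats::rnorm(200), g); b[101:110] <- 6
  m <- cbind(p1 = a, p2 = a + stats::rnorm(200, sd = 0.05),
             p3 = b, p4 = b + stats::rnorm(200, sd = 0.05))
  bp <- group_programs(m, k_range = 2:3)
  expect_identical(bp$k_star, 2L)
  expect_setequal(vapply(split(colnames(m), bp$clusters), paste,
                         "", collapse = "+"),
                  c("p1+p2", "p3+p4"))
})

test_that("identical programs trigger the degenerate-distance warning", {
  m <- matrix(stats::rnorm(100), 100, 1)[, c(1, 1, 1)]
  rownames(m) <- paste0("g", 1:100); colnames(m) <- paste0("p", 1:3)
  m[1:5, ] <- 6
  expect_warning(bp <- group_programs(m, k_range = 2), "degenerate")
  expect_identical(bp$k_star, 2L)
})

test_that("grouping is invariant to batch order and to duplicated programs", {
  set.seed(31)
  g <- paste0("g", 1:200)
  a <- stats::setNames(stats::rnorm(200), g); a[1:12] <- 6
  b <- stats::setNames(stats::rnorm(200), g); b[101:112] <- 6
  base <- cbind(p1 = a, p2 = a + stats::rnorm(200, sd = 0.05),
                p3 = b, p4 = b + stats::rnorm(200, sd = 0.05))
  bp1 <- group_programs(base, k_range = 2:3)
  bp2 <- group_programs(base[, 4:1], k_range = 2:3)
  expect_identical(bp1$k_star, bp2$k_star)
  relab <- function(cl) unname(split(seq_along(cl), cl))
  expect_setequal(
    lapply(relab(bp1$clusters), function(i) sort(colnames(base)[i])),
    lapply(relab(bp2$clusters), function(i) sort(colnames(base)[4:1][i])))
  # adding an exact duplicate keeps the structure over the originals
  dup <- cbind(base, p5 = base[, 1])
  bp3 <- group_programs(dup, k_range = 2:4)
  grp_orig <- bp3$clusters[1:4]
  expect_identical(length(unique(grp_orig)), length(unique(bp1$clusters)))
  expect_identical(bp3$clusters[["p5"]], bp3$clusters[["p1"]])
})
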