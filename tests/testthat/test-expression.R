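test_that("dense CSV round-trips bit-identically and formats are validated", {
  m <- matrix(c(3L, 0L, 1L, 7L), 2, 2,
              dimnames = list(c("G1", "G2"), c("C1", "C2")))
  em <- mk_em(m)
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression(em, path)
  back <- read_expression(path, format = "csv", batch_label = "b1")
  expect_identical(unname(back$values * 1), unname(m * 1))
  expect_identical(back$gene_ids, rownames(m))
  expect_identical(back$cell_ids, colnames(m))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,C1,C2", "G1,1,2", "G1,3,4"), dup)
  expect_error(read_expression(dup, "csv"), "duplicate gene ids")
})

test_that("matrix-market reader needs companions and consistent dimensions", {
  dirn <- withr::local_tempdir()
  mtx <- file.path(dirn, "matrix.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 2", "1 1 5", "3 2 1"), mtx)  # row 3 outside 2x2
  writeLines(c("G1", "G2"), file.path(dirn, "genes.tsv"))
  writeLines(c("C1", "C2"), file.path(dirn, "barcodes.tsv"))
  expect_error(read_expression(mtx, "mtx"))

  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 2", "1 1 5", "2 2 1"), mtx)
  em <- read_expression(mtx, "mtx", batch_label = "bx")
  expect_equal(em$values, matrix(c(5, 0, 0, 1), 2, 2,
                                 dimnames = list(c("G1", "G2"), c("C1", "C2"))))
  file.remove(file.path(dirn, "barcodes.tsv"))
  expect_error(read_expression(mtx, "mtx"), "companion")
})

test_that("lognormalize matches log2 CP10K arithmetic and flags bad cells", {
  m <- matrix(c(90, 10, 0, 5), 2, 2,
              dimnames = list(c("G1", "G2"), c("C1", "C2")))
  em <- lognormalize(mk_em(m))
  expect_true(em$normalized)
  expect_equal(em$values["G1", "C1"], log2(9001), tolerance = 1e-12)
  expect_equal(em$values["G1", "C1"], 13.1357, tolerance = 1e-4)
  expect_equal(em$values["G1", "C2"], 0)       # count 0 -> exactly 0
  # per-cell inverse transform recovers the 10k size factor
  expect_equal(unname(colSums(2^em$values - 1)), c(1e4, 1e4),
               tolerance = 1e-8)
  m0 <- m; m0[, 2] <- 0
  expect_error(lognormalize(mk_em(m0)), "C2")
})

test_that("variable-gene selection follows CV ranking and intersects batches", {
  # hand-set CVs via two-cell batches: values (a, b) give known mean/sd
  mk_batch <- function(vals) {
    m <- do.call(rbind, vals)
    rownames(m) <- paste0("G", seq_along(vals)); colnames(m) <- c("c1", "c2")
    mk_em(m, normalized = TRUE)
  }
  # CVs batch1: G1..G6 decreasing spread; batch2 reorders them
  b1 <- mk_batch(list(c(1, 9), c(2, 8), c(3, 7), c(4, 6), c(5, 5), c(4.9, 5.1)))
  b2 <- mk_batch(list(c(5, 5), c(1, 9), c(2, 8), c(4.9, 5.1), c(3, 7), c(4, 6)))
  cv <- function(x) stats::sd(x) / mean(x)
  top3 <- function(vals) {
    cvs <- vapply(vals, cv, 1)
    paste0("G", order(-cvs))[1:3]
  }
  expected <- sort(intersect(
    top3(list(c(1, 9), c(2, 8), c(3, 7), c(4, 6), c(5, 5), c(4.9, 5.1))),
    top3(list(c(5, 5), c(1, 9), c(2, 8), c(4.9, 5.1), c(3, 7), c(4, 6)))))
  expect_identical(select_variable_genes(list(b1, b2), top_k = 3), expected)
  # constant gene (CV 0) never outranks varying genes
  expect_false("G5" %in% select_variable_genes(list(b1, b2), top_k = 5))
  # saturation: top_k >= gene count returns the shared universe
  expect_identical(select_variable_genes(list(b1, b2), top_k = 100),
                   paste0("G", 1:6))
})

test_that("variable-gene selection is invariant to gene order", {
  set.seed(42)
  m <- matrix(stats::rpois(300, 5) * 1.0, 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:10)))
  em1 <- lognormalize(mk_em(m))
  perm <- sample(30)
  em2 <- lognormalize(mk_em(m[perm, ]))
  expect_identical(select_variable_genes(list(em1), 10),
                   select_variable_genes(list(em2), 10))
})

test_that("GMT files round-trip module sets", {
  sets <- list(ms1 = c("A", "B", "C"), ms2 = c("D", "E"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
})
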