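#' Construct an expression matrix
#'
#' Light container for a genes x cells expression matrix together with its
#' per-cell batch label, optional cell-type annotation, and a flag recording
#' whether the values are raw counts or log-normalized.
#'
#' @param values numeric matrix, genes in rows, cells in columns. Row names
#'   are taken as gene ids and column names as cell ids; both must be present
#'   and free of duplicates.
#' @param batch character scalar or vector of length `ncol(values)`: batch
#'   label(s) of the cells.
#' @param cell_type optional character vector of per-cell type labels.
#' @param normalized logical; `FALSE` for raw counts (default), `TRUE` for
#'   log-normalized values.
#' @return an object of class `"ExpressionMatrix"`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `batch`, `cell_type`, `normalized`.
#' @export
expression_matrix <- function(values, batch, cell_type = NULL,
                              normalized = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  gene_ids <- rownames(values)
  cell_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("values must carry gene ids as rownames and cell ids as colnames")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (length(batch) == 1L) batch <- rep(batch, ncol(values))
  if (length(batch) != ncol(values))
    stop("batch must have one label per cell")
  if (!is.null(cell_type) && length(cell_type) != ncol(values))
    stop("cell_type must have one label per cell")
  if (!normalized && any(values < 0))
    stop("counts-state matrix contains negative values")
  if (normalized && any(!is.finite(values)))
    stop("log-normalized matrix contains non-finite values")
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         batch = as.character(batch), cell_type = cell_type,
         normalized = normalized),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%s)\n",
              length(x$gene_ids), length(x$cell_ids),
              if (x$normalized) "log-normalized" else "counts"))
  cat("  batches:", paste(unique(x$batch), collapse = ", "), "\n")
  if (!is.null(x$cell_type))
    cat("  cell types:", paste(unique(x$cell_type), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Supports Matrix Market triplets with CellRanger-style companion files
#' (`genes.tsv`/`features.tsv` and `barcodes.tsv` next to the `.mtx`) and
#' dense CSV/TSV with gene ids in the first column and cell ids in the
#' header. Values are returned in counts state.
#'
#' @param path file path; for `format = "mtx"` the path of the `.mtx` file.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`; guessed from the file
#'   extension when missing.
#' @param batch_label batch id attached to every cell in the file.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("mtx", "csv", "tsv"),
                            batch_label = "batch1") {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("mtx", "csv", "tsv"))
      stop("cannot guess format from extension '", ext, "'")
    format <- ext
  }
  format <- match.arg(format)
  if (format == "mtx") {
    dirn <- dirname(path)
    gene_file <- c(file.path(dirn, "genes.tsv"), file.path(dirn, "features.tsv"))
    gene_file <- gene_file[file.exists(gene_file)][1]
    cell_file <- file.path(dirn, "barcodes.tsv")
    if (is.na(gene_file) || !file.exists(cell_file))
      stop("missing companion files: need genes.tsv (or features.tsv) and ",
           "barcodes.tsv beside ", path)
    m <- as.matrix(Matrix::readMM(path))
    genes <- utils::read.table(gene_file, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(cell_file, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("companion file lengths do not match matrix dimensions")
    dimnames(m) <- list(genes, cells)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
    rownames(m) <- genes
  }
  expression_matrix(m, batch = batch_label, normalized = FALSE)
}

#' Write an expression matrix as dense CSV
#'
#' @param em an [expression_matrix()].
#' @param path output file.
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  tab <- data.frame(gene = em$gene_ids, em$values, check.names = FALSE)
  utils::write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-normalize counts to log2 CP10K
#'
#' Scales every cell to a common size factor of 10,000 total counts and takes
#' `log2(x + 1)`: `value(g,c) = log2(count(g,c) / total(c) * 1e4 + 1)`.
#'
#' @param em counts-state [expression_matrix()]; every cell must have a
#'   positive total count.
#' @return the log-normalized `ExpressionMatrix`.
#' @export
lognormalize <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$normalized) stop("matrix is already log-normalized")
  totals <- colSums(em$values)
  if (any(totals <= 0))
    stop("cells with zero total count: ",
         paste(em$cell_ids[totals <= 0], collapse = ", "))
  v <- log2(sweep(em$values, 2, totals, "/") * 1e4 + 1)
  out <- em
  out$values <- v
  out$normalized <- TRUE
  out
}

#' Select highly variable genes shared across batches
#'
#' Ranks genes within each batch by the coefficient of variation (sd / mean)
#' of their log-normalized values, keeps the `top_k` per batch, and returns
#' the intersection across batches. Genes with zero mean get CV 0; ties at
#' the cutoff are broken by lexicographic gene id so the result is
#' deterministic. Genes absent from any batch are dropped before
#' intersection.
#'
#' @param batches list of log-normalized [expression_matrix()] objects (a
#'   counts-state matrix is log-normalized on the fly).
#' @param top_k number of genes retained per batch before intersecting
#'   (default 5000).
#' @return character vector of gene ids (sorted).
#' @export
select_variable_genes <- function(batches, top_k = 5000) {
  if (inherits(batches, "ExpressionMatrix")) batches <- list(batches)
  stopifnot(length(batches) >= 1, top_k >= 1)
  shared <- Reduce(intersect, lapply(batches, `[[`, "gene_ids"))
  if (length(shared) == 0) stop("batches share no genes")
  tops <- lapply(batches, function(em) {
    if (!em$normalized) em <- lognormalize(em)
    v <- em$values[shared, , drop = FALSE]
    mu <- rowMeans(v)
    sd_ <- apply(v, 1, stats::sd)
    cv <- ifelse(mu == 0, 0, sd_ / mu)
    ord <- order(-cv, shared)            # ties -> lexicographic gene id
    shared[ord[seq_len(min(top_k, length(shared)))]]
  })
  sel <- Reduce(intersect, tops)
  if (length(sel) == 0)
    stop("empty intersection of variable genes; per-batch sizes: ",
         paste(vapply(tops, length, 1L), collapse = ", "))
  sort(sel)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: tab-separated, one set per line
#'   (name, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors (gene ids).
#' @param path output file.
#' @param description per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "icanet") {
  if (is.null(names(sets))) names(sets) <- paste0("module_", seq_along(sets))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

# merge batches over a common gene set, preserving labels
merge_batches <- function(batches, genes = NULL) {
  if (inherits(batches, "ExpressionMatrix")) batches <- list(batches)
  shared <- Reduce(intersect, lapply(batches, `[[`, "gene_ids"))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) == 0) stop("no shared genes to merge on")
  vals <- do.call(cbind, lapply(batches, function(em)
    em$values[shared, , drop = FALSE]))
  batch <- unlist(lapply(batches, `[[`, "batch"))
  ct <- lapply(batches, `[[`, "cell_type")
  cell_type <- if (all(!vapply(ct, is.null, TRUE))) unlist(ct) else NULL
  cn <- unlist(lapply(batches, `[[`, "cell_ids"))
  if (anyDuplicated(cn)) cn <- make.unique(cn)
  colnames(vals) <- cn
  expression_matrix(vals, batch = batch, cell_type = cell_type,
                    normalized = batches[[1]]$normalized)
}
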