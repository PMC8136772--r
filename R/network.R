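#' Load a protein-protein interaction network
#'
#' Reads an edge table in the STRING `protein.links` dialect (two node
#' columns plus a `combined_score` column, space- or tab-separated, with or
#' without a header) and keeps edges with score strictly greater than
#' `score_threshold`. Edges are de-duplicated across orientations keeping
#' the maximum score; self-loops are dropped; nodes can be restricted to a
#' gene universe. An optional two-column alias table maps protein ids to
#' gene symbols before filtering.
#'
#' @param path edge file, or a data.frame with the same layout.
#' @param score_threshold minimum combined score, exclusive (default 600).
#' @param gene_universe optional character vector restricting nodes.
#' @param aliases optional data.frame (protein id, gene id) applied to both
#'   node columns.
#' @return object of class `"PPINetwork"`: list with `edges` (data.frame
#'   `from`, `to`, `combined_score`) and `nodes`.
#' @export
load_ppi <- function(path, score_threshold = 600, gene_universe = NULL,
                     aliases = NULL) {
  tab <- if (is.data.frame(path)) path else {
    first <- readLines(path, n = 1)
    header <- grepl("[A-Za-z]", strsplit(trimws(first), "[ \t]+")[[1]][3])
    utils::read.table(path, header = header, stringsAsFactors = FALSE)
  }
  if (ncol(tab) < 3) stop("unknown column layout: need node1 node2 score")
  tab <- tab[, 1:3]
  names(tab) <- c("from", "to", "combined_score")
  if (!is.numeric(tab$combined_score))
    stop("unknown column layout: third column must be the combined score")
  if (!is.null(aliases)) {
    map <- stats::setNames(as.character(aliases[[2]]), as.character(aliases[[1]]))
    hit <- function(x) ifelse(x %in% names(map), map[x], x)
    tab$from <- unname(hit(as.character(tab$from)))
    tab$to <- unname(hit(as.character(tab$to)))
  }
  tab <- tab[tab$combined_score > score_threshold, , drop = FALSE]
  tab <- tab[tab$from != tab$to, , drop = FALSE]
  if (!is.null(gene_universe))
    tab <- tab[tab$from %in% gene_universe & tab$to %in% gene_universe, ,
               drop = FALSE]
  if (nrow(tab) > 0) {
    a <- pmin(tab$from, tab$to); b <- pmax(tab$from, tab$to)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -tab$combined_score)
    tab <- data.frame(from = a[ord], to = b[ord],
                      combined_score = tab$combined_score[ord],
                      stringsAsFactors = FALSE)
    tab <- tab[!duplicated(paste(tab$from, tab$to, sep = "\r")), , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (nrow(tab) == 0)
    stop("no edge survives score > ", score_threshold,
         " within the gene universe")
  structure(list(edges = tab, nodes = sort(unique(c(tab$from, tab$to)))),
            class = "PPINetwork")
}

#' @export
print.PPINetwork <- function(x, ...) {
  cat(sprintf("PPINetwork: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Weight a PPI network with a basal program's ICA statistics
#'
#' The ICA statistic of gene g is `ICA_g = |standardized program weight|`
#' (0 for genes absent from the program). An edge (g, h) gets weight
#' `(ICA_g + ICA_h) / 2` when both endpoint statistics exceed
#' `weight_threshold_sd`, and 0 otherwise, so that only edges between
#' activated genes carry weight.
#'
#' @param ppi a [load_ppi()] network.
#' @param program named standardized gene-weight vector (a basal program).
#' @param weight_threshold_sd endpoint threshold in SD units (default 2.5).
#' @param program_id identifier stored with the result.
#' @return object of class `"WeightedNetwork"`: list with `edges`
#'   (data.frame `from`, `to`, `weight`), `ica_stat` (named vector),
#'   `program_id`. A network with no positive-weight edge triggers a
#'   warning (callers skip such programs downstream).
#' @export
weight_network <- function(ppi, program, weight_threshold_sd = 2.5,
                           program_id = "program") {
  stopifnot(inherits(ppi, "PPINetwork"))
  ica <- stats::setNames(rep(0, length(ppi$nodes)), ppi$nodes)
  shared <- intersect(names(program), ppi$nodes)
  ica[shared] <- abs(program[shared])
  a <- ica[ppi$edges$from]; b <- ica[ppi$edges$to]
  w <- ifelse(a > weight_threshold_sd & b > weight_threshold_sd,
              (a + b) / 2, 0)
  if (all(w == 0))
    warning("no edge with both endpoints above the weight threshold for ",
            program_id)
  structure(list(edges = data.frame(from = ppi$edges$from, to = ppi$edges$to,
                                    weight = unname(w),
                                    stringsAsFactors = FALSE),
                 ica_stat = ica, program_id = program_id),
            class = "WeightedNetwork")
}

#' @export
print.WeightedNetwork <- function(x, ...) {
  cat(sprintf("WeightedNetwork '%s': %d edges, %d with positive weight\n",
              x$program_id, nrow(x$edges), sum(x$edges$weight > 0)))
  invisible(x)
}

#' Detect activated modules by random-walk trapping
#'
#' Restricts the weighted network to its positive-weight subgraph and runs
#' the walktrap community algorithm for each random-walk length in
#' `walk_lengths`, cutting the merge dendrogram at maximum modularity.
#' Communities with at least `min_size` genes are kept, pooled over all walk
#' lengths, and de-duplicated by exact gene-set equality.
#'
#' @param wn a [weight_network()] result (or a list of them; modules are
#'   then pooled over programs too).
#' @param walk_lengths integer random-walk lengths (default `2:5`).
#' @param min_size minimum module size (default 4, i.e. "greater than 3").
#' @return object of class `"ModuleSet"`: list with `modules` (named list
#'   of gene-id vectors) and `provenance` (data.frame `module`,
#'   `program_id`, `walk_length`, `size`).
#' @export
detect_modules <- function(wn, walk_lengths = 2:5, min_size = 4) {
  if (inherits(wn, "WeightedNetwork")) wn <- list(wn)
  stopifnot(all(vapply(wn, inherits, TRUE, "WeightedNetwork")))
  modules <- list(); prov <- list()
  for (net in wn) {
    pos <- net$edges[net$edges$weight > 0, , drop = FALSE]
    if (nrow(pos) == 0) next
    g <- igraph::graph_from_data_frame(pos, directed = FALSE)
    for (t in walk_lengths) {
      wt <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                     steps = t)
      for (com in igraph::communities(wt)) {
        if (length(com) >= min_size) {
          modules[[length(modules) + 1L]] <- sort(com)
          prov[[length(prov) + 1L]] <-
            data.frame(program_id = net$program_id, walk_length = t,
                       size = length(com), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(modules) == 0) {
    if (all(vapply(wn, function(n) all(n$edges$weight == 0), TRUE)))
      stop("empty positive-weight subgraph")
    warning("no module of size >= ", min_size, " detected")
  }
  keys <- vapply(modules, paste, "", collapse = "\r")
  keep <- !duplicated(keys)
  modules <- modules[keep]
  prov <- if (length(prov)) do.call(rbind, prov)[keep, , drop = FALSE] else
    data.frame(program_id = character(), walk_length = integer(),
               size = integer())
  if (length(modules))
    names(modules) <- paste0("module_", seq_along(modules))
  rownames(prov) <- NULL
  if (nrow(prov)) prov <- cbind(module = names(modules), prov)
  structure(list(modules = modules, provenance = prov), class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  sz <- vapply(x$modules, length, 1L)
  cat(sprintf("ModuleSet: %d modules (sizes %s)\n", length(x$modules),
              if (length(sz)) paste(range(sz), collapse = "-") else "-"))
  invisible(x)
}
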