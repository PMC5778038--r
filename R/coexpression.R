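#' All-pairs Pearson correlation matrix
#'
#' Computes the Pearson product-moment correlation between every pair of
#' genes over the selected sample columns. Genes with zero variance over
#' those columns have no defined correlation and are removed first; their
#' IDs are recorded on the result.
#'
#' @param ds An [expression_dataset()] on the log2 scale.
#' @param columns Optional character vector of sample labels
#'   (`species_condition_rep`) to use; default all columns.
#' @return A symmetric numeric matrix of class `correlation_matrix` with
#'   gene IDs as dimnames, diagonal 1, and attribute `removed` listing the
#'   zero-variance genes that were dropped.
#' @export
pearson_matrix <- function(ds, columns = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  mat <- ds$matrix
  if (!is.null(columns)) {
    missing <- setdiff(columns, colnames(mat))
    if (length(missing)) stop("unknown sample columns: ",
                              paste(missing, collapse = ", "))
    mat <- mat[, columns, drop = FALSE]
  }
  if (ncol(mat) < 3L) stop("need at least 3 samples for correlation")
  v <- rowSums((mat - rowMeans(mat))^2)
  removed <- rownames(mat)[v == 0]
  mat <- mat[v > 0, , drop = FALSE]
  if (nrow(mat) == 0L) stop("all genes have zero variance")
  r <- stats::cor(t(mat))
  # clamp floating-point excursions outside [-1, 1]
  r[r > 1] <- 1
  r[r < -1] <- -1
  structure(r, removed = removed, class = c("correlation_matrix", "matrix"))
}

#' Rank each gene's neighbours by correlation
#'
#' For every gene g, sorts all other genes by decreasing Pearson r; the rank
#' of h in g's list is its 1-based position. Exact ties in r are broken by
#' lexicographic gene ID and receive distinct consecutive ranks, so ranking
#' is deterministic across runs and platforms.
#'
#' @param corr A `correlation_matrix` from [pearson_matrix()].
#' @param absolute Rank by `|r|` instead of signed r (negative co-regulation
#'   treated as strength).
#' @return An integer matrix R with `R[g, h]` = rank of h in g's list;
#'   diagonal `NA`.
#' @export
rank_neighbors <- function(corr, absolute = FALSE) {
  n <- nrow(corr)
  ids <- rownames(corr)
  key <- if (absolute) abs(corr) else corr
  id_ord <- xtfrm(ids)  # precomputed lexicographic sort keys
  ranks <- matrix(NA_integer_, n, n, dimnames = dimnames(corr))
  for (i in seq_len(n)) {
    r <- key[i, ]
    r[i] <- NA
    ord <- order(-r, id_ord, na.last = TRUE)[seq_len(n - 1L)]
    ranks[i, ord] <- seq_len(n - 1L)
  }
  ranks
}

#' Build an HRR-filtered co-expression network
#'
#' The highest reciprocal rank of a gene pair is
#' `HRR(g, h) = max(rank(g, h), rank(h, g))`; an edge is kept when
#' `HRR <= hrr_max`, so only mutually strong correlations survive and every
#' node has degree at most `hrr_max`.
#'
#' @param corr A `correlation_matrix` from [pearson_matrix()].
#' @param hrr_max Maximum reciprocal rank for an edge (default 3).
#' @param absolute Passed to [rank_neighbors()].
#' @return A `coexpression_network`: list with `graph` (an undirected
#'   [igraph::graph] whose vertices carry `cazy_family`, `secreted` and
#'   `de_call` attributes and whose edges carry `r` and `hrr`), `hrr_max`,
#'   and `removed` (zero-variance genes dropped upstream).
#' @export
hrr_network <- function(corr, hrr_max = 3, absolute = FALSE) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (hrr_max < 1) stop("hrr_max must be >= 1")
  ids <- rownames(corr)
  ranks <- rank_neighbors(corr, absolute = absolute)
  hrr <- pmax(ranks, t(ranks))
  keep <- which(upper.tri(hrr) & hrr <= hrr_max, arr.ind = TRUE)
  edges <- data.frame(
    from = ids[keep[, 1L]], to = ids[keep[, 2L]],
    r = corr[keep], hrr = as.integer(hrr[keep]),
    stringsAsFactors = FALSE
  )
  vertices <- data.frame(name = ids, cazy_family = NA_character_,
                         secreted = FALSE, de_call = NA_character_,
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  structure(list(graph = g, hrr_max = as.integer(hrr_max),
                 removed = attr(corr, "removed")),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d nodes, %d edges (HRR <= %d)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$hrr_max))
  n_cazy <- sum(!is.na(igraph::V(x$graph)$cazy_family))
  n_sec <- sum(igraph::V(x$graph)$secreted)
  if (n_cazy || n_sec) {
    cat(sprintf("  annotated: %d CAZy, %d secreted\n", n_cazy, n_sec))
  }
  invisible(x)
}

#' Network node identifiers
#' @param net A `coexpression_network`.
#' @return Character vector of gene IDs in the network.
#' @export
network_genes <- function(net) igraph::V(net$graph)$name

#' Attach CAZy annotation and DE calls to network nodes
#'
#' @param net A `coexpression_network`.
#' @param ann Optional [annotation_set()]; sets each node's `cazy_family`
#'   (genes absent from the annotation are treated as non-CAZy).
#' @param de Optional `de_table` from [de_test()]; sets each node's
#'   `de_call`.
#' @return The network with updated vertex attributes.
#' @export
annotate_network <- function(net, ann = NULL, de = NULL) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- net$graph
  ids <- igraph::V(g)$name
  if (!is.null(ann)) {
    stopifnot(inherits(ann, "annotation_set"))
    fam <- ann$cazy$cazy_family[match(ids, ann$cazy$gene_id)]
    g <- igraph::set_vertex_attr(g, "cazy_family", value = fam)
  }
  if (!is.null(de)) {
    stopifnot(inherits(de, "de_table"))
    g <- igraph::set_vertex_attr(g, "de_call",
                                 value = de$call[match(ids, de$gene_id)])
  }
  net$graph <- g
  net
}

#' Induced subnetwork on CAZy-annotated genes
#'
#' @param net A `coexpression_network`.
#' @param ann An [annotation_set()]; genes missing from it count as
#'   non-CAZy.
#' @return A `coexpression_network` restricted to CAZy nodes, edge
#'   attributes preserved.
#' @export
cazy_subnetwork <- function(net, ann) {
  stopifnot(inherits(net, "coexpression_network"),
            inherits(ann, "annotation_set"))
  keep <- intersect(network_genes(net), cazy_genes(ann))
  g <- igraph::induced_subgraph(net$graph, keep)
  structure(list(graph = g, hrr_max = net$hrr_max, removed = net$removed),
            class = "coexpression_network")
}

#' Summary statistics of a co-expression network
#'
#' @param net A `coexpression_network`.
#' @return A list: `nodes`, `edges`, `max_degree`, `degree_distribution`
#'   (named table of degree counts), `components` (number of connected
#'   components; 0 for the empty graph).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- net$graph
  deg <- igraph::degree(g)
  list(
    nodes = igraph::vcount(g),
    edges = igraph::ecount(g),
    max_degree = if (length(deg)) max(deg) else 0L,
    degree_distribution = table(deg),
    components = if (igraph::vcount(g))
      igraph::components(g)$no else 0L
  )
}

#' @export
summary.coexpression_network <- function(object, ...) {
  s <- network_stats(object)
  cat(sprintf(
    "coexpression_network: %d nodes, %d edges, max degree %d, %d components\n",
    s$nodes, s$edges, s$max_degree, s$components))
  invisible(s)
}

#' Plot a co-expression network
#'
#' CAZy genes are drawn in yellow, genes encoding secreted proteins in red;
#' all other genes in grey.
#'
#' @param x A `coexpression_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.coexpression_network <- function(x, ...) {
  g <- x$graph
  col <- rep("grey70", igraph::vcount(g))
  col[!is.na(igraph::V(g)$cazy_family)] <- "gold"
  col[igraph::V(g)$secreted] <- "red"
  igraph::plot.igraph(g, vertex.color = col, vertex.size = 4,
                      vertex.label = NA, ...)
  invisible(x)
}
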