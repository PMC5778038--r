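#' Node vicinity: all nodes within a path distance of a seed
#'
#' @param net A `coexpression_network`.
#' @param seed Gene ID present in the network.
#' @param depth Shortest-path distance bound (>= 0); depth 0 returns only
#'   the seed.
#' @return Character vector of gene IDs at distance `<= depth` from `seed`,
#'   including the seed.
#' @export
node_vicinity <- function(net, seed, depth = 3) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!seed %in% network_genes(net)) stop("unknown seed node: ", seed)
  if (depth < 0) stop("depth must be >= 0")
  out <- igraph::ego(net$graph, order = depth, nodes = seed)[[1L]]
  out$name
}

#' Chisel a candidate set down to a stable core
#'
#' Repeatedly and simultaneously removes every node of the candidate set
#' whose number of edges to nodes outside the set strictly exceeds its
#' number of edges inside, until no node qualifies (a fixed point, possibly
#' the empty set). Simultaneous removal makes the result independent of
#' node order.
#'
#' @param net A `coexpression_network`.
#' @param candidate Character vector of gene IDs, a subset of the network's
#'   nodes.
#' @return Character vector: the stable subset of `candidate`.
#' @export
chisel <- function(net, candidate) {
  stopifnot(inherits(net, "coexpression_network"))
  unknown <- setdiff(candidate, network_genes(net))
  if (length(unknown)) stop("candidate contains unknown nodes: ",
                            paste(unknown, collapse = ", "))
  adj <- adjacency_list(net$graph)
  chisel_adj(adj, unique(candidate))
}

# Internal chiseling on a name-keyed adjacency list.
chisel_adj <- function(adj, cand) {
  repeat {
    if (!length(cand)) return(character(0))
    deg_in <- integer(length(cand))
    deg_out <- integer(length(cand))
    for (i in seq_along(cand)) {
      nb <- adj[[cand[i]]]
      inside <- nb %in% cand
      deg_in[i] <- sum(inside)
      deg_out[i] <- length(nb) - deg_in[i]
    }
    drop <- deg_out > deg_in
    if (!any(drop)) {
      return(structure(cand, deg_in = deg_in, deg_out = deg_out))
    }
    cand <- cand[!drop]
  }
}

adjacency_list <- function(g) {
  al <- igraph::as_adj_list(g, mode = "all")
  ids <- igraph::V(g)$name
  out <- lapply(al, function(vs) ids[as.integer(vs)])
  names(out) <- ids
  out
}

# BFS vicinity on an adjacency list.
vicinity_adj <- function(adj, seed, depth) {
  visited <- seed
  frontier <- seed
  for (d in seq_len(depth)) {
    if (!length(frontier)) break
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), visited)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  visited
}

#' Partition a network with the Heuristic Cluster Chiseling Algorithm
#'
#' Each round: (1) every remaining node seeds a candidate — its vicinity at
#' `vicinity_depth` chiselled to a stable core ([chisel()]); candidates
#' whose size falls outside `[min_size, max_size]` or that lost their own
#' seed are discarded; (2) surviving candidates are scored by their
#' internal-edge fraction, `edges_inside / (edges_inside + boundary_edges)`;
#' (3) candidates are accepted greedily in order of score (descending),
#' size (descending), then smallest seed ID, skipping any that overlap an
#' accepted cluster; (4) accepted nodes are deleted from the working graph
#' and the next round begins. The procedure stops when a round accepts
#' nothing or `max_rounds` is reached; leftover nodes are reported as
#' unassigned, never force-attached.
#'
#' @param net A `coexpression_network`.
#' @param vicinity_depth Path-distance bound of the seed vicinity
#'   (default 3; use smaller values on dense graphs where a depth-3
#'   vicinity would span the whole network).
#' @param min_size,max_size Accepted cluster size bounds (defaults 3, 100).
#' @param max_rounds Cap on chisel-and-accept rounds.
#' @return A `cluster_assignment`: list with `clusters` (named list of
#'   gene-ID vectors), `scores` (internal-edge fraction per cluster),
#'   `unassigned` (gene IDs in no cluster), and the parameters used.
#' @export
hcca_cluster <- function(net, vicinity_depth = 3, min_size = 3,
                         max_size = 100, max_rounds = 100) {
  stopifnot(inherits(net, "coexpression_network"))
  if (vicinity_depth < 1) stop("vicinity_depth must be >= 1")
  if (min_size < 1 || min_size > max_size) {
    stop("need 1 <= min_size <= max_size")
  }
  if (max_rounds < 1) stop("max_rounds must be >= 1")
  if (igraph::vcount(net$graph) == 0L) stop("network is empty")

  adj <- adjacency_list(net$graph)
  remaining <- sort(names(adj))
  clusters <- list()
  scores <- numeric(0)

  for (round in seq_len(max_rounds)) {
    if (!length(remaining)) break
    work_adj <- lapply(adj[remaining], function(nb) nb[nb %in% remaining])
    cands <- list()  # key -> list(members, score, size, seed)
    for (seed in remaining) {
      vic <- vicinity_adj(work_adj, seed, vicinity_depth)
      core <- chisel_adj(work_adj, vic)
      sz <- length(core)
      if (sz < min_size || sz > max_size || !(seed %in% core)) next
      key <- paste(sort(core), collapse = "\r")
      if (!is.null(cands[[key]])) next  # same set already seeded (seeds scanned in ID order)
      internal <- sum(attr(core, "deg_in")) / 2
      boundary <- sum(attr(core, "deg_out"))
      cands[[key]] <- list(members = as.character(core),
                           score = internal / (internal + boundary),
                           size = sz, seed = seed)
    }
    if (!length(cands)) break
    sc <- vapply(cands, `[[`, numeric(1), "score")
    sz <- vapply(cands, `[[`, numeric(1), "size")
    sd_id <- vapply(cands, `[[`, character(1), "seed")
    ord <- order(-sc, -sz, sd_id)
    taken <- character(0)
    accepted_any <- FALSE
    for (i in ord) {
      m <- cands[[i]]$members
      if (any(m %in% taken)) next
      clusters[[length(clusters) + 1L]] <- m
      scores <- c(scores, cands[[i]]$score)
      taken <- c(taken, m)
      accepted_any <- TRUE
    }
    if (!accepted_any) break
    remaining <- setdiff(remaining, taken)
  }

  names(clusters) <- if (length(clusters))
    paste0("cluster_", seq_along(clusters)) else character(0)
  names(scores) <- names(clusters)
  structure(
    list(clusters = clusters, scores = scores, unassigned = remaining,
         vicinity_depth = vicinity_depth, min_size = min_size,
         max_size = max_size),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf(
    "cluster_assignment: %d clusters covering %d genes, %d unassigned\n",
    length(x$clusters), sum(sizes), length(x$unassigned)))
  if (length(sizes)) {
    cat("cluster sizes: ", paste(sizes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Cluster membership as a named vector
#'
#' @param assignment A `cluster_assignment`.
#' @return Named character vector mapping every network gene to its cluster
#'   ID or `"unassigned"`.
#' @export
cluster_membership <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  out <- c(
    unlist(lapply(names(assignment$clusters), function(cl) {
      stats::setNames(rep(cl, length(assignment$clusters[[cl]])),
                      assignment$clusters[[cl]])
    })),
    stats::setNames(rep("unassigned", length(assignment$unassigned)),
                    assignment$unassigned)
  )
  out[order(names(out))]
}

#' Per-cluster annotation summary
#'
#' Joins an annotation set onto a clustering: per cluster, the number of
#' genes, CAZy genes, the CAZy families present, and the number of secreted
#' genes.
#'
#' @param assignment A `cluster_assignment`.
#' @param ann An [annotation_set()].
#' @param species Optional species label restricting the secreted flags.
#' @return Data frame with columns `cluster_id`, `n_genes`, `n_cazy`,
#'   `families`, `n_secreted`.
#' @export
cluster_annotation_summary <- function(assignment, ann, species = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(ann, "annotation_set"))
  sec <- secreted_genes(ann, species)
  rows <- lapply(names(assignment$clusters), function(cl) {
    members <- assignment$clusters[[cl]]
    caz <- ann$cazy[ann$cazy$gene_id %in% members, , drop = FALSE]
    data.frame(
      cluster_id = cl, n_genes = length(members), n_cazy = nrow(caz),
      families = paste(sort(unique(caz$cazy_family)), collapse = ","),
      n_secreted = sum(members %in% sec), stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(cluster_id = character(0), n_genes = integer(0),
                      n_cazy = integer(0), families = character(0),
                      n_secreted = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
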