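# Shared fixtures and independent oracles used across test files.

# Wrap a named igraph as a coexpression_network with default attributes.
as_network <- function(g, hrr_max = 3L) {
  g <- igraph::set_vertex_attr(g, "cazy_family", value = NA_character_)
  g <- igraph::set_vertex_attr(g, "secreted", value = FALSE)
  g <- igraph::set_vertex_attr(g, "de_call", value = NA_character_)
  if (igraph::ecount(g) > 0 && is.null(igraph::edge_attr(g)$r)) {
    g <- igraph::set_edge_attr(g, "r", value = 0.9)
    g <- igraph::set_edge_attr(g, "hrr", value = 1L)
  }
  structure(list(graph = g, hrr_max = as.integer(hrr_max),
                 removed = character(0)),
            class = "coexpression_network")
}

graph_from_pairs <- function(pairs) {
  igraph::make_graph(pairs, directed = FALSE)
}

# Two 4-cliques joined by the path d-e-f-g.
two_clique_path_network <- function() {
  as_network(graph_from_pairs(c(
    "a","b", "a","c", "a","d", "b","c", "b","d", "c","d",
    "d","e", "e","f", "f","g",
    "g","h", "g","i", "g","j", "h","i", "h","j", "i","j")))
}

# Build a correlation_matrix object directly from a symmetric matrix.
as_corr <- function(m, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  diag(m) <- 1
  structure(m, removed = character(0),
            class = c("correlation_matrix", "matrix"))
}

# A valid random correlation matrix (correlations of random profiles).
random_corr <- function(n, seed, n_samples = 8) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * n_samples), n, n_samples)
  as_corr(stats::cor(t(x)))
}

# Independent brute-force HRR network: counts, for every ordered pair, how
# many competitors beat it (higher r, or equal r with smaller ID), with no
# shared code with rank_neighbors()/hrr_network().
brute_force_hrr_edges <- function(corr, hrr_max) {
  ids <- rownames(corr)
  n <- length(ids)
  rank_of <- function(g, h) {
    beats <- 0L
    for (j in seq_len(n)) {
      if (j == g || j == h) next
      if (corr[g, j] > corr[g, h] ||
          (corr[g, j] == corr[g, h] && ids[j] < ids[h])) {
        beats <- beats + 1L
      }
    }
    beats + 1L
  }
  edges <- character(0)
  for (g in seq_len(n - 1L)) {
    for (h in seq(g + 1L, n)) {
      if (max(rank_of(g, h), rank_of(h, g)) <= hrr_max) {
        edges <- c(edges, paste(ids[g], ids[h]))
      }
    }
  }
  sort(edges)
}

network_edge_keys <- function(net) {
  el <- igraph::as_edgelist(net$graph)
  if (nrow(el) == 0L) return(character(0))
  sort(paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L])))
}

# Brute-force Venn: classify each element by direct membership tests.
brute_force_venn <- function(sets) {
  universe <- unique(unlist(sets, use.names = FALSE))
  out <- list()
  for (el in universe) {
    sig <- paste(names(sets)[vapply(sets, function(s) el %in% s, FALSE)],
                 collapse = "&")
    out[[sig]] <- c(out[[sig]], el)
  }
  out
}

# Small expression dataset built by hand.
tiny_dataset <- function(mat, species = "Th",
                         conditions = c("cellulose", "glucose"),
                         log_scale = FALSE) {
  ns <- ncol(mat)
  nrep <- ns / length(conditions)
  samples <- data.frame(
    species = species,
    condition = rep(conditions, each = nrep),
    replicate = rep(seq_len(nrep), times = length(conditions)),
    stringsAsFactors = FALSE)
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  }
  expression_dataset(mat, samples, log_scale = log_scale)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Stochastic block model graph with equal-size communities.
sbm_graph <- function(n_comm, comm_size, p_in, p_out, seed) {
  set.seed(seed)
  P <- matrix(p_out, n_comm, n_comm)
  diag(P) <- p_in
  g <- igraph::sample_sbm(n_comm * comm_size, pref.matrix = P,
                          block.sizes = rep(comm_size, n_comm))
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n_comm * comm_size))
  g
}

sbm_truth <- function(n_comm, comm_size) {
  stats::setNames(rep(seq_len(n_comm), each = comm_size),
                  sprintf("n%03d", seq_len(n_comm * comm_size)))
}

# ARI between an HCCA assignment and planted labels; unassigned nodes are
# left as their own singleton groups.
assignment_ari <- function(assignment, truth_labels) {
  memb <- cluster_membership(assignment)[names(truth_labels)]
  un <- memb == "unassigned"
  memb[un] <- paste0("singleton_", seq_len(sum(un)))
  adjusted_rand(memb, truth_labels)
}
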