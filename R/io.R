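#' Read a simulation configuration from a YAML file
#'
#' Flat key-value YAML whose keys match the arguments of [sim_config()].
#'
#' @param path Path to the YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

#' Write an annotation set to a pair of TSV files
#'
#' @param ann An [annotation_set()].
#' @param cazy_path Path for the CAZy table (`gene_id`, `cazy_class`,
#'   `cazy_family`).
#' @param secreted_path Path for the secreted-detection table (`gene_id`,
#'   `species`, `condition`).
#' @return Invisibly, the two paths.
#' @export
write_annotation <- function(ann, cazy_path, secreted_path) {
  stopifnot(inherits(ann, "annotation_set"))
  utils::write.table(ann$cazy, cazy_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ann$secreted, secreted_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(cazy_path, secreted_path))
}

#' Read an annotation set written by [write_annotation()]
#'
#' @param cazy_path,secreted_path Paths to the two TSV files.
#' @return An [annotation_set()].
#' @export
read_annotation <- function(cazy_path, secreted_path) {
  cazy <- utils::read.delim(cazy_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  secreted <- utils::read.delim(secreted_path, stringsAsFactors = FALSE,
                                colClasses = "character")
  annotation_set(cazy, secreted)
}

#' Write a differential-expression table to TSV
#'
#' @param de A `de_table` from [de_test()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  stopifnot(inherits(de, "de_table"))
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as a TSV edge list
#'
#' Columns `gene_a`, `gene_b`, `r`, `hrr` — a SIF-style format loadable by
#' Cytoscape.
#'
#' @param net A `coexpression_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  el <- igraph::as_edgelist(net$graph)
  tab <- data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
                    r = igraph::E(net$graph)$r,
                    hrr = igraph::E(net$graph)$hrr,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network from a TSV edge list written by [write_edge_list()]
#'
#' @param path Path to the edge-list TSV.
#' @param hrr_max The HRR cutoff the network was built with (stored on the
#'   object; default the maximum hrr present).
#' @return A `coexpression_network`. Isolated nodes are not recoverable
#'   from an edge list.
#' @export
read_edge_list <- function(path, hrr_max = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "r", "hrr") %in% names(tab)))
  ids <- sort(unique(c(tab$gene_a, tab$gene_b)))
  vertices <- data.frame(name = ids, cazy_family = NA_character_,
                         secreted = FALSE, de_call = NA_character_,
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tab$gene_a, to = tab$gene_b, r = tab$r,
               hrr = as.integer(tab$hrr), stringsAsFactors = FALSE),
    directed = FALSE, vertices = vertices)
  if (is.null(hrr_max)) {
    hrr_max <- if (nrow(tab)) max(tab$hrr) else 1L
  }
  structure(list(graph = g, hrr_max = as.integer(hrr_max),
                 removed = character(0)),
            class = "coexpression_network")
}

#' Write a network to GraphML
#'
#' GraphML preserves node attributes (CAZy family, secreted flag, DE call)
#' and edge attributes (r, hrr) for import into Cytoscape.
#'
#' @param net A `coexpression_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- net$graph
  # GraphML has no NA: encode missing annotation as "none"
  fam <- igraph::V(g)$cazy_family
  dec <- igraph::V(g)$de_call
  g <- igraph::set_vertex_attr(g, "cazy_family",
                               value = ifelse(is.na(fam), "none", fam))
  g <- igraph::set_vertex_attr(g, "de_call",
                               value = ifelse(is.na(dec), "none", dec))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write node attributes to TSV
#'
#' @param net A `coexpression_network`.
#' @param path Output file path; columns `gene_id`, `cazy_family`,
#'   `secreted`, `de_call`.
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- net$graph
  tab <- data.frame(gene_id = igraph::V(g)$name,
                    cazy_family = igraph::V(g)$cazy_family,
                    secreted = igraph::V(g)$secreted,
                    de_call = igraph::V(g)$de_call,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster assignment to TSV
#'
#' One row per gene: `gene_id`, `cluster_id` (or `"unassigned"`),
#' `cluster_score`.
#'
#' @param assignment A `cluster_assignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  membership <- cluster_membership(assignment)
  score <- assignment$scores[membership]
  tab <- data.frame(gene_id = names(membership), cluster_id = membership,
                    cluster_score = ifelse(is.na(score), "", score),
                    stringsAsFactors = FALSE, row.names = NULL)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a filter report to TSV
#'
#' Two columns: `gene_id` and `status` (`kept` / `removed`).
#'
#' @param report A `filter_report` from [filter_null_genes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  tab <- data.frame(
    gene_id = c(report$kept, report$removed),
    status = c(rep("kept", length(report$kept)),
               rep("removed", length(report$removed))),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a run report to a structured text file
#'
#' Key/value lines grouped in named sections, with the per-cluster tables
#' embedded as TSV blocks — a diffable plain-text format.
#'
#' @param report A `run_report` from [build_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# run_report")
  w("[filters]")
  for (s in names(report$filters)) {
    w("%s.kept\t%d", s, report$filters[[s]]$kept)
    w("%s.removed\t%d", s, report$filters[[s]]$removed)
    w("%s.rule\t%s", s, report$filters[[s]]$rule)
  }
  w("[de]")
  for (s in names(report$de)) {
    for (k in names(report$de[[s]])) {
      w("%s.%s\t%d", s, k, report$de[[s]][[k]])
    }
  }
  w("[presence_venn]")
  for (cc in names(report$presence_venn)) {
    for (reg in names(report$presence_venn[[cc]])) {
      w("%s.%s\t%d", cc, reg, report$presence_venn[[cc]][[reg]])
    }
  }
  w("[networks]")
  for (s in names(report$networks)) {
    for (k in names(report$networks[[s]])) {
      w("%s.%s\t%d", s, k, report$networks[[s]][[k]])
    }
  }
  w("[clusters]")
  for (s in names(report$clusters)) {
    cl <- report$clusters[[s]]
    w("%s.n_clusters\t%d", s, cl$n_clusters)
    w("%s.genes_clustered\t%d", s, cl$genes_clustered)
    w("%s.unassigned\t%d", s, cl$unassigned)
    if (nrow(cl$table)) {
      w("%s.table.header\t%s", s, paste(names(cl$table), collapse = "\t"))
      for (i in seq_len(nrow(cl$table))) {
        w("%s.table.row\t%s", s,
          paste(unlist(cl$table[i, ]), collapse = "\t"))
      }
    }
  }
  w("[secreted]")
  for (s in names(report$secreted)) {
    w("%s.count\t%d", s, report$secreted[[s]])
  }
  invisible(path)
}
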