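#' Flag network nodes whose proteins were detected in the secretome
#'
#' Sets the `secreted` vertex attribute to `TRUE` for every gene to which at
#' least one detected protein maps for the given species, in any condition.
#' Proteome rows without a gene ID, or mapping to genes absent from the
#' network, are ignored and counted.
#'
#' @param net A `coexpression_network`.
#' @param prot Proteome table: data.frame with columns `protein_id`,
#'   `gene_id`, `species`, `condition`, `detected`.
#' @param species Species label selecting the proteome rows to use.
#' @return The network with updated `secreted` flags; the number of
#'   detections that could not be mapped is stored in the network's
#'   `unmapped` field.
#' @export
flag_secreted_nodes <- function(net, prot, species) {
  stopifnot(inherits(net, "coexpression_network"))
  check_proteome(prot)
  rows <- prot[prot$species == species & prot$detected, , drop = FALSE]
  ids <- network_genes(net)
  mappable <- !is.na(rows$gene_id) & rows$gene_id != "" &
    rows$gene_id %in% ids
  net$graph <- igraph::set_vertex_attr(
    net$graph, "secreted", value = ids %in% rows$gene_id[mappable])
  net$unmapped <- sum(!mappable)
  net
}

check_proteome <- function(prot) {
  need <- c("protein_id", "gene_id", "species", "condition", "detected")
  if (!is.data.frame(prot) || !all(need %in% names(prot))) {
    stop("proteome table needs columns: ", paste(need, collapse = ", "))
  }
  key <- paste(prot$protein_id, prot$species, prot$condition)
  if (anyDuplicated(key)) {
    stop("duplicate (protein, species, condition) row: ",
         key[duplicated(key)][1L])
  }
  invisible(prot)
}

#' Venn comparison of detected proteins across species
#'
#' @param prot Proteome table (see [flag_secreted_nodes()]).
#' @return Venn regions over per-species detected-protein sets, as from
#'   [venn()].
#' @export
protein_venn <- function(prot) {
  check_proteome(prot)
  det <- prot[prot$detected, , drop = FALSE]
  species <- sort(unique(det$species))
  if (length(species) < 2L) {
    stop("protein_venn needs proteins detected in at least 2 species")
  }
  sets <- lapply(species, function(s)
    unique(det$protein_id[det$species == s]))
  names(sets) <- species
  venn(sets)
}

#' CAZy class and family distribution of a gene set
#'
#' @param gene_ids Character vector of gene IDs.
#' @param ann An [annotation_set()].
#' @return A list: `classes` (named counts per CAZy class), `families`
#'   (named counts per family), `none` (genes without CAZy annotation),
#'   `total`. Class counts equal the sum of their family counts and
#'   `sum(classes) + none == total`.
#' @export
family_distribution <- function(gene_ids, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  gene_ids <- unique(gene_ids)
  caz <- ann$cazy[ann$cazy$gene_id %in% gene_ids, , drop = FALSE]
  fam <- table(caz$cazy_family)
  cls <- table(caz$cazy_class)
  list(
    classes = stats::setNames(as.integer(cls), names(cls)),
    families = stats::setNames(as.integer(fam), names(fam)),
    none = length(gene_ids) - nrow(caz),
    total = length(gene_ids)
  )
}

#' Assemble the run report
#'
#' Collects every stage of a per-species analysis into one machine-readable
#' report: noise-gene filtering, DE summaries, presence-set Venn regions,
#' network statistics for the full and CAZy-filtered networks, cluster
#' composition, and secreted-gene counts. All inputs must share a gene
#' universe; the same inputs always yield an identical report.
#'
#' @param species_results Named list (one element per species), each a list
#'   with `filter` (a `filter_report`), `de` (a `de_table`), `network`,
#'   `cazy_network` (both `coexpression_network`), `clusters` (a
#'   `cluster_assignment`) and `presence` (that species' slice of
#'   [presence_sets()]).
#' @param ann An [annotation_set()] covering the shared gene universe.
#' @param prot Proteome table (see [flag_secreted_nodes()]).
#' @return A `run_report` list with sections `filters`, `de`,
#'   `presence_venn`, `networks`, `clusters`, `secreted`.
#' @export
build_report <- function(species_results, ann, prot) {
  stopifnot(is.list(species_results), length(species_results) >= 1L,
            !is.null(names(species_results)),
            inherits(ann, "annotation_set"))
  check_proteome(prot)

  universe <- sort(unique(unlist(lapply(species_results, function(r)
    c(r$filter$kept, r$filter$removed)), use.names = FALSE)))
  offenders <- character(0)
  for (s in names(species_results)) {
    r <- species_results[[s]]
    offenders <- c(offenders,
                   setdiff(c(r$filter$kept, r$filter$removed), universe),
                   setdiff(r$de$gene_id, universe),
                   setdiff(network_genes(r$network), universe))
  }
  offenders <- c(offenders, setdiff(cazy_genes(ann), universe))
  mapped <- prot$gene_id[!is.na(prot$gene_id) & prot$gene_id != ""]
  offenders <- unique(c(offenders, setdiff(mapped, universe)))
  if (length(offenders)) {
    stop("inconsistent gene universes; offending IDs: ",
         paste(utils::head(offenders, 10L), collapse = ", "))
  }

  filters <- lapply(species_results, function(r)
    list(kept = length(r$filter$kept), removed = length(r$filter$removed),
         rule = r$filter$rule))

  de <- lapply(species_results, function(r) as.list(de_summary(r$de)))

  conds <- unique(unlist(lapply(species_results, function(r)
    sub("^.*_", "", names(r$presence))), use.names = FALSE))
  presence_venn <- list()
  if (length(species_results) >= 2L) {
    for (cc in conds) {
      sets <- lapply(species_results, function(r)
        r$presence[[grep(paste0("_", cc, "$"), names(r$presence))]])
      presence_venn[[cc]] <- lapply(venn(sets), length)
    }
  }

  networks <- lapply(species_results, function(r) {
    full <- network_stats(r$network)
    caz <- network_stats(r$cazy_network)
    list(nodes = full$nodes, edges = full$edges,
         cazy_nodes = caz$nodes, cazy_edges = caz$edges)
  })

  clusters <- lapply(names(species_results), function(s) {
    r <- species_results[[s]]
    tab <- cluster_annotation_summary(r$clusters, ann, species = s)
    list(n_clusters = length(r$clusters$clusters),
         genes_clustered = sum(lengths(r$clusters$clusters)),
         unassigned = length(r$clusters$unassigned),
         table = tab)
  })
  names(clusters) <- names(species_results)

  secreted <- lapply(names(species_results), function(s) {
    r <- species_results[[s]]
    sum(igraph::V(r$network$graph)$secreted)
  })
  names(secreted) <- names(species_results)

  structure(
    list(filters = filters, de = de, presence_venn = presence_venn,
         networks = networks, clusters = clusters, secreted = secreted),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  for (s in names(x$filters)) {
    cat(sprintf(
      " %s: kept %d / removed %d; network %d nodes / %d edges (CAZy %d/%d); %d clusters (%d genes, %d unassigned); %d secreted\n",
      s, x$filters[[s]]$kept, x$filters[[s]]$removed,
      x$networks[[s]]$nodes, x$networks[[s]]$edges,
      x$networks[[s]]$cazy_nodes, x$networks[[s]]$cazy_edges,
      x$clusters[[s]]$n_clusters, x$clusters[[s]]$genes_clustered,
      x$clusters[[s]]$unassigned, x$secreted[[s]]))
  }
  invisible(x)
}

#' Audit a run report against the artifacts it summarises
#'
#' Recomputes every count in the report from the artifacts and compares.
#' Used as the round-trip consistency check of a pipeline run.
#'
#' @param report A `run_report` from [build_report()].
#' @param species_results,ann,prot The same inputs given to
#'   [build_report()].
#' @return `TRUE` when every count matches; otherwise a character vector of
#'   mismatch descriptions.
#' @export
audit_report <- function(report, species_results, ann, prot) {
  fresh <- build_report(species_results, ann, prot)
  mism <- character(0)
  if (!identical(fresh, report)) {
    for (sec in names(report)) {
      if (!identical(fresh[[sec]], report[[sec]])) {
        mism <- c(mism, sprintf("section '%s' differs on recomputation", sec))
      }
    }
  }
  for (s in names(species_results)) {
    r <- species_results[[s]]
    sizes <- lengths(r$clusters$clusters)
    if (sum(sizes) + length(r$clusters$unassigned) !=
        report$networks[[s]]$nodes) {
      mism <- c(mism, sprintf(
        "%s: cluster sizes + unassigned != network nodes", s))
    }
    if (report$secreted[[s]] != sum(igraph::V(r$network$graph)$secreted)) {
      mism <- c(mism, sprintf("%s: secreted count mismatch", s))
    }
    if (report$filters[[s]]$kept + report$filters[[s]]$removed !=
        length(c(r$filter$kept, r$filter$removed))) {
      mism <- c(mism, sprintf("%s: filter counts mismatch", s))
    }
    if (sum(unlist(report$de[[s]])) != nrow(r$de)) {
      mism <- c(mism, sprintf("%s: DE counts do not sum to gene count", s))
    }
  }
  if (length(mism)) mism else TRUE
}
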