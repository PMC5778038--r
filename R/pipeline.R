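#' Run the full co-expression analysis on synthetic data
#'
#' Chains every stage for a multi-species synthetic study: per species,
#' generate expression data ([generate_dataset()]), exclude noise genes
#' ([filter_null_genes()]), compute presence sets, log2-normalize, call
#' differential expression ([de_test()]), build the HRR co-expression
#' network ([pearson_matrix()], [hrr_network()]), extract the CAZy
#' subnetwork, flag secreted genes, cluster with HCCA ([hcca_cluster()]),
#' and assemble the audit-ready report ([build_report()]).
#'
#' Species are simulated as independent datasets sharing the gene universe
#' and CAZy annotation; per-species seeds are derived from `config$seed` so
#' the whole run is reproducible.
#'
#' @param config A [sim_config()]; its `species` and `seed` fields are
#'   overridden per species.
#' @param species Character vector of species labels (default Th, Ta, Tr).
#' @param max_zero_fraction Passed to [filter_null_genes()].
#' @param fc_threshold,alpha Passed to [de_test()].
#' @param hrr_max Passed to [hrr_network()].
#' @param vicinity_depth,min_size,max_size Passed to [hcca_cluster()].
#' @return A `pipeline_run`: list with `species` (per-species stage
#'   results), `truth` (per-species planted truth), `annotation`,
#'   `proteome` and `report`.
#' @export
run_pipeline <- function(config, species = c("Th", "Ta", "Tr"),
                         max_zero_fraction = 0.5, fc_threshold = 1.5,
                         alpha = 0.05, hrr_max = 3, vicinity_depth = 3,
                         min_size = 3, max_size = 100) {
  stopifnot(inherits(config, "sim_config"), length(species) >= 1L)
  base_seed <- if (is.null(config$seed)) 0L else config$seed

  ann <- NULL
  proteomes <- list()
  results <- list()
  truths <- list()

  for (i in seq_along(species)) {
    s <- species[i]
    cfg <- config
    cfg$species <- s
    cfg$seed <- (base_seed + (i - 1L) * 1009L) %% .Machine$integer.max
    sim <- generate_dataset(cfg)
    truths[[s]] <- sim$truth
    ann_s <- generate_annotation(cfg, sim$truth)
    if (is.null(ann)) ann <- ann_s  # gene -> CAZy is genome-level: shared
    proteomes[[s]] <- proteome_from_annotation(ann_s)

    filt <- filter_null_genes(sim$dataset, max_zero_fraction)
    presence <- presence_sets(filt$dataset)
    logds <- log2_normalize(filt$dataset)
    de <- de_test(logds, contrast = cfg$conditions[1:2],
                  fc_threshold = fc_threshold, alpha = alpha)
    corr <- pearson_matrix(logds)
    net <- hrr_network(corr, hrr_max = hrr_max)
    net <- annotate_network(net, ann = ann, de = de)
    results[[s]] <- list(filter = filt$report, presence = presence,
                         de = de, network = net)
  }

  prot <- do.call(rbind, unname(proteomes))
  rownames(prot) <- NULL

  for (s in species) {
    results[[s]]$network <- flag_secreted_nodes(results[[s]]$network, prot, s)
    results[[s]]$cazy_network <- cazy_subnetwork(results[[s]]$network, ann)
    results[[s]]$clusters <- hcca_cluster(
      results[[s]]$network, vicinity_depth = vicinity_depth,
      min_size = min_size, max_size = max_size)
  }

  report <- build_report(results, ann, prot)
  structure(
    list(species = results, truth = truths, annotation = ann,
         proteome = prot, report = report),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run over %d species\n", length(x$species)))
  print(x$report)
  invisible(x)
}

#' Fraction of each planted module recovered inside a single cluster
#'
#' For every planted module, finds the cluster containing most of its
#' members (unassigned genes count as their own singleton groups) and
#' reports the covered fraction.
#'
#' @param assignment A `cluster_assignment`.
#' @param truth A `planted_truth` from [generate_dataset()].
#' @return Named numeric vector, one fraction per planted module.
#' @export
module_recovery <- function(assignment, truth) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(truth, "planted_truth"))
  membership <- cluster_membership(assignment)
  vapply(truth$module_members, function(members) {
    cl <- membership[intersect(members, names(membership))]
    cl <- cl[cl != "unassigned"]
    if (!length(cl)) return(0)
    max(table(cl)) / length(members)
  }, numeric(1))
}
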