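#' Simulation configuration
#'
#' Parameters for the synthetic expression generator. The generator emulates
#' the design of a fungal carbon-source fermentation experiment: one species
#' grown under two conditions (cellulose vs glucose) in biological
#' triplicates, with co-expression modules driven by shared latent factors,
#' planted fold-change effects between conditions, and excess zeros.
#'
#' On the log2 scale, gene \eqn{g} in sample \eqn{s} is
#' \deqn{y_{gs} = \mu_g + a\, z_{m(g),s} + \delta_g\, 1[s \in cond_2] +
#'   \varepsilon_{gs}}
#' with baseline \eqn{\mu_g \sim U(2, 10)}, one standard-normal latent factor
#' \eqn{z_m} per module and sample, loading \eqn{a} =
#' `module_corr_strength`, planted effect \eqn{\delta_g = \pm}`de_log2fc`
#' for differential genes (0 otherwise) and
#' \eqn{\varepsilon \sim N(0, }`noise_sd`\eqn{^2)}. Linear-scale values are
#' \eqn{2^{y}} and are then zeroed independently with probability
#' `dropout_prob`.
#'
#' @param n_genes Number of genes.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per module; a scalar or a vector of length
#'   `n_modules`.
#' @param n_conditions Number of conditions (default 2: cellulose, glucose).
#' @param n_replicates Biological replicates per condition (default 3).
#' @param module_corr_strength Latent-factor loading `a` in `[0, 1)`.
#' @param de_fraction Fraction of genes with a planted fold-change effect.
#' @param de_log2fc Magnitude of the planted effect, log2 units.
#' @param noise_sd Residual standard deviation, log2 units (> 0).
#' @param dropout_prob Probability that an observed linear value is zeroed.
#' @param cazy_fraction Fraction of genes labelled as CAZymes.
#' @param secreted_fraction Fraction of CAZy genes flagged as secreted.
#' @param species Species label used in sample descriptors.
#' @param conditions Condition labels; the planted effect applies to the
#'   second one.
#' @param baseline_range Range of the uniform baseline mean, log2 units.
#' @param seed Integer RNG seed (`NULL` leaves the RNG state alone).
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 1000, n_modules = 5, module_size = 10,
                       n_conditions = 2, n_replicates = 3,
                       module_corr_strength = 0.9, de_fraction = 0.1,
                       de_log2fc = 2, noise_sd = 0.3, dropout_prob = 0.01,
                       cazy_fraction = 0.15, secreted_fraction = 0.3,
                       species = "Th",
                       conditions = c("cellulose", "glucose"),
                       baseline_range = c(2, 10), seed = NULL) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    n_conditions = as.integer(n_conditions),
    n_replicates = as.integer(n_replicates),
    module_corr_strength = module_corr_strength,
    de_fraction = de_fraction, de_log2fc = de_log2fc, noise_sd = noise_sd,
    dropout_prob = dropout_prob, cazy_fraction = cazy_fraction,
    secreted_fraction = secreted_fraction, species = species,
    conditions = conditions, baseline_range = baseline_range,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) stop("config error: n_genes must be >= 1")
  if (cfg$n_modules < 0) stop("config error: n_modules must be >= 0")
  sizes <- module_sizes(cfg)
  if (cfg$n_modules > 0 && sum(sizes) > cfg$n_genes) {
    stop(sprintf(
      "config error: total module size %d exceeds n_genes %d",
      sum(sizes), cfg$n_genes))
  }
  if (cfg$n_modules > 0 &&
      !(length(cfg$module_size) %in% c(1L, cfg$n_modules))) {
    stop("config error: module_size must be scalar or length n_modules")
  }
  if (cfg$n_conditions < 1 || cfg$n_conditions > length(cfg$conditions)) {
    stop("config error: n_conditions must be in [1, length(conditions)]")
  }
  if (cfg$n_replicates < 1) stop("config error: n_replicates must be >= 1")
  for (p in c("de_fraction", "dropout_prob", "cazy_fraction",
              "secreted_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(sprintf("config error: %s must be in [0, 1]", p))
    }
  }
  if (cfg$module_corr_strength < 0 || cfg$module_corr_strength >= 1) {
    stop("config error: module_corr_strength must be in [0, 1)")
  }
  if (cfg$noise_sd <= 0) stop("config error: noise_sd must be > 0")
  if (cfg$de_log2fc < 0) stop("config error: de_log2fc must be >= 0")
  invisible(cfg)
}

module_sizes <- function(cfg) {
  if (cfg$n_modules == 0L) return(integer(0))
  if (length(cfg$module_size) == 1L) {
    rep(cfg$module_size, cfg$n_modules)
  } else {
    cfg$module_size
  }
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Draws one dataset from the generative model described in
#' [sim_config()]. Module members occupy the leading rows in consecutive
#' blocks; planted differential genes are drawn preferentially from genes
#' outside modules so that the co-expression and fold-change signals stay
#' separable. The same configuration and seed always reproduce the same
#' output bit for bit.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset` (an [expression_dataset()] on the
#'   linear scale) and `truth` (a `planted_truth` list: `module_members`,
#'   `de_genes_up`, `de_genes_down`; up/down refer to the second condition).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  conds <- config$conditions[seq_len(config$n_conditions)]
  samples <- data.frame(
    species = config$species,
    condition = rep(conds, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), times = length(conds)),
    stringsAsFactors = FALSE
  )
  ns <- nrow(samples)

  sizes <- module_sizes(config)
  module_of <- rep(NA_integer_, n)
  if (length(sizes)) {
    module_of[seq_len(sum(sizes))] <- rep(seq_along(sizes), times = sizes)
  }
  module_members <- lapply(seq_along(sizes),
                           function(m) gene_ids[which(module_of == m)])
  names(module_members) <- sprintf("module_%d", seq_along(sizes))

  # plant DE effects, preferring genes outside modules
  n_de <- round(config$de_fraction * n)
  free <- which(is.na(module_of))
  de_idx <- if (n_de <= length(free)) {
    sort(sample(free, n_de))
  } else {
    sort(c(free, sample(which(!is.na(module_of)), n_de - length(free))))
  }
  delta <- numeric(n)
  n_up <- ceiling(n_de / 2)
  up_idx <- de_idx[seq_len(n_up)]
  down_idx <- setdiff(de_idx, up_idx)
  delta[up_idx] <- config$de_log2fc
  delta[down_idx] <- -config$de_log2fc

  mu <- stats::runif(n, config$baseline_range[1], config$baseline_range[2])
  y <- matrix(stats::rnorm(n * ns, 0, config$noise_sd), n, ns) + mu
  if (length(sizes)) {
    z <- matrix(stats::rnorm(length(sizes) * ns), length(sizes), ns)
    in_mod <- !is.na(module_of)
    y[in_mod, ] <- y[in_mod, , drop = FALSE] +
      config$module_corr_strength * z[module_of[in_mod], , drop = FALSE]
  }
  if (config$n_conditions >= 2 && length(de_idx)) {
    cond2 <- samples$condition == conds[2]
    y[de_idx, cond2] <- y[de_idx, cond2, drop = FALSE] + delta[de_idx]
  }

  x <- 2^y
  if (config$dropout_prob > 0) {
    x[stats::runif(n * ns) < config$dropout_prob] <- 0
  }
  rownames(x) <- gene_ids

  truth <- structure(
    list(module_members = module_members,
         de_genes_up = gene_ids[up_idx],
         de_genes_down = gene_ids[down_idx]),
    class = "planted_truth"
  )
  list(dataset = expression_dataset(x, samples), truth = truth)
}

#' Generate a synthetic CAZy annotation and secretome overlay
#'
#' Assigns CAZy class/family labels to a fraction of genes, preferentially
#' covering the planted modules so that CAZy-subnetwork extraction has
#' structure to find, and flags a fraction of CAZy genes as secreted
#' (detected in the exoproteome) in specific species-by-condition cells.
#' Classes are drawn from GH, AA, GT, CBM and CE with glycoside hydrolases
#' most frequent, as in fungal lignocellulolytic secretomes.
#'
#' @param config A [sim_config()].
#' @param truth The `planted_truth` returned by [generate_dataset()] for the
#'   same config.
#' @return An `annotation_set`: list with `cazy` (data.frame `gene_id`,
#'   `cazy_class`, `cazy_family`) and `secreted` (data.frame `gene_id`,
#'   `species`, `condition`).
#' @export
generate_annotation <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "planted_truth"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)

  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  n_cazy <- round(config$cazy_fraction * config$n_genes)
  module_genes <- unlist(truth$module_members, use.names = FALSE)
  pool <- c(module_genes, setdiff(gene_ids, module_genes))
  cazy_ids <- pool[seq_len(n_cazy)]

  classes <- c("GH", "AA", "GT", "CBM", "CE")
  class_probs <- c(0.45, 0.2, 0.15, 0.1, 0.1)
  cazy_class <- sample(classes, n_cazy, replace = TRUE, prob = class_probs)
  cazy_family <- paste0(cazy_class, sample(1:99, n_cazy, replace = TRUE))
  cazy <- data.frame(gene_id = cazy_ids, cazy_class = cazy_class,
                     cazy_family = cazy_family, stringsAsFactors = FALSE)

  n_sec <- round(config$secreted_fraction * n_cazy)
  sec_ids <- if (n_sec > 0) sample(cazy_ids, n_sec) else character(0)
  conds <- config$conditions[seq_len(config$n_conditions)]
  secreted <- if (length(sec_ids)) {
    rows <- lapply(sec_ids, function(g) {
      in_cond <- stats::runif(length(conds)) < 0.7
      if (!any(in_cond)) in_cond[sample(length(conds), 1L)] <- TRUE
      data.frame(gene_id = g, species = config$species,
                 condition = conds[in_cond], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    data.frame(gene_id = character(0), species = character(0),
               condition = character(0), stringsAsFactors = FALSE)
  }
  annotation_set(cazy, secreted)
}

#' Construct an annotation set
#'
#' @param cazy Data frame with columns `gene_id`, `cazy_class`,
#'   `cazy_family`; the family string must start with its class (e.g. family
#'   "GH18" for class "GH").
#' @param secreted Data frame with columns `gene_id`, `species`,
#'   `condition`: one row per cell in which the gene's protein was detected.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(cazy, secreted = NULL) {
  stopifnot(is.data.frame(cazy),
            all(c("gene_id", "cazy_class", "cazy_family") %in% names(cazy)))
  if (anyDuplicated(cazy$gene_id)) stop("duplicate gene_id in CAZy table")
  bad <- !startsWith(cazy$cazy_family, cazy$cazy_class)
  if (any(bad)) {
    stop("cazy_family must carry its class prefix; offending gene: ",
         cazy$gene_id[bad][1L])
  }
  if (is.null(secreted)) {
    secreted <- data.frame(gene_id = character(0), species = character(0),
                           condition = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "species", "condition") %in% names(secreted)))
  structure(list(cazy = cazy, secreted = secreted), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d CAZy genes (%s), %d secreted-detection rows\n",
              nrow(x$cazy),
              paste(names(sort(table(x$cazy$cazy_class), decreasing = TRUE)),
                    collapse = "/"),
              nrow(x$secreted)))
  invisible(x)
}

#' CAZy gene identifiers of an annotation set
#' @param ann An `annotation_set`.
#' @return Character vector of CAZy-annotated gene IDs.
#' @export
cazy_genes <- function(ann) ann$cazy$gene_id

#' Secreted gene identifiers for a species
#' @param ann An `annotation_set`.
#' @param species Species label; `NULL` for all species.
#' @return Character vector of gene IDs flagged secreted (any condition).
#' @export
secreted_genes <- function(ann, species = NULL) {
  s <- ann$secreted
  if (!is.null(species)) s <- s[s$species %in% species, , drop = FALSE]
  unique(s$gene_id)
}

#' Derive a proteome detection table from an annotation set
#'
#' Expands the secreted flags of an annotation set into the long proteome
#' format used for secretome integration: one row per
#' (protein, species, condition) detection, with a synthetic protein ID per
#' gene.
#'
#' @param ann An `annotation_set`.
#' @return A data.frame with columns `protein_id`, `gene_id`, `species`,
#'   `condition`, `detected`.
#' @export
proteome_from_annotation <- function(ann) {
  s <- ann$secreted
  data.frame(
    protein_id = if (nrow(s)) paste0("prot_", s$gene_id) else character(0),
    gene_id = s$gene_id, species = s$species, condition = s$condition,
    detected = rep(TRUE, nrow(s)), stringsAsFactors = FALSE
  )
}
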