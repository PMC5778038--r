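test_that("pearson correlations match hand-computed values", {
  mat <- rbind(x = c(1, 2, 3), y = c(2, 4, 6), z = c(6, 4, 2))
  ds <- tiny_dataset(mat, conditions = "cellulose")
  ds$log_scale <- TRUE
  r <- pearson_matrix(ds)
  expect_equal(r["x", "y"], 1)
  expect_equal(r["x", "z"], -1)
  expect_true(isSymmetric(unclass(r)))

  mat4 <- rbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))
  ds4 <- tiny_dataset(mat4, conditions = c("cellulose", "glucose"))
  ds4$log_scale <- TRUE
  expect_equal(pearson_matrix(ds4)["x", "y"], 0.8)
})

test_that("zero-variance genes are removed and reported", {
  mat <- rbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2), c = c(4, 3, 2, 1))
  ds <- tiny_dataset(mat, conditions = c("cellulose", "glucose"))
  ds$log_scale <- TRUE
  r <- pearson_matrix(ds)
  expect_equal(rownames(r), c("a", "c"))
  expect_equal(attr(r, "removed"), "b")
  flat <- tiny_dataset(matrix(1, 2, 4, dimnames = list(c("a", "b"), NULL)),
                       conditions = c("cellulose", "glucose"))
  flat$log_scale <- TRUE
  expect_error(pearson_matrix(flat), "zero variance")
  expect_error(pearson_matrix(ds, columns = colnames(ds$matrix)[1:2]),
               "3 samples")
})

test_that("neighbor ranks order by r with deterministic ID tie-break", {
  m <- as_corr(rbind(c(1, 0.9, 0.2),
                     c(0.9, 1, 0.5),
                     c(0.2, 0.5, 1)), ids = c("A", "B", "C"))
  rk <- rank_neighbors(m)
  expect_equal(rk["A", "B"], 1L)
  expect_equal(rk["A", "C"], 2L)
  expect_true(is.na(rk["A", "A"]))

  # exact tie: r(A,B) == r(A,C) -> B before C by ID
  mt <- as_corr(rbind(c(1, 0.7, 0.7),
                      c(0.7, 1, 0.1),
                      c(0.7, 0.1, 1)), ids = c("A", "C", "B"))
  rkt <- rank_neighbors(mt)
  expect_equal(rkt["A", "B"], 1L)
  expect_equal(rkt["A", "C"], 2L)
})

test_that("hrr_network reproduces the hand-enumerated 4-gene example", {
  m <- as_corr(rbind(
    c(1,   0.9,  0.8,  0.1),
    c(0.9, 1,    0.85, 0.2),
    c(0.8, 0.85, 1,    0.3),
    c(0.1, 0.2,  0.3,  1)), ids = c("A", "B", "C", "D"))
  net2 <- hrr_network(m, hrr_max = 2)
  expect_setequal(network_edge_keys(net2), c("A B", "A C", "B C"))
  eid <- igraph::get_edge_ids(net2$graph, c("A", "B"))
  expect_equal(igraph::E(net2$graph)$hrr[eid], 1L)
  net1 <- hrr_network(m, hrr_max = 1)
  expect_setequal(network_edge_keys(net1), "A B")
  # hrr_max >= n-1: every pair becomes an edge
  net_all <- hrr_network(m, hrr_max = 3)
  expect_equal(igraph::ecount(net_all$graph), choose(4, 2))
})

test_that("hrr_network matches the brute-force oracle on random matrices", {
  for (s in 1:10) {
    n <- sample(5:30, 1)
    k <- sample(1:4, 1)
    corr <- random_corr(n, seed = s)
    expect_identical(network_edge_keys(hrr_network(corr, k)),
                     brute_force_hrr_edges(corr, k))
  }
})

test_that("degree is bounded by hrr_max and edges grow monotonically", {
  for (s in 1:5) {
    corr <- random_corr(25, seed = 100 + s)
    prev <- character(0)
    for (k in 1:5) {
      net <- hrr_network(corr, k)
      deg <- igraph::degree(net$graph)
      expect_lte(max(deg), k)
      keys <- network_edge_keys(net)
      expect_true(all(prev %in% keys))
      expect_lte(length(keys), k * 25 / 2)
      prev <- keys
    }
  }
})

test_that("permuting gene order yields the same edge set and attributes", {
  corr <- random_corr(20, seed = 77)
  perm <- sample(20)
  corr_p <- as_corr(unclass(corr)[perm, perm], ids = rownames(corr)[perm])
  a <- hrr_network(corr, 3)
  b <- hrr_network(corr_p, 3)
  expect_identical(network_edge_keys(a), network_edge_keys(b))
  attrs <- function(net) {
    el <- igraph::as_edgelist(net$graph)
    key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    df <- data.frame(key, r = igraph::E(net$graph)$r,
                     hrr = igraph::E(net$graph)$hrr)
    df[order(df$key), ]
  }
  expect_equal(attrs(a)$r, attrs(b)$r, tolerance = 1e-12)
  expect_identical(attrs(a)$hrr, attrs(b)$hrr)
})

test_that("most HRR edges stay within planted modules", {
  frac <- vapply(1:3, function(s) {
    cfg <- sim_config(n_genes = 50, n_modules = 5, module_size = 10,
                      module_corr_strength = 0.9, noise_sd = 0.3,
                      de_fraction = 0, dropout_prob = 0, seed = s)
    sim <- generate_dataset(cfg)
    net <- hrr_network(pearson_matrix(log2_normalize(sim$dataset)), 3)
    el <- igraph::as_edgelist(net$graph)
    mod <- rep(NA_integer_, 50)
    names(mod) <- genes(sim$dataset)
    for (m in seq_along(sim$truth$module_members)) {
      mod[sim$truth$module_members[[m]]] <- m
    }
    mean(mod[el[, 1]] == mod[el[, 2]])
  }, numeric(1))
  expect_gte(mean(frac), 0.8)
})

test_that("cazy_subnetwork induces the annotated subgraph", {
  net <- as_network(graph_from_pairs(c("a", "b", "b", "c", "c", "d", "d", "e")))
  ann <- annotation_set(data.frame(
    gene_id = c("a", "b"), cazy_class = c("GH", "AA"),
    cazy_family = c("GH18", "AA9"), stringsAsFactors = FALSE))
  sub <- cazy_subnetwork(net, ann)
  expect_setequal(network_genes(sub), c("a", "b"))
  expect_equal(igraph::ecount(sub$graph), 1L)

  none <- cazy_subnetwork(net, annotation_set(data.frame(
    gene_id = character(0), cazy_class = character(0),
    cazy_family = character(0), stringsAsFactors = FALSE)))
  expect_equal(igraph::vcount(none$graph), 0L)

  all_ann <- annotation_set(data.frame(
    gene_id = letters[1:5], cazy_class = "GH",
    cazy_family = "GH5", stringsAsFactors = FALSE))
  full <- cazy_subnetwork(net, all_ann)
  expect_identical(network_edge_keys(full), network_edge_keys(net))
})

test_that("network_stats reports counts consistent with the graph", {
  tri <- as_network(graph_from_pairs(c("a", "b", "b", "c", "c", "a")))
  s <- network_stats(tri)
  expect_equal(s$nodes, 3L)
  expect_equal(s$edges, 3L)
  expect_equal(s$max_degree, 2)
  expect_equal(s$components, 1L)

  empty <- as_network(igraph::make_empty_graph(0, directed = FALSE))
  se <- network_stats(empty)
  expect_equal(se$nodes, 0L)
  expect_equal(se$edges, 0L)
  expect_equal(se$components, 0L)

  two <- as_network(graph_from_pairs(c("a", "b", "c", "d")))
  expect_equal(network_stats(two)$components, 2L)
})

test_that("annotate_network transfers CAZy families and DE calls", {
  net <- as_network(graph_from_pairs(c("a", "b", "b", "c")))
  ann <- annotation_set(data.frame(
    gene_id = "b", cazy_class = "GH", cazy_family = "GH7",
    stringsAsFactors = FALSE))
  de <- structure(
    data.frame(gene_id = c("a", "b", "c"), log2fc = c(1, 0, -1),
               p_value = c(0.01, 0.9, 0.01),
               call = c("up_in_cellulose", "none", "up_in_glucose"),
               stringsAsFactors = FALSE),
    class = c("de_table", "data.frame"),
    contrast = c("cellulose", "glucose"))
  out <- annotate_network(net, ann = ann, de = de)
  v <- igraph::V(out$graph)
  expect_equal(v$cazy_family[v$name == "b"], "GH7")
  expect_true(is.na(v$cazy_family[v$name == "a"]))
  expect_equal(v$de_call[v$name == "c"], "up_in_glucose")
})
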