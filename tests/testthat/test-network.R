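test_that("prevalence filter uses a strict fraction threshold", {
  m <- matrix(0, 15, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[1:2, "a"] <- 5   # 2/15 = 0.133 > 0.10 -> kept
  m[1, "b"] <- 5     # 1/15 = 0.067       -> removed
  m[1:15, "c"] <- 1
  out <- prevalence_filter(m, 0.10)
  expect_setequal(colnames(out), c("a", "c"))
  # threshold 0 keeps everything with at least one occurrence
  expect_equal(ncol(prevalence_filter(m, 0)), 3)
  expect_warning(prevalence_filter(matrix(0, 5, 2), 0.1), "empty network")
})

test_that("spearman edges capture monotone pairs and respect the positive-rho rule", {
  x <- 1:10
  m <- cbind(up = x, up2 = exp(x), down = 11 - x, noise = c(5, 1, 4, 2, 6, 3, 8, 7, 10, 9))
  ed <- spearman_edges(m, rho_min = 0.7, p_max = 0.01)
  key <- paste(ed$source, ed$target)
  expect_true("up up2" %in% key)
  expect_equal(ed$rho[key == "up up2"], 1)
  # perfectly decreasing pair: rho = -1, excluded by the positive-rho filter
  expect_false(any(grepl("down", key)))
  ed_abs <- spearman_edges(m, rho_min = 0.7, p_max = 0.01, use_abs = TRUE)
  expect_true("up down" %in% paste(ed_abs$source, ed_abs$target))
  expect_equal(ed_abs$rho[paste(ed_abs$source, ed_abs$target) == "up down"], -1)
})

test_that("edges are invariant to strictly monotone abundance transforms", {
  pl <- planted_correlation_table(seed = 3)
  e1 <- spearman_edges(pl$abundance)
  e2 <- spearman_edges(log1p(pl$abundance) + 2)
  expect_identical(e1[, c("source", "target")], e2[, c("source", "target")])
  expect_equal(e1$rho, e2$rho, tolerance = 1e-12)
})

test_that("constant taxa are skipped with a warning", {
  m <- cbind(a = 1:8, b = rep(4, 8), c = c(2, 1, 4, 3, 6, 5, 8, 7))
  expect_warning(ed <- spearman_edges(m, rho_min = 0.1, p_max = 1), "constant")
  expect_false("b" %in% c(ed$source, ed$target))
})

test_that("planted correlation blocks are recovered with high precision and recall", {
  tp <- 0; fp <- 0; fn <- 0
  for (s in 1:3) {
    pl <- planted_correlation_table(seed = s)
    ed <- spearman_edges(pl$abundance, rho_min = 0.7, p_max = 0.01)
    key <- paste(ed$source, ed$target)
    tp <- tp + sum(key %in% pl$true_pairs)
    fp <- fp + sum(!key %in% pl$true_pairs)
    fn <- fn + sum(!pl$true_pairs %in% key)
  }
  expect_gte(tp / (tp + fp), 0.9)
  expect_gte(tp / (tp + fn), 0.9)
})

test_that("module detection separates disjoint cliques and scores a single edge at Q = 0", {
  k5a <- t(utils::combn(1:5, 2))
  k5b <- t(utils::combn(6:10, 2))
  edges <- data.frame(source = sprintf("n%02d", c(k5a[, 1], k5b[, 1])),
                      target = sprintf("n%02d", c(k5a[, 2], k5b[, 2])))
  mods <- detect_modules(edges, seed = 1)
  expect_equal(mods$n_modules, 2)
  grp <- split(names(mods$membership), mods$membership)
  expect_setequal(sapply(grp, length), c(5, 5))
  single <- data.frame(source = "a", target = "b")
  m1 <- detect_modules(single, seed = 1)
  expect_equal(m1$modularity, 0)
  empty <- detect_modules(data.frame(source = character(),
                                     target = character()), seed = 1)
  expect_equal(empty$n_modules, 0)
})

test_that("planted stochastic block model modules are recovered (adjusted Rand)", {
  ari <- sapply(1:5, function(s) {
    set.seed(s)
    g <- igraph::sample_sbm(60, pref.matrix = diag(0.55, 4) + 0.05,
                            block.sizes = rep(15, 4))
    mclust::adjustedRandIndex(detect_modules(g, seed = s)$membership,
                              rep(1:4, each = 15))
  })
  expect_gte(mean(ari), 0.8)
})

test_that("partition modularity beats the trivial one-module partition", {
  set.seed(2)
  g <- igraph::sample_sbm(40, pref.matrix = diag(0.4, 2) + 0.05,
                          block.sizes = c(20, 20))
  mods <- detect_modules(g, seed = 1)
  q_trivial <- igraph::modularity(g, rep(1, 40))
  expect_gte(mods$modularity, q_trivial)
})

test_that("topology metrics match enumeration on canonical graphs", {
  k4 <- igraph::make_full_graph(4)
  m <- topology_metrics(k4)
  expect_equal(m$average_degree, 3)
  expect_equal(m$average_path_length, 1)
  expect_equal(m$clustering_coefficient, 1)
  # path graph A-B-C
  path3 <- data.frame(source = c("A", "B"), target = c("B", "C"))
  m3 <- topology_metrics(path3)
  expect_equal(m3$average_degree, 4 / 3, tolerance = 1e-12)
  expect_equal(m3$average_path_length, 4 / 3, tolerance = 1e-12)
  expect_equal(m3$clustering_coefficient, 0)
  # triangle plus pendant: qualifying nodes are the three triangle vertices;
  # the one attached to the pendant has 2 of 3 closed neighbor pairs -> 1/3
  tri <- data.frame(source = c("A", "B", "C", "C"),
                    target = c("B", "C", "A", "D"))
  mt <- topology_metrics(tri)
  expect_equal(mt$clustering_coefficient, (1 + 1 + 1 / 3) / 3,
               tolerance = 1e-12)
})

test_that("metrics agree with brute-force computation on random small graphs", {
  set.seed(14)
  for (r in 1:10) {
    n <- sample(5:10, 1)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.45)
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    m <- topology_metrics(g)
    expect_equal(m$average_degree, sum(adj) / n, tolerance = 1e-12)
    sp <- hand_shortest_paths(adj)
    comp <- igraph::components(g)
    big <- which(comp$membership == which.max(comp$csize))
    if (length(big) >= 2) {
      spb <- sp[big, big]
      expect_equal(m$average_path_length,
                   mean(spb[upper.tri(spb)]), tolerance = 1e-12)
    }
    cc <- hand_local_clustering(adj)
    deg <- rowSums(adj)
    if (any(deg >= 2))
      expect_equal(m$clustering_coefficient, mean(cc[deg >= 2]),
                   tolerance = 1e-12)
  }
})

test_that("co_occurrence_network assembles nodes, modules and metrics coherently", {
  pl <- planted_correlation_table(seed = 6)
  net <- co_occurrence_network(pl$abundance, min_prevalence = 0.1, seed = 2)
  expect_s3_class(net, "co_network")
  expect_true(all(net$edges$rho > 0.7))
  expect_true(all(net$edges$p < 0.01))
  expect_setequal(names(net$nodes), c("taxon", "degree", "module"))
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  expect_gte(net$modularity, 0)
  # module ids partition the node set
  expect_true(all(!is.na(net$nodes$module)))
})
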