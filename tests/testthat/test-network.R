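test_that("edge inclusion follows the strict rho and p thresholds", {
  # two taxa strictly co-monotone across 9 samples: exact p well under 0.01
  set.seed(1)
  m9 <- cbind(t1 = 1:9, t2 = (1:9)^2 + 0.0, t3 = sample(101:109))
  m9 <- m9[sample(9), ]
  rownames(m9) <- paste0("s", 1:9)
  net9 <- build_network(m9)
  key <- paste(net9$edges$from, net9$edges$to)
  expect_true("t1 t2" %in% key)
  e <- net9$edges[net9$edges$from == "t1" & net9$edges$to == "t2", ]
  expect_equal(e$rho, 1)
  expect_equal(e$sign, "positive")
  expect_lt(e$p, 0.01)

  # same monotone pattern over 4 samples: exact two-sided p = 1/12 > 0.01
  m4 <- cbind(t1 = 1:4, t2 = c(2, 3, 5, 9), t3 = c(7, 3, 9, 2))
  rownames(m4) <- paste0("s", 1:4)
  net4 <- build_network(m4)
  expect_false("t1 t2" %in% paste(net4$edges$from, net4$edges$to))
  expect_equal(cor.test(m4[, 1], m4[, 2], method = "spearman",
                        exact = TRUE)$p.value, 1 / 12, tolerance = 1e-12)

  # rho exactly 0.6 is excluded by the strict inequality
  m5 <- cbind(t1 = c(1, 2, 3, 4, 5), t2 = c(2, 1, 5, 3, 4),
              t3 = c(9, 1, 4, 7, 2))
  rownames(m5) <- paste0("s", 1:5)
  expect_equal(cor(m5[, 1], m5[, 2], method = "spearman"), 0.6)
  net5 <- build_network(m5, rho_threshold = 0.6, p_threshold = 1)
  expect_false("t1 t2" %in% paste(net5$edges$from, net5$edges$to))
  net5b <- build_network(m5, rho_threshold = 0.59, p_threshold = 1)
  expect_true("t1 t2" %in% paste(net5b$edges$from, net5b$edges$to))
})

test_that("every reported edge satisfies both thresholds; isolates retained", {
  sim <- simulate_counts(synth_config(n_samples_per_group = 21, n_groups = 1,
                                      n_taxa = 40, sequencing_depth = 5000,
                                      seed = 8))
  f <- filter_taxa(sim$counts)
  net <- build_network(f)
  expect_equal(nrow(net$nodes), ncol(f))  # isolated taxa stay in the node set
  expect_true(all(abs(net$edges$rho) > 0.6))
  expect_true(all(net$edges$p < 0.01))
  # BH mode only shrinks the edge set
  net_bh <- build_network(f, correction = "bh")
  expect_lte(nrow(net_bh$edges), nrow(net$edges))

  expect_error(build_network(f[1:3, ]), class = "netstab_invalid_input")
})

test_that("topology matches closed forms on canonical graphs", {
  k3 <- topology(toy_network(complete_edges(3)))
  expect_equal(k3$density, 1)
  expect_equal(k3$mean_clustering, 1)
  expect_equal(k3$diameter, 1)
  expect_equal(k3$mean_degree, 2)

  p3 <- topology(toy_network(path_edges(3)))
  expect_equal(p3$mean_path_length, 4 / 3, tolerance = 1e-12)
  expect_equal(p3$diameter, 2)
  expect_equal(p3$n_edges, 2)
})

test_that("topology agrees with brute-force recomputation on random graphs", {
  for (s in 1:8) {
    n <- sample(8:30, 1)
    net <- toy_network(random_graph_edges(n, 0.15, seed = 300 + s),
                       nodes = paste0("v", 1:n))
    top <- topology(net)
    adj <- adjacency_of(net)
    d <- bfs_distances(adj)
    # largest component by BFS; compare path metrics only when it is unique
    comp_sizes <- rowSums(is.finite(d))
    seed_node <- which.max(comp_sizes)
    members <- which(is.finite(d[seed_node, ]))
    if (length(members) > 1 &&
        sum(comp_sizes == max(comp_sizes)) == length(members)) {
      dg <- d[members, members]
      finite <- dg[upper.tri(dg)]
      expect_equal(top$mean_path_length, mean(finite))
      expect_equal(top$diameter, max(finite))
    }
    expect_equal(top$mean_degree, sum(adj) / n)
    expect_equal(top$density, sum(adj) / (n * (n - 1)))
    # local clustering by direct triple counting
    cl <- vapply(seq_len(n), function(i) {
      nb <- which(adj[i, ])
      if (length(nb) < 2) return(0)
      sum(adj[nb, nb]) / (length(nb) * (length(nb) - 1))
    }, numeric(1))
    expect_equal(top$mean_clustering, mean(cl), tolerance = 1e-12)
    expect_true(top$density >= 0 && top$density <= 1)
    if (is.finite(top$diameter)) {
      expect_gte(top$diameter, top$mean_path_length)
    }
  }
})

test_that("module detection recovers planted partitions", {
  # two disjoint 5-cliques: exactly the cliques, Q = 0.5
  e <- rbind(complete_edges(5, prefix = "a"), complete_edges(5, prefix = "b"))
  part <- detect_modules(toy_network(e), seed = 1)
  expect_equal(length(unique(part$module)), 2)
  expect_equal(length(unique(part$module[startsWith(part$node, "a")])), 1)
  expect_equal(length(unique(part$module[startsWith(part$node, "b")])), 1)
  expect_equal(attr(part, "modularity"), 0.5, tolerance = 1e-12)

  # a single clique is one module
  p1 <- detect_modules(toy_network(complete_edges(6)), seed = 1)
  expect_equal(length(unique(p1$module)), 1)

  # an edgeless graph: every node its own module, Q = 0
  net0 <- toy_network(complete_edges(3)[0, , drop = FALSE],
                      nodes = paste0("v", 1:4))
  p0 <- detect_modules(net0, seed = 1)
  expect_equal(length(unique(p0$module)), 4)
  expect_equal(attr(p0, "modularity"), 0)
})

test_that("Zi-Pi values and roles follow their definitions", {
  # node with all links inside its own module: Pi = 0
  e <- rbind(complete_edges(5, prefix = "a"), complete_edges(5, prefix = "b"))
  net <- toy_network(e)
  part <- detect_modules(net, seed = 1)
  roles <- zipi(net, part)
  expect_true(all(roles$pi == 0))
  expect_true(all(roles$zi == 0))  # all within-degrees equal inside a clique

  # bridge node with one link into each clique: Pi = 1 - 2 (1/2)^2 = 0.5
  e2 <- rbind(e, data.frame(from = c("bridge", "bridge"), to = c("a1", "b1")))
  net2 <- toy_network(e2)
  part2 <- detect_modules(net2, seed = 1)
  roles2 <- zipi(net2, part2)
  expect_equal(roles2$pi[roles2$node == "bridge"], 0.5)
  expect_equal(as.character(roles2$role[roles2$node == "bridge"]),
               "peripheral")  # Pi = 0.5 < 0.62

  # role grid exactly matches the thresholds
  grid <- expand.grid(zi = c(-1, 0, 2.49, 2.5, 3), pi = c(0, 0.5, 0.61, 0.62, 0.9))
  role <- classify_node_role(grid$zi, grid$pi)
  expected <- ifelse(grid$zi >= 2.5,
                     ifelse(grid$pi < 0.62, "module_hub", "network_hub"),
                     ifelse(grid$pi >= 0.62, "connector", "peripheral"))
  expect_equal(as.character(role), expected)

  # the role partition is exhaustive and mutually exclusive
  expect_false(any(is.na(roles2$role)))
  expect_equal(sum(table(roles2$role)), nrow(roles2))
  expect_setequal(keystone_taxa(roles2),
                  roles2$node[roles2$role != "peripheral"])
})

test_that("network exports are Gephi-readable GraphML and TSV", {
  sim <- simulate_counts(synth_config(n_samples_per_group = 12, n_groups = 1,
                                      n_taxa = 20, sequencing_depth = 2000,
                                      seed = 2))
  net <- build_network(filter_taxa(sim$counts))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(net$nodes))
  expect_equal(igraph::ecount(back), nrow(net$edges))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tsv)
  el <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(el), nrow(net$edges))
})
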