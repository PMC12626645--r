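test_that("global efficiency matches closed forms", {
  expect_equal(global_efficiency(toy_network(complete_edges(4))), 1)
  expect_equal(global_efficiency(toy_network(complete_edges(7))), 1)
  expect_equal(global_efficiency(toy_network(path_edges(3))),
               (1 + 1 + 0.5) / 3, tolerance = 1e-12)
  net0 <- toy_network(path_edges(3)[0, , drop = FALSE],
                      nodes = paste0("v", 1:4))
  expect_equal(global_efficiency(net0), 0)
  expect_error(global_efficiency(toy_network(path_edges(2)[0, , drop = FALSE],
                                             nodes = "v1")),
               class = "netstab_invalid_input")
})

test_that("vulnerability matches closed forms and symmetries", {
  expect_equal(vulnerability(toy_network(complete_edges(4))), 0)
  # star: E = 0.75; deleting the center leaves an edgeless remainder
  star <- toy_network(star_edges(3))
  expect_equal(global_efficiency(star), 0.75)
  expect_equal(vulnerability(star), 1)
  # C4 is fully redundant: deleting any node leaves P3 with equal efficiency
  expect_equal(vulnerability(toy_network(cycle_edges(4))), 0,
               tolerance = 1e-12)
  # longer cycles lose a little efficiency per deletion (detours lengthen),
  # exactly (E(Cn) - E(P(n-1))) / E(Cn)
  for (n in 5:7) {
    e_cycle <- global_efficiency(toy_network(cycle_edges(n)))
    e_path <- global_efficiency(toy_network(path_edges(n - 1)))
    expect_equal(vulnerability(toy_network(cycle_edges(n))),
                 (e_cycle - e_path) / e_cycle, tolerance = 1e-12)
  }
  # invariance under node relabeling
  e <- random_graph_edges(12, 0.3, seed = 77)
  v1 <- vulnerability(toy_network(e))
  perm <- setNames(paste0("w", sample(12)), paste0("v", 1:12))
  e2 <- data.frame(from = perm[e$from], to = perm[e$to])
  expect_equal(vulnerability(toy_network(e2)), v1, tolerance = 1e-12)
})

test_that("robustness cascade behaves exactly on degenerate networks", {
  # complete all-positive network, equal abundances: no secondary extinctions
  net <- toy_network(complete_edges(10))
  rb <- robustness(net, removal_fraction = 0.5, n_reps = 25, seed = 1)
  expect_true(all(rb$replicates == 0.5))

  # all-negative edges: every survivor has wMIS <= 0, cascade empties
  eneg <- complete_edges(6)
  eneg$rho <- -0.9
  rbneg <- robustness(toy_network(eneg), removal_fraction = 0.5,
                      n_reps = 10, seed = 2)
  expect_true(all(rbneg$replicates == 0))

  # missing abundances are rejected
  expect_error(robustness(net, abundances = c(v1 = 0.5), n_reps = 2,
                          seed = 1),
               class = "netstab_invalid_input")
})

test_that("robustness on a perfect matching equals exhaustive enumeration", {
  # 4 disjoint positive edges over 8 nodes; removing 4 nodes leaves each
  # survivor alive iff its partner also survived
  em <- data.frame(from = paste0("v", c(1, 3, 5, 7)),
                   to = paste0("v", c(2, 4, 6, 8)))
  net <- toy_network(em)
  sets <- combn(8, 4)
  exact <- mean(apply(sets, 2, function(rm) {
    alive <- rep(TRUE, 8)
    alive[rm] <- FALSE
    pairs <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 2, byrow = TRUE)
    intact <- alive[pairs[, 1]] & alive[pairs[, 2]]
    2 * sum(intact) / 8
  }))
  rb <- robustness(net, removal_fraction = 0.5, n_reps = 10000, seed = 3)
  expect_equal(rb$mean, exact, tolerance = 0.01)
})

test_that("adding positive edges does not decrease mean robustness", {
  base <- random_graph_edges(14, 0.2, seed = 5)
  base$rho <- ifelse(seq_len(nrow(base)) %% 3 == 0, -0.7, 0.8)
  all_pairs <- complete_edges(14)
  key <- paste(all_pairs$from, all_pairs$to)
  extra <- all_pairs[!(key %in% paste(base$from, base$to)), ][1:15, ]
  extra$rho <- 0.9
  nodes <- paste0("v", 1:14)
  r_base <- robustness(toy_network(base, nodes = nodes), n_reps = 300,
                       seed = 9)
  r_more <- robustness(toy_network(rbind(base, extra), nodes = nodes),
                       n_reps = 300, seed = 9)
  se <- sqrt(r_base$sd^2 / 300 + r_more$sd^2 / 300)
  expect_gte(r_more$mean, r_base$mean - 2 * se)
})

test_that("connectedness aggregates corrected correlations as defined", {
  m <- random_counts(30, 12, seed = 6)
  conn <- connectedness(m, null_mode = "observed")
  # oracle: recompute from the correlation matrix directly
  cc <- cor(relative_abundance(m))
  diag(cc) <- NA
  pos <- apply(cc, 1, function(v) mean(v[v > 0], na.rm = TRUE))
  pos[is.nan(pos)] <- 0
  neg <- apply(cc, 1, function(v) mean(v[v < 0], na.rm = TRUE))
  neg[is.nan(neg)] <- 0
  expect_equal(conn$pos_connectedness, unname(pos), tolerance = 1e-12)
  expect_equal(conn$neg_connectedness, unname(neg), tolerance = 1e-12)
  expect_true(all(conn$pos_connectedness >= 0))
  expect_true(all(conn$neg_connectedness <= 0))

  # taxa shuffle is seed-stable
  c1 <- connectedness(m, n_shuffle = 25, seed = 4)
  c2 <- connectedness(m, n_shuffle = 25, seed = 4)
  expect_identical(c1, c2)
})

test_that("cohesion follows the abundance-weighted formula", {
  m <- rbind(s1 = c(40, 60), s2 = c(10, 90))
  colnames(m) <- c("t1", "t2")
  conn <- tibble::tibble(taxon = c("t1", "t2"),
                         pos_connectedness = c(0.5, 0.25),
                         neg_connectedness = c(-0.2, 0))
  coh <- cohesion(m, conn)
  expect_equal(coh$cohesion_pos[1], 0.4 * 0.5 + 0.6 * 0.25, tolerance = 1e-12)
  expect_equal(coh$cohesion_neg[1], 0.4 * -0.2, tolerance = 1e-12)
  expect_equal(coh$np_ratio[1], 0.08 / 0.35, tolerance = 1e-12)

  # all-zero connectedness: zero cohesion, undefined N:P
  conn0 <- tibble::tibble(taxon = c("t1", "t2"),
                          pos_connectedness = c(0, 0),
                          neg_connectedness = c(0, 0))
  coh0 <- cohesion(m, conn0)
  expect_true(all(coh0$cohesion_pos == 0))
  expect_true(all(is.na(coh0$np_ratio)))

  expect_error(cohesion(m, conn[1, ]), class = "netstab_invalid_input")

  # sign constraints on real data
  mm <- random_counts(20, 10, seed = 8)
  ch <- cohesion(mm, connectedness(mm, n_shuffle = 20, seed = 1))
  expect_true(all(ch$cohesion_pos >= 0))
  expect_true(all(ch$cohesion_neg <= 0))
})

test_that("keystone removal reports the vulnerability change", {
  star <- toy_network(star_edges(4))
  kt <- keystone_removal_test(star, "center")
  expect_equal(kt$v_before, 1)
  expect_equal(kt$v_after, 0)
  expect_equal(kt$delta_v, -1)

  kt0 <- keystone_removal_test(star, character(0))
  expect_equal(kt0$delta_v, 0)

  # removing an isolated node never changes remaining shortest paths
  for (s in 1:5) {
    n <- sample(8:20, 1)
    e <- random_graph_edges(n, 0.25, seed = 500 + s)
    nodes <- c(paste0("v", 1:n), "isolated")
    net <- toy_network(e, nodes = nodes)
    gsub_ <- igraph::delete_vertices(net$graph, "isolated")
    d_with <- igraph::distances(net$graph, weights = NA)
    d_without <- igraph::distances(gsub_, weights = NA)
    keep <- rownames(d_without)
    expect_equal(d_with[keep, keep], d_without)
  }

  expect_error(keystone_removal_test(star, c("center", "leaf1", "leaf2")),
               class = "netstab_invalid_input")
})

test_that("stability comparisons handle degenerate and strong cases", {
  x <- c(0.4, 0.41, 0.39, 0.4)
  same <- compare_stability(x, x, test = "paired")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(3)
  a <- rnorm(30, 0, 0.01) + 5
  b <- rnorm(30, 0, 0.01)
  strong <- compare_stability(a, b)
  expect_lt(strong$p_value, 1e-3)

  fwd <- compare_stability(a, b)
  rev <- compare_stability(b, a)
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p_value, rev$p_value)

  expect_error(compare_stability(1:3, 1:4, test = "paired"),
               class = "netstab_invalid_input")
})
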