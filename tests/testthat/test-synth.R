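test_that("simulated trees are rooted, deterministic, and metric", {
  expect_error(simulate_tree(1), class = "netstab_invalid_argument")

  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  expect_equal(tr2$Nnode, 1)
  expect_true(ape::is.rooted(tr2))

  expect_identical(ape::write.tree(simulate_tree(50, seed = 7)),
                   ape::write.tree(simulate_tree(50, seed = 7)))

  tr <- simulate_tree(50, seed = 7)
  expect_true(all(tr$edge.length > 0))
  d <- stats::cophenetic(tr)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # triangle inequality over every ordered triple
  violations <- 0
  for (k in seq_len(nrow(d))) {
    violations <- violations + sum(d > outer(d[, k], d[k, ], "+") + 1e-12)
  }
  expect_equal(violations, 0)
})

test_that("simulated counts conserve depth and are seed-reproducible", {
  cfg <- synth_config(n_samples_per_group = 6, n_groups = 2, n_taxa = 25,
                      sequencing_depth = 1234, seed = 3)
  sim <- simulate_counts(cfg)
  expect_true(all(rowSums(sim$counts) == 1234))
  expect_equal(dim(sim$counts), c(12, 25))
  expect_setequal(unique(sim$truth$module_of_taxon), c(0, 1, 2, 3))
  # every taxon in exactly one module
  expect_equal(length(sim$truth$module_of_taxon), 25)

  sim2 <- simulate_counts(cfg)
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$truth$true_edges, sim2$truth$true_edges)
})

test_that("rho = 0 config yields near-null pairwise correlations at n = 84", {
  cfg <- synth_config(n_samples_per_group = 21, n_groups = 4, n_taxa = 30,
                      within_module_rho = 0, between_module_rho = 0,
                      neg_edge_fraction = 0, sequencing_depth = 5000,
                      seed = 11)
  sim <- simulate_counts(cfg)
  rho <- cor(apply(sim$counts, 2, rank))
  expect_lte(mean(abs(rho[upper.tri(rho)])), 0.15)
})

test_that("planted modules separate within- from between-module correlation", {
  for (s in 1:10) {
    cfg <- synth_config(n_samples_per_group = 21, n_groups = 4, n_taxa = 60,
                        n_modules = 3, module_coverage = 1,
                        within_module_rho = 0.8, between_module_rho = 0,
                        neg_edge_fraction = 0, sequencing_depth = 5000,
                        seed = s)
    sim <- simulate_counts(cfg)
    mod <- sim$truth$module_of_taxon
    rho <- cor(apply(sim$counts, 2, rank))
    same <- outer(mod, mod, "==")
    up <- upper.tri(rho)
    expect_gt(mean(rho[same & up]), mean(rho[!same & up]))
  }
})

test_that("structural recovery: planted edges survive the network thresholds", {
  # at the default 4 x 21 design the generator must feed the network stage
  cfg <- synth_config(seed = 1)
  sim <- simulate_counts(cfg)
  f <- filter_taxa(sim$counts)
  te <- sim$truth$true_edges
  te <- te[te$taxon_a %in% colnames(f) & te$taxon_b %in% colnames(f), ]
  expect_gt(nrow(te), 100)
  net <- build_network(f)
  edge_key <- paste(pmin(net$edges$from, net$edges$to),
                    pmax(net$edges$from, net$edges$to))
  true_key <- paste(pmin(te$taxon_a, te$taxon_b),
                    pmax(te$taxon_a, te$taxon_b))
  expect_gte(mean(true_key %in% edge_key), 0.8)
})

test_that("selection regime plants phylogenetically structured communities", {
  sa <- simulate_assembly("selection", 20, 100, seed = 3)
  expect_equal(dim(sa$counts), c(20, 100))
  trait <- sa$truth$trait
  rel <- sa$counts / rowSums(sa$counts)
  cwm <- as.vector(rel %*% trait)  # community-weighted mean trait
  grp <- factor(sa$truth$optimum_of_community)
  between <- var(tapply(cwm, grp, mean))
  within <- mean(tapply(cwm, grp, var))
  expect_gt(between, within)
})

test_that("dispersal limitation with disjoint pools shares no taxa", {
  da <- simulate_assembly("dispersal_limitation", 2, 100, seed = 1)
  present <- da$counts > 0
  expect_equal(sum(present[1, ] & present[2, ]), 0)
})

test_that("drift regime is reproducible and regime labels are validated", {
  d1 <- simulate_assembly("drift", 5, 40, seed = 3)
  d2 <- simulate_assembly("drift", 5, 40, seed = 3)
  expect_identical(d1$counts, d2$counts)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_error(simulate_assembly("neutralish", 5, 40, seed = 1),
               class = "netstab_invalid_argument")
})

test_that("simulate_env honors the path diagram", {
  # all-zero coefficients: no induced correlation
  env0 <- simulate_env(500, c("X->Y" = 0, "Z->Y" = 0), seed = 2)
  cc <- cor(as.matrix(env0))
  expect_lte(max(abs(cc[upper.tri(cc)])), 0.2)

  # single edge with unit-variance noise recovers its standardized slope
  env1 <- simulate_env(500, c("X->Y" = 0.8), noise_sd = 0.6, seed = 5)
  slope <- coef(lm(Y ~ X, data = env1))[["X"]]
  expect_lt(abs(slope - 0.8), 0.1)

  # noiseless chain is deterministic end to end
  env2 <- simulate_env(100, c("X->M" = 1, "M->Y" = 1), noise_sd = 0,
                       seed = 8)
  expect_equal(cor(env2$X, env2$Y), 1, tolerance = 1e-12)

  expect_error(simulate_env(50, c("X->Y" = 1, "Y->X" = 1), seed = 1),
               class = "netstab_invalid_argument")
})

test_that("a simulated study round-trips through plain-text files", {
  study <- simulate_study(synth_config(n_samples_per_group = 4, n_groups = 2,
                                       n_taxa = 12, sequencing_depth = 300,
                                       seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_study(study, dir)
  expect_true(all(file.exists(paths)))
  back <- read_count_table(paths[["counts"]])
  expect_true(all(back[rownames(study$counts), colnames(study$counts)] ==
                    study$counts))
  tr <- ape::read.tree(paths[["tree"]])
  expect_setequal(tr$tip.label, colnames(study$counts))
})
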