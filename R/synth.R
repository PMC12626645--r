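#' Configuration for the synthetic count-table generator
#'
#' Defaults mirror the study design the package is aimed at: four host/condition
#' groups of 21 samples each, a few hundred taxa with a log-normal abundance
#' spectrum, block-modular latent correlation strong enough that within-module
#' taxon pairs survive the co-occurrence thresholds (|rho| > 0.6, p < 0.01),
#' and a fraction of negatively coupled taxa.
#'
#' @param n_samples_per_group samples per group (>= 1).
#' @param n_groups number of groups (>= 1).
#' @param n_taxa number of taxa (>= 2).
#' @param n_modules number of latent correlation modules (>= 1).
#' @param module_coverage fraction of taxa assigned to modules; the remainder
#'   are uncorrelated background taxa, as in real communities where most taxa
#'   show no strong co-occurrence structure. (A fully modular community also
#'   cancels much of its own signal under compositional closure, because the
#'   shared module factors dominate the per-sample total.)
#' @param within_module_rho latent correlation between taxa sharing a module.
#' @param between_module_rho latent correlation across (non-background)
#'   modules.
#' @param neg_edge_fraction fraction of taxa per module with negated loading,
#'   creating negative within-module correlations.
#' @param sequencing_depth library size each sample is closed to.
#' @param lognormal_sigma sd of log baseline abundances (abundance spectrum).
#' @param seed integer seed, or NULL.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_samples_per_group = 21,
                         n_groups = 4,
                         n_taxa = 300,
                         n_modules = 3,
                         module_coverage = 0.5,
                         within_module_rho = 0.8,
                         between_module_rho = 0.1,
                         neg_edge_fraction = 0.3,
                         sequencing_depth = 10000,
                         lognormal_sigma = 1,
                         seed = NULL) {
  check_scalar(n_samples_per_group, "n_samples_per_group", 1, Inf, TRUE)
  check_scalar(n_groups, "n_groups", 1, Inf, TRUE)
  check_scalar(n_taxa, "n_taxa", 2, Inf, TRUE)
  check_scalar(n_modules, "n_modules", 1, n_taxa, TRUE)
  check_scalar(module_coverage, "module_coverage", 0, 1)
  check_scalar(within_module_rho, "within_module_rho", -1, 1)
  check_scalar(between_module_rho, "between_module_rho", -1, 1)
  check_scalar(neg_edge_fraction, "neg_edge_fraction", 0, 1)
  check_scalar(sequencing_depth, "sequencing_depth", 1, Inf, TRUE)
  check_scalar(lognormal_sigma, "lognormal_sigma", 1e-12, Inf)
  if (!is.null(seed)) check_scalar(seed, "seed", -2^31 + 1, 2^31 - 1, TRUE)
  structure(as.list(environment()), class = "synth_config")
}

#' Simulate a rooted ultrametric phylogeny
#'
#' Pure-birth (Yule) tree with unit birth rate, rescaled to height 1. Tip
#' labels are zero-padded so they sort stably.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed, or NULL.
#' @param tip_prefix label prefix for tips.
#' @return an [ape::phylo] tree with strictly positive branch lengths.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, tip_prefix = "zotu") {
  check_scalar(n_taxa, "n_taxa", 2, Inf, TRUE)
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  # guard against zero-length edges, then rescale to height 1
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- taxon_labels(n_taxa, tip_prefix)
  tr
}

taxon_labels <- function(n, prefix = "zotu") {
  sprintf("%s_%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

# signed block-modular correlation matrix with PSD repair (eigenvalue
# clipping); module id 0 marks uncorrelated background taxa
block_covariance <- function(module, signs, rho_w, rho_b) {
  s <- length(module)
  modular <- outer(module > 0, module > 0, "&")
  same <- outer(module, module, "==") & modular
  sig <- outer(signs, signs)
  R <- ifelse(same, rho_w, ifelse(modular, rho_b, 0)) * sig
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 0) {
    lam <- pmax(ev$values, 1e-10)
    R <- ev$vectors %*% (lam * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / outer(d, d)  # re-normalize to unit diagonal
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < -1e-8) {
      abort("latent covariance is not positive semi-definite after repair.",
            class = "netstab_generation_failure")
    }
  }
  list(R = R, A = ev$vectors %*% diag(sqrt(pmax(ev$values, 0))))
}

#' Simulate a compositional count table with planted module structure
#'
#' Latent multivariate-normal scores with block covariance (strong within-module
#' correlation, weak between), exponentiated onto a log-normal abundance
#' spectrum and closed by multinomial sampling at a fixed sequencing depth —
#' the closure mimics amplicon compositionality, including its induced negative
#' correlation bias. A fraction of taxa per module carry a negated loading, so
#' their within-module correlations are negative (the planted negative edges).
#'
#' @param cfg a [synth_config()].
#' @return list with `counts` (samples x taxa integer matrix), `metadata`
#'   (tibble: sample_id, group) and `truth` (module membership, signed true
#'   edge list, baseline log-abundances, loading signs).
#' @export
simulate_counts <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_samples_per_group * cfg$n_groups
  s <- cfg$n_taxa
  with_seed(cfg$seed, {
    n_mod_taxa <- round(cfg$module_coverage * s)
    module <- c(sort(rep_len(seq_len(cfg$n_modules), n_mod_taxa)),
                rep(0L, s - n_mod_taxa))  # 0 = unstructured background
    signs <- rep(1, s)
    if (cfg$neg_edge_fraction > 0) {
      for (m in seq_len(cfg$n_modules)) {
        idx <- which(module == m)
        k <- floor(cfg$neg_edge_fraction * length(idx))
        if (k > 0) signs[sample(idx, k)] <- -1
      }
    }
    cv <- block_covariance(module, signs, cfg$within_module_rho,
                           cfg$between_module_rho)
    z <- matrix(rnorm(n * s), n, s) %*% t(cv$A)
    mu <- rnorm(s, 0, cfg$lognormal_sigma)
    lambda <- exp(sweep(z, 2, mu, "+"))
    prob <- lambda / rowSums(lambda)
    counts <- t(apply(prob, 1, function(p) {
      rmultinom(1, cfg$sequencing_depth, p)[, 1]
    }))
    taxa <- taxon_labels(s)
    colnames(counts) <- taxa
    grp <- rep(paste0("G", seq_len(cfg$n_groups)),
               each = cfg$n_samples_per_group)
    rownames(counts) <- sprintf("s_%s_%02d", grp,
                                rep(seq_len(cfg$n_samples_per_group),
                                    cfg$n_groups))
    names(module) <- names(signs) <- taxa
    true_edges <- purrr::map_dfr(seq_len(cfg$n_modules), function(m) {
      idx <- which(module == m)
      if (length(idx) < 2) return(tibble())
      pr <- combn(idx, 2)
      tibble(taxon_a = taxa[pr[1, ]], taxon_b = taxa[pr[2, ]],
             sign = signs[pr[1, ]] * signs[pr[2, ]], module = m)
    })
    list(counts = counts,
         metadata = tibble(sample_id = rownames(counts), group = grp),
         truth = list(module_of_taxon = module, loading_sign = signs,
                      true_edges = true_edges, log_baseline = mu))
  })
}

#' Simulate communities assembled under a known ecological regime
#'
#' Validation data for the null-model stage. Under `selection`, tips carry a
#' Brownian trait on the tree and each community filters the species pool by
#' trait distance to its environmental optimum (two contrasting optima produce
#' heterogeneous selection between optimum groups). Under
#' `dispersal_limitation`, each community is colonized from a spatially
#' restricted contiguous window of the pool, irrespective of phylogeny. Under
#' `drift`, membership is a uniform random draw from the pool.
#'
#' @param regime one of "selection", "dispersal_limitation", "drift".
#' @param n_communities number of communities (>= 2).
#' @param n_taxa species-pool size (>= 2).
#' @param seed integer seed, or NULL.
#' @param depth individuals per community.
#' @param richness_frac fraction of the pool present in each community.
#' @param selection_width width (in trait sd units) of the Gaussian filter.
#' @param pool_fraction window width (fraction of the pool) for dispersal
#'   limitation; windows for different communities are evenly spaced and
#'   disjoint whenever `n_communities * pool_fraction <= 1`.
#' @return list with `counts`, `tree`, and `truth` (regime plus regime-specific
#'   detail such as trait values and optimum assignment).
#' @export
simulate_assembly <- function(regime, n_communities, n_taxa, seed = NULL,
                              depth = 1000, richness_frac = 0.3,
                              selection_width = 0.5, pool_fraction = 0.25) {
  regimes <- c("selection", "dispersal_limitation", "drift")
  if (!is.character(regime) || length(regime) != 1 || !regime %in% regimes) {
    abort(paste0("`regime` must be one of: ", paste(regimes, collapse = ", ")),
          class = "netstab_invalid_argument")
  }
  check_scalar(n_communities, "n_communities", 2, Inf, TRUE)
  check_scalar(n_taxa, "n_taxa", 2, Inf, TRUE)
  tree <- simulate_tree(n_taxa, seed = if (is.null(seed)) NULL else seed + 1L)
  richness <- max(2L, round(richness_frac * n_taxa))
  with_seed(seed, {
    counts <- matrix(0L, n_communities, n_taxa,
                     dimnames = list(sprintf("c_%02d", seq_len(n_communities)),
                                     tree$tip.label))
    truth <- list(assembly_regime = regime)
    if (regime == "selection") {
      trait <- ape::rTraitCont(tree, model = "BM", sigma = 1)
      opt_pool <- c(mean(trait) - sd(trait), mean(trait) + sd(trait))
      opt_of <- rep_len(1:2, n_communities)
      w_sd <- selection_width * sd(trait)
      for (c_i in seq_len(n_communities)) {
        w <- exp(-(trait - opt_pool[opt_of[c_i]])^2 / (2 * w_sd^2))
        keep <- sample(n_taxa, richness, prob = w)
        counts[c_i, keep] <- rmultinom(1, depth, w[keep])[, 1]
      }
      truth$trait <- trait
      truth$optimum_of_community <- opt_of
      truth$optima <- opt_pool
    } else if (regime == "dispersal_limitation") {
      width <- max(richness, round(pool_fraction * n_taxa))
      centers <- round(seq(width / 2, n_taxa - width / 2,
                           length.out = n_communities))
      for (c_i in seq_len(n_communities)) {
        lo <- max(1, centers[c_i] - floor((width - 1) / 2))
        window <- seq(lo, min(n_taxa, lo + width - 1))
        keep <- sample(window, min(richness, length(window)))
        counts[c_i, keep] <- rmultinom(1, depth,
                                       rep(1, length(keep)))[, 1]
      }
      truth$window_center <- centers
      truth$window_width <- width
    } else {
      for (c_i in seq_len(n_communities)) {
        keep <- sample(n_taxa, richness)
        counts[c_i, keep] <- rmultinom(1, depth, rep(1, richness))[, 1]
      }
    }
    list(counts = counts, tree = tree, truth = truth)
  })
}

parse_path_edges <- function(path_coefficients) {
  if (is.data.frame(path_coefficients)) {
    stopifnot(all(c("from", "to", "coefficient") %in% names(path_coefficients)))
    edges <- tibble(from = as.character(path_coefficients$from),
                    to = as.character(path_coefficients$to),
                    coefficient = as.numeric(path_coefficients$coefficient))
  } else {
    nm <- names(path_coefficients)
    if (is.null(nm) || !all(grepl("->", nm, fixed = TRUE))) {
      abort("path coefficients must be named 'from->to' or be a data frame.",
            class = "netstab_invalid_argument")
    }
    parts <- strsplit(nm, "->", fixed = TRUE)
    edges <- tibble(from = trimws(vapply(parts, `[`, "", 1)),
                    to = trimws(vapply(parts, `[`, "", 2)),
                    coefficient = as.numeric(path_coefficients))
  }
  edges
}

# topological order of a DAG given an edge tibble; errors (naming a cycle
# member set) if cyclic
topo_order <- function(edges, vars = NULL) {
  vars <- union(vars %||% character(), union(edges$from, edges$to))
  deps <- split(edges$from, edges$to)
  order <- character()
  remaining <- vars
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v) {
      all(!(deps[[v]] %||% character()) %in% remaining)
    }, TRUE)]
    if (!length(ready)) {
      abort(paste0("cyclic path specification among: ",
                   paste(remaining, collapse = ", ")),
            class = "netstab_invalid_argument")
    }
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Simulate environmental covariates from a linear path diagram
#'
#' Exogenous variables are standard normal; every endogenous variable is the
#' stated linear combination of its parents plus Gaussian noise. All columns
#' are returned z-scored, so with unit-variance constructions the generating
#' coefficients are standardized path weights.
#'
#' @param n_samples number of samples.
#' @param path_coefficients named numeric ("X->Y" = beta) or data frame with
#'   columns from, to, coefficient. Must be acyclic.
#' @param noise_sd scalar, or named vector keyed by endogenous variable.
#' @param seed integer seed, or NULL.
#' @param standardize z-score the returned columns (default TRUE).
#' @return tibble of all variables (attribute "truth" carries the edge list).
#' @export
simulate_env <- function(n_samples, path_coefficients, noise_sd = 1,
                         seed = NULL, standardize = TRUE) {
  check_scalar(n_samples, "n_samples", 2, Inf, TRUE)
  edges <- parse_path_edges(path_coefficients)
  order <- topo_order(edges)
  endo <- unique(edges$to)
  with_seed(seed, {
    dat <- matrix(NA_real_, n_samples, length(order),
                  dimnames = list(NULL, order))
    for (v in order) {
      if (!v %in% endo) {
        dat[, v] <- rnorm(n_samples)
      } else {
        e <- edges[edges$to == v, ]
        sdv <- if (length(noise_sd) > 1) {
          if (!v %in% names(noise_sd)) {
            abort(sprintf("no noise_sd entry for endogenous variable '%s'.", v),
                  class = "netstab_invalid_argument")
          }
          noise_sd[[v]]
        } else {
          noise_sd
        }
        dat[, v] <- as.vector(dat[, e$from, drop = FALSE] %*% e$coefficient) +
          rnorm(n_samples, 0, sdv)
      }
    }
    if (standardize) {
      dat <- apply(dat, 2, function(col) {
        s <- sd(col)
        if (s > 0) (col - mean(col)) / s else col - mean(col)
      })
    }
    out <- as_tibble(as.data.frame(dat))
    attr(out, "truth") <- list(path_coefficients = edges)
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Bundles the pieces every pipeline stage needs: a modular count table over
#' groups, matching metadata, a phylogeny over the same taxa, and an
#' environmental table in which the bloom covariate (MCs) differs between
#' designated bloom groups and water temperature is unrelated noise.
#'
#' @param cfg a [synth_config()].
#' @param bloom_groups group labels treated as bloom-exposed (default the
#'   even-numbered groups).
#' @param bloom_effect shift in mean MCs for bloom groups.
#' @return list: `counts`, `metadata`, `tree`, `env`, `truth`.
#' @export
simulate_study <- function(cfg = synth_config(), bloom_groups = NULL,
                           bloom_effect = 2) {
  sim <- simulate_counts(cfg)
  tree <- simulate_tree(cfg$n_taxa,
                        seed = if (is.null(cfg$seed)) NULL else cfg$seed + 7L)
  groups <- unique(sim$metadata$group)
  bloom_groups <- bloom_groups %||% groups[seq_along(groups) %% 2 == 0]
  bloom <- sim$metadata$group %in% bloom_groups
  env_seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 11L
  env <- with_seed(env_seed, tibble(
    sample_id = sim$metadata$sample_id,
    WT = rnorm(nrow(sim$metadata), 25, 3),
    MCs = pmax(0, rnorm(nrow(sim$metadata), 0.5, 0.3) +
                 ifelse(bloom, bloom_effect, 0))
  ))
  sim$metadata$bloom <- ifelse(bloom, "bloom", "no_bloom")
  list(counts = sim$counts, metadata = sim$metadata, tree = tree, env = env,
       truth = c(sim$truth, list(bloom_groups = bloom_groups,
                                 bloom_effect = bloom_effect)))
}

#' Write a synthetic study to plain-text files
#'
#' Taxa-by-sample TSV counts, TSV metadata and environment, Newick tree, and a
#' JSON ground-truth sidecar.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             env = file.path(dir, "env.tsv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  write_count_table(study$counts, paths[["counts"]])
  readr::write_tsv(study$metadata, paths[["metadata"]])
  readr::write_tsv(study$env, paths[["env"]])
  ape::write.tree(study$tree, paths[["tree"]])
  truth <- study$truth
  truth$module_of_taxon <- as.list(truth$module_of_taxon)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
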