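#' Pipeline configuration
#'
#' Collects every stage parameter with the conventional defaults (0.1% / one
#' third inclusion filter; |rho| > 0.6, p < 0.01 edges; 50% removal over 100
#' replicates; 999 null iterations) plus a master seed from which each stage
#' seed is derived deterministically via [derive_seed()].
#'
#' @param min_mean_rel_abund,min_prevalence taxon filter thresholds.
#' @param rho_threshold,p_threshold,correction network edge thresholds.
#' @param removal_fraction,n_reps robustness cascade settings.
#' @param n_null null-model iterations (betaNTI and Raup-Crick).
#' @param n_shuffle taxa-shuffle iterations for connectedness.
#' @param n_perm permutations for group tests.
#' @param rf_trees,rf_perm keystone-importance forest settings.
#' @param seed master seed.
#' @return validated `netstab_config` list.
#' @export
netstab_config <- function(min_mean_rel_abund = 0.001,
                           min_prevalence = 1 / 3,
                           rho_threshold = 0.6, p_threshold = 0.01,
                           correction = "none",
                           removal_fraction = 0.5, n_reps = 100,
                           n_null = 999, n_shuffle = 200, n_perm = 999,
                           rf_trees = 500, rf_perm = 100,
                           seed = 42) {
  check_scalar(min_mean_rel_abund, "min_mean_rel_abund", 0, 1)
  check_scalar(min_prevalence, "min_prevalence", 0, 1)
  check_scalar(rho_threshold, "rho_threshold", 0, 1)
  check_scalar(p_threshold, "p_threshold", 0, 1)
  if (!correction %in% c("none", "bh")) {
    abort("`correction` must be 'none' or 'bh'.",
          class = "netstab_invalid_argument")
  }
  check_scalar(removal_fraction, "removal_fraction", 1e-12, 1 - 1e-12)
  check_scalar(n_reps, "n_reps", 1, Inf, TRUE)
  check_scalar(n_null, "n_null", 99, Inf, TRUE)
  check_scalar(n_shuffle, "n_shuffle", 1, Inf, TRUE)
  check_scalar(n_perm, "n_perm", 1, Inf, TRUE)
  check_scalar(rf_trees, "rf_trees", 1, Inf, TRUE)
  check_scalar(rf_perm, "rf_perm", 1, Inf, TRUE)
  check_scalar(seed, "seed", -2^31 + 1, 2^31 - 1, TRUE)
  structure(as.list(environment()), class = "netstab_config")
}

#' Run the full per-group analysis pipeline
#'
#' For every group: taxon filter, assembly null models (betaNTI, Raup-Crick,
#' five-process partition), signed co-occurrence network with topology,
#' modules and Zi-Pi roles, stability (robustness, vulnerability, cohesion),
#' keystone-removal test and keystone importance. Across all samples: alpha
#' diversity, Bray-Curtis PCoA, PERMANOVA and ANOSIM. Optionally, forward
#' selection of environmental drivers of per-sample N:P cohesion and a
#' standardized path model. Reruns with the same inputs and config write
#' byte-identical outputs.
#'
#' @param counts count matrix (samples x taxa) or data frame.
#' @param metadata data frame with `sample_id` and `group` columns.
#' @param tree phylogeny covering the taxa (NULL skips the assembly stage).
#' @param env optional data frame of environmental covariates per sample.
#' @param config a [netstab_config()].
#' @param out_dir optional output directory for TSV/GraphML/JSON artifacts.
#' @param dag optional list of formulas for the path model (requires `env`).
#' @return list with per-group results, cross-group tests, `summary` tibble,
#'   and (if requested) driver models.
#' @export
run_pipeline <- function(counts, metadata, tree = NULL, env = NULL,
                         config = netstab_config(), out_dir = NULL,
                         dag = NULL) {
  stopifnot(inherits(config, "netstab_config"))
  m <- as_count_matrix(counts)
  g_all <- resolve_groups(metadata, rownames(m))
  log_lines <- c("netstab pipeline log",
                 paste0("master_seed: ", config$seed),
                 paste0("n_samples: ", nrow(m)),
                 paste0("n_taxa: ", ncol(m)),
                 paste0("groups: ", paste(levels(g_all), collapse = ", ")))
  emit <- function(...) log_lines <<- c(log_lines, sprintf(...))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  write_out <- function(obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    readr::write_tsv(obj, file.path(out_dir, name))
  }
  fail_marker <- function(stage, err) {
    if (!is.null(out_dir)) {
      writeLines(c("FAILED", paste0("stage: ", stage),
                   paste0("error: ", conditionMessage(err))),
                 file.path(out_dir, "FAILED"))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      fail_marker(name, e)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "netstab_stage_error", parent = e)
    })
  }

  # ---- cross-group diversity on all samples ----
  diversity <- stage("diversity", {
    alpha <- alpha_diversity(m)
    bc <- bray_curtis(m)
    ord <- pcoa(bc)
    pm <- permanova(bc, g_all, n_perm = config$n_perm,
                    seed = derive_seed(config$seed, "permanova"))
    an <- anosim(bc, g_all, n_perm = config$n_perm,
                 seed = derive_seed(config$seed, "anosim"))
    emit("diversity: alpha for %d samples; PERMANOVA R2=%.3f p=%.4g",
         nrow(alpha), pm$r2, pm$p_value)
    list(alpha = alpha, bray_curtis = bc, pcoa = ord,
         group_tests = dplyr::bind_rows(pm, an))
  })
  write_out(diversity$alpha, "alpha_diversity.tsv")
  write_out(diversity$group_tests, "group_tests.tsv")
  if (!is.null(out_dir)) {
    coords <- as_tibble(diversity$pcoa$coordinates[, 1:min(3,
      ncol(diversity$pcoa$coordinates)), drop = FALSE])
    coords$sample_id <- diversity$pcoa$sample_ids
    readr::write_tsv(coords[, c(ncol(coords), seq_len(ncol(coords) - 1))],
                     file.path(out_dir, "pcoa_coordinates.tsv"))
  }

  # ---- per-group stages ----
  groups <- levels(g_all)
  per_group <- purrr::map(groups, function(grp) {
    mg <- m[g_all == grp, , drop = FALSE]
    res <- list(group = grp)
    res$filtered <- stage(paste0("filter/", grp), {
      fm <- filter_taxa(mg, config$min_mean_rel_abund, config$min_prevalence)
      emit("filter[%s]: %d of %d taxa retained", grp, ncol(fm), ncol(mg))
      fm
    })
    if (!is.null(tree)) {
      res$assembly <- stage(paste0("assembly/", grp), {
        tr <- ape::keep.tip(tree, intersect(tree$tip.label,
                                            colnames(res$filtered)))
        fa <- res$filtered[, tr$tip.label, drop = FALSE]
        fa <- fa[rowSums(fa) > 0, , drop = FALSE]
        bn <- bnti(fa, tr, n_null = config$n_null,
                   seed = derive_seed(config$seed, paste0("bnti/", grp)))
        rc <- rc_bray(fa, n_null = config$n_null,
                      seed = derive_seed(config$seed, paste0("rc/", grp)))
        part <- partition_processes(bn, rc)
        emit("assembly[%s]: %d pairs partitioned", grp, nrow(part$pairs))
        part
      })
    }
    res$network <- stage(paste0("network/", grp), {
      net <- build_network(res$filtered, config$rho_threshold,
                           config$p_threshold, config$correction)
      emit("network[%s]: %d nodes, %d edges", grp, nrow(net$nodes),
           nrow(net$edges))
      net
    })
    res$modules <- stage(paste0("modules/", grp), {
      detect_modules(res$network,
                     seed = derive_seed(config$seed, paste0("louvain/", grp)))
    })
    res$topology <- stage(paste0("topology/", grp), {
      dplyr::bind_cols(tibble(group = grp),
                       topology(res$network, res$modules))
    })
    res$roles <- stage(paste0("zipi/", grp), {
      zipi(res$network, res$modules)
    })
    res$keystones <- keystone_taxa(res$roles)
    res$stability <- stage(paste0("stability/", grp), {
      rb <- robustness(res$network, removal_fraction = config$removal_fraction,
                       n_reps = config$n_reps,
                       seed = derive_seed(config$seed, paste0("robust/", grp)))
      vul <- if (nrow(res$network$nodes) >= 3) vulnerability(res$network)
             else NA_real_
      conn <- connectedness(res$filtered, n_shuffle = config$n_shuffle,
                            seed = derive_seed(config$seed,
                                               paste0("cohesion/", grp)))
      coh <- cohesion(res$filtered, conn)
      emit("stability[%s]: robustness %.3f, vulnerability %.3f", grp,
           rb$mean, vul)
      list(robustness = rb, vulnerability = vul, connectedness = conn,
           cohesion = coh)
    })
    res$keystone_test <- stage(paste0("keystone_removal/", grp), {
      remaining <- nrow(res$network$nodes) - length(res$keystones)
      if (remaining >= 3) {
        # an empty keystone set is the trivial case: delta_v = 0
        keystone_removal_test(res$network, res$keystones)
      } else {
        tibble(v_before = res$stability$vulnerability,
               v_after = NA_real_, delta_v = NA_real_,
               n_removed = length(res$keystones))
      }
    })
    res$importance <- stage(paste0("importance/", grp), {
      y <- res$stability$cohesion$np_ratio
      ok <- length(res$keystones) >= 1 && nrow(res$filtered) >= 10 &&
        length(unique(y[!is.na(y)])) >= 2
      if (ok) {
        Xk <- relative_abundance(res$filtered)[, res$keystones, drop = FALSE]
        keystone_importance(Xk, y, n_trees = config$rf_trees,
                            n_perm = config$rf_perm,
                            seed = derive_seed(config$seed,
                                               paste0("rf/", grp)))
      } else {
        emit("importance[%s]: skipped (%d keystones)", grp,
             length(res$keystones))
        NULL
      }
    })
    if (!is.null(out_dir)) {
      write_edge_list(res$network,
                      file.path(out_dir, paste0("edges_", grp, ".tsv")))
      write_network_graphml(res$network,
                            file.path(out_dir, paste0("network_", grp,
                                                      ".graphml")))
      readr::write_tsv(res$roles, file.path(out_dir,
                                            paste0("node_roles_", grp,
                                                   ".tsv")))
      readr::write_tsv(res$stability$cohesion,
                       file.path(out_dir, paste0("cohesion_", grp, ".tsv")))
      readr::write_tsv(tidy(res$stability$robustness),
                       file.path(out_dir, paste0("robustness_", grp,
                                                 ".tsv")))
      if (!is.null(res$assembly)) {
        readr::write_tsv(res$assembly$fractions,
                         file.path(out_dir, paste0("assembly_", grp,
                                                   ".tsv")))
      }
      if (!is.null(res$importance)) {
        readr::write_tsv(res$importance,
                         file.path(out_dir, paste0("importance_", grp,
                                                   ".tsv")))
      }
    }
    res
  })
  names(per_group) <- groups

  summary_tbl <- purrr::map_dfr(per_group, function(res) {
    frac_of <- function(proc) {
      if (is.null(res$assembly)) return(NA_real_)
      fr <- res$assembly$fractions
      sum(fr$fraction[fr$process %in% proc])
    }
    drift <- frac_of("drift")
    tibble(
      group = res$group,
      n_taxa_filtered = ncol(res$filtered),
      n_nodes = nrow(res$network$nodes),
      n_edges = nrow(res$network$edges),
      modularity = attr(res$modules, "modularity"),
      drift_fraction = drift,
      selection_fraction = frac_of(c("heterogeneous_selection",
                                     "homogeneous_selection")),
      dispersal_fraction = frac_of(c("dispersal_limitation",
                                     "homogenizing_dispersal")),
      robustness_mean = res$stability$robustness$mean,
      robustness_sd = res$stability$robustness$sd,
      vulnerability = res$stability$vulnerability,
      mean_np_cohesion = mean(res$stability$cohesion$np_ratio, na.rm = TRUE),
      n_keystones = length(res$keystones),
      delta_v_keystone_removal = res$keystone_test$delta_v
    )
  })

  drivers <- NULL
  if (!is.null(env)) {
    drivers <- stage("drivers", {
      coh_all <- purrr::map_dfr(per_group, ~ .x$stability$cohesion)
      env_df <- as.data.frame(env)
      id_col <- intersect(c("sample_id", "sample"), names(env_df))[1]
      if (!is.na(id_col)) {
        idx <- match(coh_all$sample_id, env_df[[id_col]])
        env_df <- env_df[idx, setdiff(names(env_df), id_col), drop = FALSE]
      }
      sel <- forward_select(env_df, coh_all$np_ratio,
                            n_perm = config$n_perm,
                            seed = derive_seed(config$seed, "forward"))
      pm <- if (!is.null(dag)) {
        dat <- cbind(env_df, np_cohesion = coh_all$np_ratio)
        fit_path_model(dag, dat)
      }
      emit("drivers: %d variable(s) selected", nrow(sel))
      list(selected = sel, path_model = pm)
    })
    if (!is.null(out_dir)) {
      write_out(drivers$selected, "forward_selection.tsv")
      if (!is.null(drivers$path_model)) {
        write_out(drivers$path_model$coefficients, "path_coefficients.tsv")
        write_out(drivers$path_model$effects, "path_effects.tsv")
      }
    }
  }

  if (!is.null(out_dir)) {
    write_out(summary_tbl, "summary.tsv")
    jsonlite::write_json(summary_tbl, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  list(diversity = diversity, groups = per_group, summary = summary_tbl,
       drivers = drivers, config = config)
}
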