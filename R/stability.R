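#' Global efficiency of a network
#'
#' Mean inverse shortest-path length (unweighted hops) over all ordered node
#' pairs; disconnected pairs contribute 0. Equals 1 on a complete graph and 0
#' on an edgeless one.
#'
#' @param net `cooccurrence_network` or igraph graph (>= 2 nodes).
#' @return efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  g <- as_netstab_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) {
    abort("global efficiency needs >= 2 nodes.",
          class = "netstab_invalid_input")
  }
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Vulnerability of a network
#'
#' The maximum relative drop in global efficiency caused by deleting a single
#' node: `V = max_i (E - E_-i) / E`, with `E_-i` computed over the remaining
#' nodes. Defined as 0 when `E = 0`.
#'
#' @param net `cooccurrence_network` or igraph graph (>= 3 nodes).
#' @return vulnerability in `[0, 1]` (can be negative only if removal raises
#'   efficiency, which hop-count efficiency does not allow).
#' @export
vulnerability <- function(net) {
  g <- as_netstab_graph(net)
  n <- igraph::vcount(g)
  if (n < 3) {
    abort("vulnerability needs >= 3 nodes.", class = "netstab_invalid_input")
  }
  e0 <- global_efficiency(g)
  if (e0 == 0) return(0)
  drops <- vapply(seq_len(n), function(i) {
    gi <- igraph::delete_vertices(g, i)
    (e0 - global_efficiency(gi)) / e0
  }, numeric(1))
  max(drops)
}

signed_adjacency <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  nodes <- net$nodes$name
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(net$edges)) {
    ia <- match(net$edges$from, nodes)
    ib <- match(net$edges$to, nodes)
    w[cbind(ia, ib)] <- net$edges$rho
    w[cbind(ib, ia)] <- net$edges$rho
  }
  w
}

#' Robustness to random node loss with secondary extinctions
#'
#' Each replicate deletes `floor(removal_fraction * N)` random nodes, then
#' iterates a cascade: every survivor's abundance-weighted mean interaction
#' strength over its surviving neighbors,
#' `wMIS_i = sum_j b_j rho_ij / sum_j b_j`, is recomputed and all nodes with
#' `wMIS <= threshold` (including survivors left with no neighbors, whose
#' wMIS is 0) are removed simultaneously, until a fixed point. The replicate
#' value is the fraction of the original nodes remaining.
#'
#' @param net `cooccurrence_network`.
#' @param abundances named per-taxon proportions; defaults to the node mean
#'   relative abundances stored in the network.
#' @param removal_fraction fraction of nodes deleted initially, in (0, 1).
#' @param n_reps number of random replicates.
#' @param seed integer seed, or NULL.
#' @param extinction_threshold wMIS cutoff (nodes with wMIS <= it die).
#' @return `robustness_sim`: replicates, mean, sd, parameters.
#' @export
robustness <- function(net, abundances = NULL, removal_fraction = 0.5,
                       n_reps = 100, seed = NULL, extinction_threshold = 0) {
  stopifnot(inherits(net, "cooccurrence_network"))
  check_scalar(removal_fraction, "removal_fraction", 1e-12, 1 - 1e-12)
  check_scalar(n_reps, "n_reps", 1, Inf, TRUE)
  nodes <- net$nodes$name
  b <- abundances %||% setNames(net$nodes$mean_rel_abund, nodes)
  if (!all(nodes %in% names(b))) {
    abort(paste0("abundance missing for node(s): ",
                 paste(setdiff(nodes, names(b)), collapse = ", ")),
          class = "netstab_invalid_input")
  }
  b <- b[nodes]
  w <- signed_adjacency(net)
  a <- abs(w) > 0
  n <- length(nodes)
  n_remove <- floor(removal_fraction * n)
  reps <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      alive <- rep(TRUE, n)
      alive[sample.int(n, n_remove)] <- FALSE
      repeat {
        if (!any(alive)) break
        ba <- b * alive
        num <- as.vector(w %*% ba)
        den <- as.vector(a %*% ba)
        wmis <- ifelse(den > 0, num / den, 0)
        die <- alive & (wmis <= extinction_threshold)
        if (!any(die)) break
        alive[die] <- FALSE
      }
      sum(alive) / n
    }, numeric(1))
  })
  structure(list(replicates = reps, mean = mean(reps), sd = sd(reps),
                 params = list(removal_fraction = removal_fraction,
                               n_reps = n_reps, seed = seed,
                               extinction_threshold = extinction_threshold,
                               n_nodes = n)),
            class = "robustness_sim")
}

#' @export
print.robustness_sim <- function(x, ...) {
  cat(sprintf("Robustness: %.3f +/- %.3f (%d replicates, %.0f%% removal, %d nodes)\n",
              x$mean, x$sd, x$params$n_reps,
              100 * x$params$removal_fraction, x$params$n_nodes))
  invisible(x)
}

#' @export
tidy.robustness_sim <- function(x, ...) {
  tibble(replicate = seq_along(x$replicates),
         proportion_remaining = x$replicates)
}

#' @export
glance.robustness_sim <- function(x, ...) {
  tibble(mean_robustness = x$mean, sd_robustness = x$sd,
         n_reps = x$params$n_reps,
         removal_fraction = x$params$removal_fraction)
}

#' Per-taxon positive and negative connectedness
#'
#' Pairwise correlations between taxa on relative abundances; in
#' `taxa_shuffle` mode the expected null correlation (columns permuted
#' independently, averaged over `n_shuffle` shuffles) is subtracted per pair
#' first. A taxon's positive connectedness is the mean of its positive
#' (corrected) correlations, its negative connectedness the mean of the
#' negative ones; taxa with no qualifying partners get 0.
#'
#' @param x filtered count matrix (samples x taxa) or data frame; >= 5
#'   samples.
#' @param null_mode "taxa_shuffle" (default) or "observed" (no correction).
#' @param n_shuffle number of column shuffles for the null.
#' @param seed integer seed, or NULL.
#' @param method correlation type ("pearson", the cohesion convention, or
#'   "spearman").
#' @return tibble: taxon, pos_connectedness (>= 0), neg_connectedness (<= 0).
#' @export
connectedness <- function(x, null_mode = c("taxa_shuffle", "observed"),
                          n_shuffle = 200, seed = NULL,
                          method = c("pearson", "spearman")) {
  null_mode <- match.arg(null_mode)
  method <- match.arg(method)
  m <- as_count_matrix(x)
  if (nrow(m) < 5) {
    abort("connectedness needs >= 5 samples.",
          class = "netstab_invalid_input")
  }
  rel <- relative_abundance(m)
  const <- apply(rel, 2, function(v) max(v) == min(v))
  if (any(const)) {
    warn(sprintf("%d constant taxa: correlations treated as 0.", sum(const)))
  }
  obs <- suppressWarnings(cor(rel, method = method))
  obs[!is.finite(obs)] <- 0
  corr <- obs
  if (null_mode == "taxa_shuffle") {
    check_scalar(n_shuffle, "n_shuffle", 1, Inf, TRUE)
    null_sum <- matrix(0, ncol(rel), ncol(rel))
    with_seed(seed, {
      for (i in seq_len(n_shuffle)) {
        shuf <- apply(rel, 2, sample)
        cs <- suppressWarnings(cor(shuf, method = method))
        cs[!is.finite(cs)] <- 0
        null_sum <- null_sum + cs
      }
    })
    corr <- obs - null_sum / n_shuffle
  }
  diag(corr) <- NA
  corr[const, ] <- NA
  corr[, const] <- NA
  pos <- apply(corr, 1, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(v) else 0
  })
  neg <- apply(corr, 1, function(v) {
    v <- v[!is.na(v) & v < 0]
    if (length(v)) mean(v) else 0
  })
  pos[const] <- 0
  neg[const] <- 0
  tibble(taxon = colnames(m), pos_connectedness = unname(pos),
         neg_connectedness = unname(neg))
}

#' Per-sample cohesion and the negative:positive ratio
#'
#' `cohesion_pos(sample) = sum_i b_i(sample) * pos_connectedness_i` over the
#' m taxa of the community (and analogously for the negative component), with
#' `b` the within-sample relative abundances. The N:P ratio is
#' `|cohesion_neg| / cohesion_pos` (missing when positive cohesion is 0);
#' higher negative relative to positive cohesion indicates a more stable
#' community.
#'
#' @param x count matrix (samples x taxa) or data frame.
#' @param conn [connectedness()] table covering all taxa of `x`.
#' @return tibble: sample_id, cohesion_pos, cohesion_neg, np_ratio.
#' @export
cohesion <- function(x, conn) {
  m <- as_count_matrix(x)
  if (!all(colnames(m) %in% conn$taxon)) {
    abort(paste0("connectedness missing for taxa: ",
                 paste(setdiff(colnames(m), conn$taxon), collapse = ", ")),
          class = "netstab_invalid_input")
  }
  rel <- relative_abundance(m)
  idx <- match(colnames(m), conn$taxon)
  pos <- as.vector(rel %*% conn$pos_connectedness[idx])
  neg <- as.vector(rel %*% conn$neg_connectedness[idx])
  tibble(sample_id = rownames(m), cohesion_pos = pos, cohesion_neg = neg,
         np_ratio = ifelse(pos > 0, abs(neg) / pos, NA_real_))
}

#' Vulnerability change after keystone removal
#'
#' Recomputes vulnerability after deleting the keystone node set; a positive
#' `delta_v` means the network became more vulnerable without its keystones.
#'
#' @param net `cooccurrence_network` or igraph graph.
#' @param keystones node names to remove (subset of the node set).
#' @return one-row tibble: v_before, v_after, delta_v, n_removed.
#' @export
keystone_removal_test <- function(net, keystones) {
  g <- as_netstab_graph(net)
  nodes <- igraph::V(g)$name
  keystones <- as.character(keystones)
  if (!all(keystones %in% nodes)) {
    abort(paste0("keystones not in the network: ",
                 paste(setdiff(keystones, nodes), collapse = ", ")),
          class = "netstab_invalid_input")
  }
  v_before <- vulnerability(g)
  if (length(keystones) == 0) {
    return(tibble(v_before = v_before, v_after = v_before, delta_v = 0,
                  n_removed = 0L))
  }
  if (length(nodes) - length(keystones) < 3) {
    abort("fewer than 3 nodes would remain after keystone removal.",
          class = "netstab_invalid_input")
  }
  g2 <- igraph::delete_vertices(g, keystones)
  v_after <- vulnerability(g2)
  tibble(v_before = v_before, v_after = v_after,
         delta_v = v_after - v_before, n_removed = length(keystones))
}

#' Compare stability metrics between two groups
#'
#' t-test on two vectors of replicate-level robustness or per-sample cohesion
#' values; Welch two-sample by default, or paired. Identical paired vectors
#' (all differences zero) return t = 0, p = 1 by convention.
#'
#' @param a,b numeric vectors.
#' @param test "welch" or "paired".
#' @return one-row tibble: test, statistic, df, p_value, mean_a, mean_b.
#' @export
compare_stability <- function(a, b, test = c("welch", "paired")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (test == "paired" && length(a) != length(b)) {
    abort("paired comparison needs equal-length vectors.",
          class = "netstab_invalid_input")
  }
  tt <- tryCatch(
    t.test(a, b, paired = test == "paired", var.equal = FALSE),
    error = function(e) NULL
  )
  # all-zero differences (or constant data) leave t undefined; report the
  # no-evidence convention t = 0, p = 1
  if (is.null(tt) || !is.finite(tt$statistic)) {
    return(tibble(test = test, statistic = 0, df = NA_real_, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b)))
  }
  tibble(test = test, statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         mean_a = mean(a), mean_b = mean(b))
}
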