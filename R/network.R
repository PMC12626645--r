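spearman_matrix <- function(m) {
  n <- nrow(m)
  rk <- apply(m, 2, rank)  # mid-ranks for ties
  const <- apply(rk, 2, function(v) max(v) == min(v))
  rho <- suppressWarnings(cor(rk))
  if (any(const)) {
    warn(sprintf("%d constant taxa: their correlations are undefined and skipped.",
                 sum(const)))
    rho[const, ] <- NA
    rho[, const] <- NA
  }
  # p-values: exact permutation distribution (via cor.test) for small
  # tie-free samples, t approximation otherwise
  pv <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(rho))
  tied <- apply(m, 2, function(v) anyDuplicated(v) > 0)
  if (n <= 9) {
    for (i in seq_len(ncol(m) - 1)) {
      if (const[i]) next
      for (j in seq((i + 1), ncol(m))) {
        if (const[j]) next
        pv[i, j] <- pv[j, i] <- if (!tied[i] && !tied[j]) {
          cor.test(m[, i], m[, j], method = "spearman",
                   exact = TRUE)$p.value
        } else {
          spearman_t_p(rho[i, j], n)
        }
      }
    }
  } else {
    pv[] <- spearman_t_p(rho, n)
  }
  diag(pv) <- NA
  list(rho = rho, p = pv)
}

spearman_t_p <- function(rho, n) {
  r <- pmin(pmax(rho, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  2 * pt(-abs(tt), df = n - 2)
}

#' Build a signed Spearman co-occurrence network
#'
#' Spearman rank correlation (mid-ranks for ties) between all taxon pairs
#' across samples; a pair becomes an edge iff `|rho|` is strictly above
#' `rho_threshold` and its two-sided p-value (exact permutation for tie-free
#' n <= 9, t approximation otherwise; optionally Benjamini-Hochberg adjusted)
#' is strictly below `p_threshold`. Isolated taxa remain in the node set.
#'
#' @param x filtered count matrix (samples x taxa) or data frame; >= 4 samples
#'   (at 4 tie-free samples the smallest exact two-sided p is 1/12, so no pair
#'   can clear a 0.01 threshold).
#' @param rho_threshold correlation magnitude threshold (strict).
#' @param p_threshold significance threshold (strict).
#' @param correction "none" (threshold raw p) or "bh".
#' @return `cooccurrence_network`: igraph graph plus node and edge tibbles.
#' @export
build_network <- function(x, rho_threshold = 0.6, p_threshold = 0.01,
                          correction = c("none", "bh")) {
  correction <- match.arg(correction)
  m <- as_count_matrix(x)
  if (nrow(m) < 4) {
    abort("network construction needs >= 4 samples.",
          class = "netstab_invalid_input")
  }
  sp <- spearman_matrix(m)
  p_use <- sp$p
  if (correction == "bh") {
    up <- upper.tri(p_use)
    p_use[up] <- p.adjust(p_use[up], method = "BH")
    p_use[lower.tri(p_use)] <- t(p_use)[lower.tri(p_use)]
  }
  keep <- !is.na(sp$rho) & !is.na(p_use) &
    abs(sp$rho) > rho_threshold & p_use < p_threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  taxa <- colnames(m)
  edges <- tibble(
    from = taxa[idx[, 1]], to = taxa[idx[, 2]],
    rho = sp$rho[idx], p = sp$p[idx], p_adjusted = p_use[idx],
    sign = ifelse(sp$rho[idx] > 0, "positive", "negative")
  ) |> dplyr::arrange(.data$from, .data$to)
  rel <- relative_abundance(m)
  nodes <- tibble(name = taxa, mean_rel_abund = colMeans(rel))
  g <- igraph::graph_from_data_frame(
    edges |> dplyr::mutate(weight = .data$rho),
    directed = FALSE, vertices = nodes
  )
  structure(list(graph = g, nodes = nodes, edges = edges,
                 params = list(rho_threshold = rho_threshold,
                               p_threshold = p_threshold,
                               correction = correction,
                               n_samples = nrow(m))),
            class = "cooccurrence_network")
}

as_netstab_graph <- function(net) {
  if (inherits(net, "cooccurrence_network")) return(net$graph)
  if (inherits(net, "igraph")) return(net)
  abort("expected a cooccurrence_network or igraph object.",
        class = "netstab_invalid_input")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Signed co-occurrence network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges (", sum(x$edges$sign == "positive"), "positive /",
      sum(x$edges$sign == "negative"), "negative )\n")
  cat("thresholds: |rho| >", x$params$rho_threshold, ", p <",
      x$params$p_threshold, "\n")
  invisible(x)
}

#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

#' @export
glance.cooccurrence_network <- function(x, ...) topology(x)

#' Topological summary of a network
#'
#' Node/edge counts, mean degree 2E/N, density 2E/(N(N-1)), average unweighted
#' path length and diameter over the largest connected component, mean local
#' clustering coefficient (nodes of degree < 2 contribute 0), modularity of
#' the detected partition, and mean normalized betweenness and closeness
#' centrality (closeness within reachable sets; isolated nodes contribute 0).
#'
#' @param net `cooccurrence_network` or igraph graph.
#' @param partition optional [detect_modules()] result; computed (seed 1) if
#'   missing.
#' @return one-row tibble of metrics.
#' @export
topology <- function(net, partition = NULL) {
  g <- as_netstab_graph(net)
  n <- igraph::vcount(g)
  if (n == 0) {
    abort("empty network.", class = "netstab_empty_result")
  }
  e <- igraph::ecount(g)
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  if (igraph::vcount(giant) > 1) {
    dg <- igraph::distances(giant, weights = NA)
    finite <- dg[upper.tri(dg)]
    mean_path <- mean(finite)
    diam <- max(finite)
  } else {
    mean_path <- NA_real_
    diam <- NA_real_
  }
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  cl[igraph::degree(g) < 2] <- 0
  btw <- if (n > 2) igraph::betweenness(g, weights = NA, normalized = TRUE)
         else rep(0, n)
  cls <- suppressWarnings(igraph::closeness(g, weights = NA,
                                            normalized = TRUE))
  cls[!is.finite(cls)] <- 0
  part <- partition %||% (if (e > 0) detect_modules(net, seed = 1) else NULL)
  tibble(
    n_nodes = n, n_edges = e,
    mean_degree = 2 * e / n,
    density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
    mean_path_length = mean_path, diameter = diam,
    mean_clustering = mean(cl),
    modularity = if (is.null(part)) 0 else attr(part, "modularity"),
    n_modules = if (is.null(part)) n else dplyr::n_distinct(part$module),
    mean_betweenness = mean(btw),
    mean_closeness = mean(cls)
  )
}

#' Detect modules by greedy modularity maximization
#'
#' Louvain community detection on the unweighted (edge-presence) graph,
#' deterministic under a fixed seed. An edgeless network yields one module per
#' node with Q = 0.
#'
#' @param net `cooccurrence_network` or igraph graph.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed, or NULL.
#' @return `module_partition` tibble (node, module) with attribute
#'   `modularity`.
#' @export
detect_modules <- function(net, resolution = 1, seed = NULL) {
  g <- as_netstab_graph(net)
  nodes <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  if (igraph::ecount(g) == 0) {
    out <- tibble(node = nodes, module = seq_along(nodes))
    attr(out, "modularity") <- 0
    class(out) <- c("module_partition", class(out))
    return(out)
  }
  comm <- with_seed(seed, igraph::cluster_louvain(
    g, weights = NA, resolution = resolution))
  memb <- igraph::membership(comm)
  out <- tibble(node = nodes, module = as.integer(memb))
  gu <- if ("weight" %in% igraph::edge_attr_names(g)) {
    igraph::delete_edge_attr(g, "weight")
  } else g
  attr(out, "modularity") <- igraph::modularity(gu, memb)
  class(out) <- c("module_partition", class(out))
  out
}

#' Classify node roles from Zi and Pi
#'
#' Vectorized role assignment by the standard thresholds; used by [zipi()].
#'
#' @param zi within-module degree z-scores.
#' @param pi among-module connectivity values.
#' @param zi_threshold,pi_threshold role thresholds.
#' @return factor with levels peripheral, connector, module_hub, network_hub.
#' @export
classify_node_role <- function(zi, pi, zi_threshold = 2.5,
                               pi_threshold = 0.62) {
  role <- dplyr::case_when(
    zi >= zi_threshold & pi < pi_threshold ~ "module_hub",
    zi >= zi_threshold & pi >= pi_threshold ~ "network_hub",
    zi < zi_threshold & pi >= pi_threshold ~ "connector",
    TRUE ~ "peripheral"
  )
  factor(role, levels = c("peripheral", "connector", "module_hub",
                          "network_hub"))
}

#' Within-module degree (Zi) and among-module connectivity (Pi)
#'
#' Computed on unsigned edge presence. `Zi` is the z-score of a node's
#' within-module degree relative to its module (0 when the module sd is 0);
#' `Pi = 1 - sum_s (k_is / k_i)^2` over modules s (0 for isolated nodes).
#' Roles follow the standard thresholds: module hubs (Zi >= 2.5, Pi < 0.62),
#' network hubs (Zi >= 2.5, Pi >= 0.62), connectors (Zi < 2.5, Pi >= 0.62),
#' peripherals (Zi < 2.5, Pi < 0.62). Non-peripheral nodes are the potential
#' keystone taxa.
#'
#' @param net `cooccurrence_network` or igraph graph.
#' @param partition [detect_modules()] result covering every node.
#' @param zi_threshold,pi_threshold role thresholds.
#' @return `node_roles` tibble: node, module, degree, zi, pi, role.
#' @export
zipi <- function(net, partition, zi_threshold = 2.5, pi_threshold = 0.62) {
  g <- as_netstab_graph(net)
  nodes <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  if (!all(nodes %in% partition$node)) {
    abort(paste0("nodes missing from the partition: ",
                 paste(setdiff(nodes, partition$node), collapse = ", ")),
          class = "netstab_invalid_input")
  }
  mod <- partition$module[match(nodes, partition$node)]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  k_total <- rowSums(adj)
  mods <- sort(unique(mod))
  # k_is: links of node i into module s
  k_is <- vapply(mods, function(s) rowSums(adj[, mod == s, drop = FALSE]),
                 numeric(length(nodes)))
  if (length(nodes) == 1) k_is <- matrix(k_is, nrow = 1)
  k_within <- k_is[cbind(seq_along(nodes), match(mod, mods))]
  zi <- numeric(length(nodes))
  for (s in mods) {
    in_s <- mod == s
    mu <- mean(k_within[in_s])
    sg <- sd(k_within[in_s])
    zi[in_s] <- if (!is.na(sg) && sg > 0) (k_within[in_s] - mu) / sg else 0
  }
  pi_ <- unname(ifelse(k_total > 0,
                       1 - rowSums((k_is / pmax(k_total, 1))^2), 0))
  out <- tibble(node = nodes, module = mod, degree = unname(k_total),
                within_degree = unname(k_within), zi = unname(zi), pi = pi_,
                role = classify_node_role(zi, pi_, zi_threshold, pi_threshold))
  class(out) <- c("node_roles", class(out))
  out
}

#' Extract potential keystone taxa from a node-role table
#'
#' Keystones are all non-peripheral nodes (connectors, module hubs, network
#' hubs).
#'
#' @param roles a [zipi()] table.
#' @return character vector of node names.
#' @export
keystone_taxa <- function(roles) {
  as.character(roles$node[roles$role != "peripheral"])
}

#' Export a network as GraphML
#'
#' Node attributes (mean relative abundance) and edge attributes (rho, p,
#' sign) are preserved; the file is readable by Gephi.
#'
#' @param net `cooccurrence_network`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_network_graphml <- function(net, path) {
  g <- as_netstab_graph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export the edge list as TSV
#'
#' @param net `cooccurrence_network`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "cooccurrence_network"))
  readr::write_tsv(net$edges, path)
  invisible(path)
}
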