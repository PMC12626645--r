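# Test utilities: hand-built networks, brute-force oracles, toy tables.

# build a cooccurrence_network directly from an edge data frame, bypassing
# correlation screening, for closed-form graph cases
toy_network <- function(edges, nodes = NULL, abund = NULL) {
  edges <- as.data.frame(edges)
  if (is.null(edges$rho)) edges$rho <- rep(1, nrow(edges))
  if (is.null(edges$p)) edges$p <- rep(1e-6, nrow(edges))
  edges$p_adjusted <- edges$p
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  if (is.null(abund)) abund <- rep(1 / length(nodes), length(nodes))
  node_df <- data.frame(name = nodes, mean_rel_abund = abund)
  edges$weight <- edges$rho
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = node_df)
  structure(list(graph = g,
                 nodes = tibble::as_tibble(node_df),
                 edges = tibble::as_tibble(
                   edges[, c("from", "to", "rho", "p", "p_adjusted", "sign")]),
                 params = list(rho_threshold = NA, p_threshold = NA,
                               correction = "none", n_samples = NA)),
            class = "cooccurrence_network")
}

complete_edges <- function(n, prefix = "v") {
  pr <- t(combn(n, 2))
  data.frame(from = paste0(prefix, pr[, 1]), to = paste0(prefix, pr[, 2]))
}

path_edges <- function(n, prefix = "v") {
  data.frame(from = paste0(prefix, seq_len(n - 1)),
             to = paste0(prefix, seq_len(n - 1) + 1))
}

star_edges <- function(n_leaves) {
  data.frame(from = rep("center", n_leaves),
             to = paste0("leaf", seq_len(n_leaves)))
}

cycle_edges <- function(n, prefix = "v") {
  data.frame(from = paste0(prefix, seq_len(n)),
             to = paste0(prefix, c(seq_len(n - 1) + 1, 1)))
}

random_graph_edges <- function(n, p_edge, seed) {
  set.seed(seed)
  pr <- t(combn(n, 2))
  keep <- runif(nrow(pr)) < p_edge
  data.frame(from = paste0("v", pr[keep, 1]), to = paste0("v", pr[keep, 2]))
}

# all-pairs hop distances by breadth-first search (oracle)
bfs_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
      nxt <- nxt[d[s, nxt] == Inf & nxt != s]
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

adjacency_of <- function(net) {
  igraph::as_adjacency_matrix(net$graph, sparse = FALSE) > 0
}

# adjusted Rand index between two labelings (oracle implementation)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  c2 <- function(x) x * (x - 1) / 2
  sij <- sum(c2(tab))
  sa <- sum(c2(rowSums(tab)))
  sb <- sum(c2(colSums(tab)))
  expected <- sa * sb / c2(length(a))
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# brute-force betaMNTD (direct transcription of the definition)
bmntd_brute <- function(m, tree, weighted = TRUE) {
  d <- stats::cophenetic(tree)[colnames(m), colnames(m)]
  w <- if (weighted) m / rowSums(m) else (m > 0) / rowSums(m > 0)
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (k in seq_len(n - 1)) {
    for (l in (k + 1):n) {
      ik <- which(m[k, ] > 0)
      il <- which(m[l, ] > 0)
      a <- sum(vapply(ik, function(i) w[k, i] * min(d[i, il]), 0))
      b <- sum(vapply(il, function(j) w[l, j] * min(d[j, ik]), 0))
      out[k, l] <- out[l, k] <- 0.5 * (a + b)
    }
  }
  out
}

# small random count table
random_counts <- function(n_samples, n_taxa, seed, depth = 500) {
  set.seed(seed)
  m <- t(vapply(seq_len(n_samples),
                function(i) rmultinom(1, depth,
                                      rexp(n_taxa))[, 1],
                integer(n_taxa)))
  dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                      paste0("t", seq_len(n_taxa)))
  m
}

# planted-signal regression data for importance tests
make_importance_data <- function(seed, n = 100, p = 5, beta = 3, sd = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("k", seq_len(p))))
  list(X = X, y = beta * X[, 1] + rnorm(n, 0, sd))
}
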