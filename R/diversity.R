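#' Per-sample alpha diversity
#'
#' Shannon H = -sum p log p (natural log), Simpson = 1 - sum p^2, Pielou
#' evenness = H / log(observed richness) (missing when only one taxon is
#' present), and bias-corrected Chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1))
#' with F1/F2 the singleton/doubleton counts (defined even when F2 = 0).
#'
#' @param x count matrix (samples x taxa) or data frame.
#' @return tibble: sample_id, shannon, simpson, pielou, chao1.
#' @export
alpha_diversity <- function(x) {
  m <- as_count_matrix(x)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(paste0("empty sample(s): ",
                 paste(rownames(m)[tot <= 0], collapse = ", ")),
          class = "netstab_invalid_input")
  }
  p <- m / tot
  shannon <- unname(apply(p, 1, function(pi) {
    pi <- pi[pi > 0]
    -sum(pi * log(pi))
  }))
  simpson <- unname(1 - rowSums(p^2))
  s_obs <- unname(rowSums(m > 0))
  pielou <- ifelse(s_obs > 1, shannon / log(s_obs), NA_real_)
  f1 <- unname(rowSums(m == 1))
  f2 <- unname(rowSums(m == 2))
  chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  tibble(sample_id = rownames(m), shannon = shannon, simpson = simpson,
         pielou = pielou, chao1 = chao1)
}

#' Pairwise group tests on an alpha-diversity metric
#'
#' Two-sample t-tests (Welch by default) for every pair of groups.
#'
#' @param alpha tibble from [alpha_diversity()].
#' @param groups grouping vector or metadata data frame.
#' @param metric column of `alpha` to test.
#' @param var_equal use Student's pooled-variance t-test instead of Welch.
#' @return tibble of pairwise comparisons.
#' @export
compare_alpha <- function(alpha, groups, metric = "shannon",
                          var_equal = FALSE) {
  g <- resolve_groups(groups, alpha$sample_id)
  vals <- alpha[[metric]]
  pairs <- combn(levels(g), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- vals[g == pairs[1, i]]
    b <- vals[g == pairs[2, i]]
    tt <- t.test(a, b, var.equal = var_equal)
    tibble(metric = metric, group_a = pairs[1, i], group_b = pairs[2, i],
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value)
  })
}

#' Bray-Curtis dissimilarity between samples
#'
#' Computed on relative abundances, so entries are in `[0, 1]`. Bray-Curtis is
#' a semimetric: the triangle inequality is not guaranteed.
#'
#' @param x count matrix (samples x taxa) or data frame.
#' @return a [stats::dist] with sample labels.
#' @export
bray_curtis <- function(x) {
  rel <- relative_abundance(x)
  vegan::vegdist(rel, method = "bray")
}

as_square_dist <- function(d, what = "d") {
  if (inherits(d, "dist")) return(as.matrix(d))
  if (is.matrix(d)) {
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
      abort(sprintf("`%s` must be symmetric.", what),
            class = "netstab_invalid_input")
    }
    return(d)
  }
  abort(sprintf("`%s` must be a dist object or symmetric matrix.", what),
        class = "netstab_invalid_input")
}

#' Principal coordinate analysis (classical scaling)
#'
#' Gower double-centering followed by eigendecomposition. Negative eigenvalues
#' (possible for semimetric input such as Bray-Curtis) are reported but
#' excluded from the proportion-explained denominator; `correction =
#' "cailliez"` applies the additive constant instead.
#'
#' @param d distance matrix ([stats::dist] or symmetric matrix).
#' @param k number of axes to retain (default all positive).
#' @param correction "none" or "cailliez".
#' @return object of class `netstab_pcoa`: eigenvalues, coordinates,
#'   proportion explained.
#' @export
pcoa <- function(d, k = NULL, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  dm <- as_square_dist(d)
  n <- nrow(dm)
  if (any(diag(dm) != 0)) {
    abort("distance matrix must have a zero diagonal.",
          class = "netstab_invalid_input")
  }
  gower_center <- function(dm) {
    a <- -0.5 * dm^2
    b <- sweep(a, 1, rowMeans(a))
    b <- sweep(b, 2, colMeans(a))
    b + mean(a)
  }
  g <- gower_center(dm)
  if (correction == "cailliez" && min(eigen(g, symmetric = TRUE,
                                            only.values = TRUE)$values) < -1e-8) {
    cm <- stats::cmdscale(dm, k = n - 1, eig = TRUE, add = TRUE)
    dm <- as.matrix(stats::dist(cm$points))  # corrected distances are Euclidean
    g <- gower_center(dm)
  }
  ev <- eigen(g, symmetric = TRUE)
  pos <- ev$values > 1e-8 * max(abs(ev$values), 1e-300)
  n_axes <- sum(pos)
  k <- min(k %||% n_axes, n_axes)
  coords <- if (k > 0) {
    ev$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(ev$values[seq_len(k)]), k)
  } else {
    matrix(0, n, 0)
  }
  rownames(coords) <- rownames(dm)
  colnames(coords) <- if (k > 0) paste0("PCo", seq_len(k)) else character()
  prop <- if (n_axes > 0) ev$values[seq_len(n_axes)] / sum(ev$values[pos])
          else numeric()
  structure(list(eigenvalues = ev$values, coordinates = coords,
                 prop_explained = prop, sample_ids = rownames(dm),
                 correction = correction),
            class = "netstab_pcoa")
}

#' @export
print.netstab_pcoa <- function(x, ...) {
  cat("PCoA:", length(x$sample_ids), "samples,",
      ncol(x$coordinates), "retained axes\n")
  if (length(x$prop_explained)) {
    cat("first axes explain:",
        paste0(sprintf("%.1f%%", 100 * head(x$prop_explained, 3)),
               collapse = ", "), "\n")
  }
  invisible(x)
}

run_grouptest <- function(d, groups, n_perm, seed, method) {
  dm <- as_square_dist(d)
  g <- resolve_groups(groups, rownames(dm) %||% as.character(seq_len(nrow(dm))))
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("need >= 2 groups with >= 2 samples each.",
          class = "netstab_invalid_input")
  }
  check_scalar(n_perm, "n_perm", 1, Inf, TRUE)
  dd <- as.dist(dm)
  if (method == "permanova") {
    fit <- with_seed(seed, vegan::adonis2(dd ~ g, permutations = n_perm))
    tibble(method = "permanova", statistic = fit$F[1], r2 = fit$R2[1],
           p_value = fit$`Pr(>F)`[1], n_perm = n_perm,
           seed = as.integer(seed %||% NA))
  } else {
    fit <- with_seed(seed, vegan::anosim(dd, g, permutations = n_perm))
    tibble(method = "anosim", statistic = unname(fit$statistic), r2 = NA_real_,
           p_value = fit$signif, n_perm = n_perm,
           seed = as.integer(seed %||% NA))
  }
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F and R^2 from the Anderson sum-of-squares decomposition with a
#' label-permutation p-value, `p = (1 + #permuted F >= observed) / (1 +
#' n_perm)`.
#'
#' @param d distance matrix.
#' @param groups grouping vector or metadata data frame.
#' @param n_perm number of permutations.
#' @param seed integer seed, or NULL.
#' @return one-row tibble: method, statistic, r2, p_value, n_perm, seed.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  run_grouptest(d, groups, n_perm, seed, "permanova")
}

#' ANOSIM on a distance matrix
#'
#' R = (mean between-group rank - mean within-group rank) / (M/4) with
#' M = n(n-1)/2, bounded in `[-1, 1]`, with a label-permutation p-value.
#'
#' @inheritParams permanova
#' @return one-row tibble as in [permanova()] (r2 is NA for ANOSIM).
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL) {
  run_grouptest(d, groups, n_perm, seed, "anosim")
}
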