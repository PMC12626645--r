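align_tree_taxa <- function(m, tree) {
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing)) {
    abort(paste0("taxa missing from the tree: ",
                 paste(missing, collapse = ", ")),
          class = "netstab_invalid_input")
  }
  stats::cophenetic(tree)[colnames(m), colnames(m)]
}

community_weights <- function(m, weighted) {
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(paste0("empty sample(s): ",
                 paste(rownames(m)[tot <= 0], collapse = ", ")),
          class = "netstab_invalid_input")
  }
  if (weighted) m / tot else (m > 0) / rowSums(m > 0)
}

#' Between-community mean nearest taxon distance
#'
#' For each sample pair, the abundance-weighted (or, unweighted, the
#' richness-weighted) mean of each taxon's patristic distance to its nearest
#' relative in the paired community, averaged over both directions.
#'
#' @param x count matrix (samples x taxa) or data frame.
#' @param tree phylogeny whose tips cover all taxa in `x`.
#' @param weighted weight by relative abundance (default) or presence.
#' @return a [stats::dist] of betaMNTD values.
#' @export
bmntd <- function(x, tree, weighted = TRUE) {
  m <- as_count_matrix(x)
  d <- align_tree_taxa(m, tree)
  w <- community_weights(m, weighted)
  out <- bmntd_cpp(w, d)
  dimnames(out) <- list(rownames(m), rownames(m))
  as.dist(out)
}

#' Beta nearest taxon index (phylogenetic null model)
#'
#' z-score of observed betaMNTD against a null in which taxon labels are
#' shuffled across the tree tips (richness and abundances preserved):
#' `betaNTI = (obs - mean null) / sd null`. Pairs whose null sd collapses to
#' zero get betaNTI 0 and are flagged in the `degenerate` attribute.
#' `|betaNTI| > 2` indicates deterministic selection (heterogeneous when
#' positive, homogeneous when negative).
#'
#' @inheritParams bmntd
#' @param n_null number of label shuffles (>= 99).
#' @param seed integer seed, or NULL.
#' @return symmetric matrix of betaNTI values with attribute `degenerate`
#'   (logical matrix of sd-zero pairs).
#' @export
bnti <- function(x, tree, n_null = 999, seed = NULL, weighted = TRUE) {
  check_scalar(n_null, "n_null", 99, Inf, TRUE)
  m <- as_count_matrix(x)
  d <- align_tree_taxa(m, tree)
  w <- community_weights(m, weighted)
  obs <- bmntd_cpp(w, d)
  s <- ncol(m)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_null), function(i) sample.int(s), integer(s)))
  })
  nulls <- bmntd_null_cpp(w, d, perms)  # n_null x n_pairs, pairs k<l row-major
  n <- nrow(m)
  mu <- colMeans(nulls)
  sg <- apply(nulls, 2, sd)
  z <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  deg <- matrix(FALSE, n, n, dimnames = dimnames(z))
  col <- 1L
  for (k in seq_len(n - 1)) {
    for (l in seq((k + 1), n)) {
      if (sg[col] > 0) {
        z[k, l] <- z[l, k] <- (obs[k, l] - mu[col]) / sg[col]
      } else {
        deg[k, l] <- deg[l, k] <- TRUE
      }
      col <- col + 1L
    }
  }
  structure(z, degenerate = deg)
}

#' Raup-Crick metric on Bray-Curtis dissimilarity
#'
#' For each sample pair, the observed Bray-Curtis value is ranked within a
#' null distribution of dissimilarities between probabilistically re-assembled
#' communities: each null sample draws its observed richness (selection
#' probability proportional to occupancy across samples) and is filled to its
#' observed total abundance (probability proportional to pool relative
#' abundance). `RC = 2 ((#null < obs) + 0.5 (#null = obs)) / n_null - 1`,
#' bounded in `[-1, 1]`; `RC > 0.95` flags dispersal limitation, `RC < -0.95`
#' homogenizing dispersal.
#'
#' @param x count matrix (samples x taxa) or data frame.
#' @param n_null number of null assemblies.
#' @param seed integer seed, or NULL.
#' @return symmetric matrix of RC values.
#' @export
rc_bray <- function(x, n_null = 999, seed = NULL) {
  check_scalar(n_null, "n_null", 1, Inf, TRUE)
  m <- as_count_matrix(x)
  obs <- as.matrix(bray_curtis(m))
  n <- nrow(m)
  s <- ncol(m)
  occ <- colSums(m > 0)
  pool <- colSums(m)
  if (all(occ == 0)) {
    abort("count table has no occurrences.", class = "netstab_invalid_input")
  }
  rich <- rowSums(m > 0)
  tot <- rowSums(m)
  less <- matrix(0, n, n)
  ties <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      null <- matrix(0, n, s)
      for (k in seq_len(n)) {
        pick <- sample.int(s, rich[k], prob = occ)
        fill <- tot[k] - rich[k]
        cnt <- rep(1, rich[k])
        if (fill > 0) {
          pr <- pool[pick]
          if (sum(pr) <= 0) pr <- rep(1, length(pick))
          cnt <- cnt + rmultinom(1, fill, pr)[, 1]
        }
        null[k, pick] <- cnt
      }
      bc <- as.matrix(vegan::vegdist(null / rowSums(null), method = "bray"))
      less <- less + (bc < obs - 1e-12)
      ties <- ties + (abs(bc - obs) <= 1e-12)
    }
  })
  rc <- 2 * ((less + 0.5 * ties) / n_null) - 1
  diag(rc) <- 0
  dimnames(rc) <- list(rownames(m), rownames(m))
  rc
}

#' Partition sample pairs into five community-assembly processes
#'
#' Each pair is classified exactly once by the standard thresholds:
#' betaNTI > 2, heterogeneous selection; betaNTI < -2, homogeneous selection;
#' otherwise RC > 0.95, dispersal limitation; RC < -0.95, homogenizing
#' dispersal; remaining pairs, drift.
#'
#' @param bnti symmetric betaNTI matrix (from [bnti()]).
#' @param rc symmetric RC matrix (from [rc_bray()]), same samples.
#' @param bnti_threshold selection threshold on |betaNTI|.
#' @param rc_threshold dispersal threshold on |RC|.
#' @return `assembly_partition` object: per-pair tibble plus process fractions
#'   (which always sum to 1).
#' @export
partition_processes <- function(bnti, rc, bnti_threshold = 2,
                                rc_threshold = 0.95) {
  bm <- as_square_dist(bnti, "bnti")
  rm_ <- as_square_dist(rc, "rc")
  if (!identical(dim(bm), dim(rm_)) ||
      !identical(rownames(bm), rownames(rm_))) {
    abort("betaNTI and RC matrices must cover the same sample pairs.",
          class = "netstab_invalid_input")
  }
  n <- nrow(bm)
  idx <- which(upper.tri(bm), arr.ind = TRUE)
  b <- bm[upper.tri(bm)]
  r <- rm_[upper.tri(rm_)]
  process <- dplyr::case_when(
    b > bnti_threshold ~ "heterogeneous_selection",
    b < -bnti_threshold ~ "homogeneous_selection",
    r > rc_threshold ~ "dispersal_limitation",
    r < -rc_threshold ~ "homogenizing_dispersal",
    TRUE ~ "drift"
  )
  lvls <- c("heterogeneous_selection", "homogeneous_selection",
            "dispersal_limitation", "homogenizing_dispersal", "drift")
  pairs <- tibble(
    sample_a = (rownames(bm) %||% as.character(seq_len(n)))[idx[, 1]],
    sample_b = (rownames(bm) %||% as.character(seq_len(n)))[idx[, 2]],
    bnti = b, rc = r, process = factor(process, levels = lvls)
  )
  fr <- as.numeric(table(pairs$process)) / nrow(pairs)
  structure(list(pairs = pairs,
                 fractions = tibble(process = lvls, fraction = fr)),
            class = "assembly_partition")
}

#' @export
print.assembly_partition <- function(x, ...) {
  cat("Assembly partition over", nrow(x$pairs), "sample pairs\n")
  print(x$fractions)
  invisible(x)
}

#' @export
tidy.assembly_partition <- function(x, ...) x$pairs

#' @export
glance.assembly_partition <- function(x, ...) {
  tidyr::pivot_wider(x$fractions, names_from = "process",
                     values_from = "fraction")
}
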