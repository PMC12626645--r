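#' Coerce input to a validated samples-by-taxa count matrix
#'
#' All analysis functions accept either a numeric matrix (samples in rows,
#' taxa in columns, both dimensions named) or a data frame whose first column
#' holds sample identifiers and whose remaining columns are taxon counts.
#'
#' @param x matrix or data frame of counts.
#' @param allow_fractional keep non-integer values (relative abundances are
#'   fine for correlation-based stages); counts read from disk are integer.
#' @return numeric matrix, samples in rows, with unique dimnames.
#' @export
as_count_matrix <- function(x, allow_fractional = TRUE) {
  if (is.data.frame(x)) {
    first <- x[[1]]
    if (is.character(first) || is.factor(first)) {
      m <- as.matrix(x[, -1, drop = FALSE])
      rownames(m) <- as.character(first)
    } else {
      m <- as.matrix(x)
      if (is.null(rownames(m))) rownames(m) <- paste0("sample_", seq_len(nrow(m)))
    }
  } else if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) rownames(m) <- paste0("sample_", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("taxon_", seq_len(ncol(m)))
  } else {
    abort("`x` must be a matrix or data frame of counts.",
          class = "netstab_invalid_input")
  }
  storage.mode(m) <- "double"
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("count table needs at least 2 samples and 2 taxa.",
          class = "netstab_invalid_input")
  }
  if (anyDuplicated(rownames(m))) {
    abort("duplicate sample ids in count table.", class = "netstab_parse_error")
  }
  if (anyDuplicated(colnames(m))) {
    abort("duplicate taxon ids in count table.", class = "netstab_parse_error")
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite count at sample '%s', taxon '%s'.",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]),
          class = "netstab_parse_error")
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative count at sample '%s', taxon '%s'.",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]),
          class = "netstab_parse_error")
  }
  if (!allow_fractional && any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    abort(sprintf("non-integer count at sample '%s', taxon '%s'.",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]),
          class = "netstab_parse_error")
  }
  m
}

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically from
#' the master seed and the stage name, so no stage consumes global randomness.
#'
#' @param master integer master seed.
#' @param stage character stage tag.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# run expr under a local RNG seed without touching the global stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x < lo || x > hi || (integerish && x != round(x))) {
    abort(sprintf("`%s` must be a %s in [%s, %s].", name,
                  if (integerish) "whole number" else "number", lo, hi),
          class = "netstab_invalid_argument")
  }
  invisible(x)
}

# align a grouping vector (or data frame + column) to sample ids
resolve_groups <- function(groups, sample_ids, group_col = "group") {
  if (is.data.frame(groups)) {
    id_col <- intersect(c("sample_id", "sample"), names(groups))[1]
    if (is.na(id_col) || !group_col %in% names(groups)) {
      abort("metadata must contain a sample id column ('sample_id') and the group column.",
            class = "netstab_invalid_input")
    }
    idx <- match(sample_ids, groups[[id_col]])
    if (anyNA(idx)) {
      abort(paste0("samples missing from metadata: ",
                   paste(sample_ids[is.na(idx)], collapse = ", ")),
            class = "netstab_invalid_input")
    }
    g <- groups[[group_col]][idx]
  } else {
    if (length(groups) != length(sample_ids)) {
      abort("`groups` must have one entry per sample.",
            class = "netstab_invalid_input")
    }
    g <- groups
  }
  factor(g)
}
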