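#' Read a count table from TSV
#'
#' Expects taxa as rows and samples as columns (the common OTU-table layout);
#' set `taxa_as_rows = FALSE` for the transposed orientation. The first column
#' must hold identifiers. Cells must be finite non-negative integers.
#'
#' @param path TSV file.
#' @param taxa_as_rows orientation flag.
#' @return samples-by-taxa numeric matrix.
#' @export
read_count_table <- function(path, taxa_as_rows = TRUE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(raw) < 2) {
    abort("count table must have an id column plus at least one data column.",
          class = "netstab_parse_error")
  }
  ids <- as.character(raw[[1]])
  num <- raw[, -1, drop = FALSE]
  bad_col <- names(num)[!vapply(num, is.numeric, TRUE)]
  if (length(bad_col)) {
    abort(paste0("non-numeric column(s): ", paste(bad_col, collapse = ", ")),
          class = "netstab_parse_error")
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (taxa_as_rows) m <- t(m)
  as_count_matrix(m, allow_fractional = FALSE)
}

#' Write a count table as TSV
#'
#' @param x count matrix (samples x taxa) or data frame.
#' @param path output file.
#' @param taxa_as_rows write taxa as rows (default, OTU-table layout).
#' @return invisibly, `path`.
#' @export
write_count_table <- function(x, path, taxa_as_rows = TRUE) {
  m <- as_count_matrix(x)
  if (taxa_as_rows) {
    out <- tibble(taxon_id = colnames(m)) |>
      dplyr::bind_cols(as_tibble(t(m)))
  } else {
    out <- tibble(sample_id = rownames(m)) |>
      dplyr::bind_cols(as_tibble(m))
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with a `sample_id` (or `sample`) column and a group column.
#' @param group_col name of the grouping column.
#' @return tibble.
#' @export
read_sample_metadata <- function(path, group_col = "group") {
  md <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  id_col <- intersect(c("sample_id", "sample"), names(md))[1]
  if (is.na(id_col)) {
    abort("metadata needs a 'sample_id' (or 'sample') column.",
          class = "netstab_parse_error")
  }
  if (!group_col %in% names(md)) {
    abort(sprintf("metadata lacks group column '%s'.", group_col),
          class = "netstab_parse_error")
  }
  if (anyDuplicated(md[[id_col]])) {
    abort("duplicate sample ids in metadata.", class = "netstab_parse_error")
  }
  md
}

#' Convert counts to relative abundances
#'
#' @param x count matrix (samples x taxa) or data frame.
#' @return matrix of proportions; each sample (row) sums to 1.
#' @export
relative_abundance <- function(x) {
  m <- as_count_matrix(x)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(paste0("sample(s) with zero total count: ",
                 paste(rownames(m)[tot <= 0], collapse = ", ")),
          class = "netstab_invalid_input")
  }
  m / tot
}

#' Apply the taxon-inclusion filter
#'
#' Retains taxa whose across-sample mean (or max) relative abundance is
#' strictly above `min_mean_rel_abund` AND which occur (count > 0) in strictly
#' more than `min_prevalence` of samples. Defaults are the conventional
#' 0.1% / one-third screen used before co-occurrence network construction.
#' The operation is idempotent and never alters retained counts.
#'
#' @param x count matrix (samples x taxa) or data frame.
#' @param min_mean_rel_abund abundance threshold (proportion).
#' @param min_prevalence prevalence threshold (proportion of samples).
#' @param abund_stat use the "mean" (default) or "max" relative abundance.
#' @return filtered count matrix, sample set and taxon order unchanged.
#' @export
filter_taxa <- function(x, min_mean_rel_abund = 0.001, min_prevalence = 1 / 3,
                        abund_stat = c("mean", "max")) {
  abund_stat <- match.arg(abund_stat)
  m <- as_count_matrix(x)
  rel <- relative_abundance(m)
  ab <- if (abund_stat == "mean") colMeans(rel) else apply(rel, 2, max)
  prev <- colMeans(m > 0)
  keep <- ab > min_mean_rel_abund & prev > min_prevalence
  if (!any(keep)) {
    abort("all taxa removed by the abundance/prevalence filter.",
          class = "netstab_empty_result")
  }
  m[, keep, drop = FALSE]
}
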