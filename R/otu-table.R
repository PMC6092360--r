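#' Read an OTU count table from TSV
#'
#' Reads a tab-separated community table into the wide tibble layout used
#' throughout the package: one `otu_id` column followed by one integer column
#' per sample. Lines starting with `#` are ignored. Tables stored with samples
#' as rows are transposed on read; when `orientation = "auto"` the choice is
#' made by matching row identifiers against `metadata$sample_id` (falling back
#' to OTUs-as-rows, the amplicon convention).
#'
#' @param path Path to a TSV file whose first column holds identifiers.
#' @param orientation `"auto"`, `"otus_as_rows"` or `"samples_as_rows"`.
#' @param metadata Optional sample metadata tibble (used by `"auto"`).
#' @return A validated wide count tibble.
#' @export
read_otu_table <- function(path,
                           orientation = c("auto", "otus_as_rows", "samples_as_rows"),
                           metadata = NULL) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(raw) < 2) abort("count table needs an ID column plus at least one data column")
  ids <- as.character(raw[[1]])
  if (orientation == "auto") {
    orientation <- "otus_as_rows"
    if (!is.null(metadata) && all(ids %in% metadata$sample_id)) {
      orientation <- "samples_as_rows"
    }
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(m, 2, function(col) all(!is.na(suppressWarnings(as.numeric(col))))))
    abort(paste0("non-numeric cells in column(s): ",
                 paste(colnames(raw)[-1][bad], collapse = ", ")))
  }
  rownames(m) <- ids
  if (orientation == "samples_as_rows") m <- t(m)
  tbl <- matrix_to_table(m)
  validate_otu_table(tbl)
  tbl
}

#' Write an OTU count table to TSV
#'
#' @param x Wide count tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  validate_otu_table(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Read sample metadata from TSV
#'
#' The first column is taken as `sample_id`. A `period` column, when present,
#' is turned into an ordered factor following first appearance in the file.
#'
#' @param path Path to a TSV file.
#' @return A tibble with `sample_id` first.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  names(meta)[1] <- "sample_id"
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    abort(paste0("duplicated sample_id: ",
                 paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", ")))
  }
  if ("period" %in% names(meta) && !is.factor(meta$period)) {
    meta$period <- factor(meta$period, levels = unique(meta$period), ordered = TRUE)
  }
  meta
}

#' Validate a wide OTU count tibble
#'
#' Checks the structural invariants: unique OTU and sample identifiers,
#' non-negative integer counts, at least one OTU and two samples, and strictly
#' positive per-sample totals.
#'
#' @param x Wide count tibble (`otu_id` + sample columns) or matrix.
#' @return `x`, invisibly; errors describe the first violation found.
#' @export
validate_otu_table <- function(x) {
  m <- counts_matrix(x)
  if (nrow(m) < 1) abort("table must contain at least one OTU")
  if (ncol(m) < 2) abort("table must contain at least two samples")
  if (anyDuplicated(rownames(m))) {
    abort(paste0("duplicated OTU ID: ",
                 paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(m))) {
    abort(paste0("duplicated sample ID: ",
                 paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
  }
  if (anyNA(m)) abort("counts contain missing values")
  if (any(m < 0)) abort("counts must be non-negative")
  if (!all(is_whole(m))) {
    idx <- which(!is_whole(m), arr.ind = TRUE)[1, ]
    abort(sprintf("non-integer count at OTU '%s', sample '%s'",
                  rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  if (any(colSums(m) <= 0)) {
    abort(paste0("zero-total sample(s): ",
                 paste(colnames(m)[colSums(m) <= 0], collapse = ", ")))
  }
  invisible(x)
}

#' Remove whole-dataset singletons
#'
#' Drops OTUs whose total read count across all samples is at or below
#' `threshold` (default 1, i.e. classic singleton removal before rarefaction).
#'
#' @param x Wide count tibble.
#' @param threshold Maximum total count removed (default 1).
#' @return Filtered tibble; the number of dropped OTUs is attached as
#'   attribute `n_dropped`.
#' @export
remove_singletons <- function(x, threshold = 1) {
  m <- counts_matrix(x)
  keep <- rowSums(m) > threshold
  out <- matrix_to_table(m[keep, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Drop OTUs with zero counts everywhere
#'
#' @param x Wide count tibble.
#' @return Filtered tibble with attribute `n_dropped`.
#' @export
drop_empty_otus <- function(x) remove_singletons(x, threshold = 0)

#' Rarefy each sample to a common read depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to `depth`. Each sample uses a private RNG stream
#' derived from `seed` and the sample identifier, so the draw for a given
#' sample does not depend on column order.
#'
#' @param x Wide count tibble.
#' @param depth Target reads per sample (>= 1; must not exceed any total).
#' @param seed Integer seed.
#' @return Rarefied count tibble (all column totals equal `depth`).
#' @export
rarefy_counts <- function(x, depth, seed = 1L) {
  m <- counts_matrix(x)
  validate_otu_table(x)
  if (depth < 1) abort("rarefaction depth must be >= 1")
  totals <- colSums(m)
  short <- totals < depth
  if (any(short)) {
    abort(paste0("depth ", depth, " exceeds total reads of sample(s): ",
                 paste(colnames(m)[short], collapse = ", ")))
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    if (totals[j] == depth) next
    cnt <- round(m[, j])
    reads <- rep.int(seq_along(cnt), cnt)
    keep <- with_local_seed(derive_seed(seed, colnames(m)[j]),
                            sample(reads, depth))
    out[, j] <- tabulate(keep, nbins = nrow(m))
  }
  matrix_to_table(out)
}

#' Per-sample relative abundances
#'
#' Divides each sample column by its total so every column sums to one.
#'
#' @param x Wide count tibble.
#' @return Tibble of the same shape holding proportions.
#' @export
relative_abundance <- function(x) {
  m <- counts_matrix(x)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort(paste0("zero-total sample(s): ",
                 paste(colnames(m)[totals <= 0], collapse = ", ")))
  }
  matrix_to_table(sweep(m, 2, totals, "/"))
}
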