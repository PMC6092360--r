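#' Classify OTUs into six abundance categories
#'
#' Applies per-sample relative-abundance rules over each OTU's minimum and
#' maximum across samples:
#' \describe{
#'   \item{AAT}{always abundant, min >= `abundant_cut`}
#'   \item{CAT}{conditionally abundant, min >= `rare_cut` and max >= `abundant_cut`}
#'   \item{ART}{always rare, max < `rare_cut`}
#'   \item{CRT}{conditionally rare, min < `rare_cut` and max < `abundant_cut`}
#'   \item{MT}{moderate, min >= `rare_cut` and max < `abundant_cut`}
#'   \item{CRAT}{conditionally rare and abundant, min < `rare_cut` and max >= `abundant_cut`}
#' }
#' Abundant thresholds are inclusive (`>=`), rare thresholds strict (`<`), so
#' the six rules partition the (min, max) plane and exactly one fires per OTU.
#' The roll-up groups AAT+CAT as AT (abundant taxa) and ART+CRT as RT (rare
#' taxa).
#'
#' @param rel Relative-abundance tibble (from [relative_abundance()]).
#' @param abundant_cut Abundant threshold as a proportion (default 0.01 = 1%).
#' @param rare_cut Rare threshold as a proportion (default 1e-4 = 0.01%).
#' @return Tibble with `otu_id`, `min_rel`, `max_rel`, `mean_rel`, `category`,
#'   `rollup`.
#' @export
classify_otus <- function(rel, abundant_cut = 0.01, rare_cut = 1e-4) {
  if (!(rare_cut > 0 && rare_cut < abundant_cut && abundant_cut < 1)) {
    abort("thresholds must satisfy 0 < rare_cut < abundant_cut < 1")
  }
  m <- counts_matrix(rel)
  mins <- apply(m, 1, min)
  maxs <- apply(m, 1, max)
  category <- dplyr::case_when(
    mins >= abundant_cut ~ "AAT",
    maxs < rare_cut ~ "ART",
    mins >= rare_cut & maxs >= abundant_cut ~ "CAT",
    mins < rare_cut & maxs >= abundant_cut ~ "CRAT",
    mins >= rare_cut ~ "MT",
    TRUE ~ "CRT"
  )
  rollup <- dplyr::case_when(
    category %in% c("AAT", "CAT") ~ "AT",
    category %in% c("ART", "CRT") ~ "RT",
    TRUE ~ category
  )
  tibble::tibble(
    otu_id = rownames(m),
    min_rel = unname(mins),
    max_rel = unname(maxs),
    mean_rel = unname(rowMeans(m)),
    category = factor(category, levels = c("AAT", "CAT", "ART", "CRT", "MT", "CRAT")),
    rollup = factor(rollup, levels = c("AT", "RT", "MT", "CRAT"))
  )
}

#' Summarise an abundance classification
#'
#' Counts OTUs (and, when counts are supplied, reads) per category or roll-up
#' group, with percentages of the whole table.
#'
#' @param classes Output of [classify_otus()].
#' @param counts Optional count tibble for read shares.
#' @param by `"rollup"` (default) or `"category"`.
#' @return Tibble with `group`, `n_otus`, `pct_otus` (and `pct_reads`).
#' @export
class_summary <- function(classes, counts = NULL, by = c("rollup", "category")) {
  by <- match.arg(by)
  grp <- classes[[by]]
  out <- dplyr::count(tibble::tibble(group = grp), .data$group,
                      name = "n_otus", .drop = FALSE)
  out$pct_otus <- round(100 * out$n_otus / nrow(classes), 2)
  if (!is.null(counts)) {
    m <- counts_matrix(counts)
    reads <- rowSums(m)[classes$otu_id]
    tot <- vapply(split(reads, grp), sum, numeric(1))
    out$pct_reads <- round(100 * tot[as.character(out$group)] / sum(m), 2)
  }
  out
}

#' Split a count table into roll-up subcommunities
#'
#' Partitions the OTU set by roll-up label (AT, RT, MT, CRAT) leaving counts
#' untouched. Empty subcommunities are kept as zero-row tibbles so the result
#' always covers the four groups.
#'
#' @param x Wide count tibble.
#' @param classes Output of [classify_otus()] covering every OTU in `x`.
#' @return Named list of count tibbles, one per roll-up label.
#' @export
subcommunity_tables <- function(x, classes) {
  m <- counts_matrix(x)
  missing <- setdiff(rownames(m), classes$otu_id)
  if (length(missing)) {
    abort(paste0("unclassified OTU(s): ", paste(utils::head(missing, 5), collapse = ", ")))
  }
  unknown <- setdiff(classes$otu_id, rownames(m))
  if (length(unknown)) {
    abort(paste0("classification names unknown OTU(s): ",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  roll <- stats::setNames(as.character(classes$rollup), classes$otu_id)
  lapply(stats::setNames(nm = c("AT", "RT", "MT", "CRAT")), function(g) {
    matrix_to_table(m[roll[rownames(m)] == g, , drop = FALSE])
  })
}

#' Shared and unique OTU counts across sample groups (Venn regions)
#'
#' An OTU belongs to a group when it has a positive count in at least one of
#' the group's samples. Every non-empty region of the presence/absence set
#' algebra is counted; region labels join group names with `&`.
#'
#' @param x Wide count tibble.
#' @param metadata Sample metadata with `sample_id` and the grouping column.
#' @param group Name of the grouping column (default `"period"`).
#' @return Tibble with `region` and `n_otus`; counts sum to the number of OTUs
#'   present anywhere.
#' @export
shared_otu_counts <- function(x, metadata, group = "period") {
  m <- counts_matrix(x)
  g <- metadata[[group]][match(colnames(m), metadata$sample_id)]
  if (anyNA(g)) abort("metadata does not cover all samples")
  levs <- if (is.factor(g)) levels(droplevels(g)) else unique(g)
  if (length(levs) < 2) abort("need at least two groups")
  pres <- vapply(levs, function(lv) {
    cols <- which(as.character(g) == lv)
    if (!length(cols)) abort(paste0("group '", lv, "' has no samples"))
    rowSums(m[, cols, drop = FALSE]) > 0
  }, logical(nrow(m)))
  anywhere <- rowSums(pres) > 0
  region <- apply(pres[anywhere, , drop = FALSE], 1, function(p) {
    paste(levs[p], collapse = "&")
  })
  out <- dplyr::count(tibble::tibble(region = region), .data$region, name = "n_otus")
  dplyr::arrange(out, dplyr::desc(.data$n_otus))
}

#' Per-period mean relative abundance and ternary coordinates
#'
#' Averages each OTU's relative abundance over the samples of each period.
#' With exactly three periods, the three means are renormalised to sum to one
#' and reported as ternary coordinates; OTUs absent everywhere are flagged
#' (`defined = FALSE`) and get `NA` coordinates.
#'
#' @param rel Relative-abundance tibble.
#' @param metadata Sample metadata with `sample_id` and the grouping column.
#' @param group Grouping column name (default `"period"`).
#' @return Tibble with `otu_id`, one `mean_<period>` column per period,
#'   ternary `tern_<period>` columns (three periods only) and `defined`.
#' @export
period_mean_abundance <- function(rel, metadata, group = "period") {
  m <- counts_matrix(rel)
  g <- metadata[[group]][match(colnames(m), metadata$sample_id)]
  if (anyNA(g)) abort("metadata does not cover all samples")
  levs <- if (is.factor(g)) levels(droplevels(g)) else unique(g)
  means <- vapply(levs, function(lv) {
    cols <- which(as.character(g) == lv)
    if (!length(cols)) abort(paste0("group '", lv, "' has no samples"))
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  out <- tibble::tibble(otu_id = rownames(m))
  for (lv in levs) out[[paste0("mean_", lv)]] <- unname(means[, lv])
  tot <- rowSums(means)
  out$defined <- tot > 0
  if (length(levs) == 3) {
    tern <- sweep(means, 1, tot, "/")
    tern[tot == 0, ] <- NA_real_
    for (lv in levs) out[[paste0("tern_", lv)]] <- unname(tern[, lv])
  }
  out
}
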