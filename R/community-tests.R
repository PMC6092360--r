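# All permutation p-values in this file use the add-one estimator
# (1 + #{perm >= obs}) / (1 + n_perm), so p is never exactly zero.

anosim_statistic <- function(ranks, within, m) {
  (mean(ranks[!within]) - mean(ranks[within])) / (m / 2)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities exceed
#' within-group dissimilarities. All pairwise distances are midranked;
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` with
#' `M = n(n-1)/2`. R near 1 means groups are well separated, near 0 (or below)
#' random grouping. P is obtained by permuting group labels, or by exhaustive
#' enumeration of all label permutations when `exact = TRUE` (feasible for
#' small n).
#'
#' @param d `dist` of dissimilarities.
#' @param groups Group label per sample (in the order of `d`'s labels).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed.
#' @param exact Enumerate all permutations instead (n <= 8 recommended).
#' @return Tibble with `statistic`, `p_value`, `n_permutations`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1L, exact = FALSE) {
  dm <- dist_to_matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n) abort("one group label per sample required")
  if (any(table(groups) < 2)) abort("every group needs at least two samples")
  v <- upper_vec(dm)
  ranks <- rank(v)  # midranks for ties
  m <- length(v)
  gi <- row(dm)[upper.tri(dm)]
  gj <- col(dm)[upper.tri(dm)]
  within_of <- function(g) g[gi] == g[gj]
  obs <- anosim_statistic(ranks, within_of(groups), m)
  if (exact) {
    perms <- all_permutations(n)
    stats_perm <- apply(perms, 1, function(p) {
      anosim_statistic(ranks, within_of(groups[p]), m)
    })
    p_value <- mean(stats_perm >= obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    stats_perm <- with_local_seed(seed, vapply(seq_len(n_perm), function(i) {
      anosim_statistic(ranks, within_of(sample(groups)), m)
    }, numeric(1)))
    p_value <- (1 + sum(stats_perm >= obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  tibble::tibble(statistic = obs, p_value = p_value, n_permutations = n_used)
}

#' SIMPER contribution of one sample pair
#'
#' Per-OTU share of the Bray-Curtis dissimilarity between two samples:
#' `|x_i - y_i| / sum(x + y)`. The contributions sum exactly to the pair's
#' Bray-Curtis dissimilarity.
#'
#' @param x,y Count vectors on the same OTU axis.
#' @return Numeric vector of per-OTU contributions.
#' @export
simper_pair <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must share the OTU axis")
  abs(x - y) / sum(x + y)
}

#' Similarity-percentage (SIMPER) decomposition
#'
#' Averages [simper_pair()] contributions over all between-group sample pairs
#' and expresses each OTU's share as a percentage of the mean between-group
#' Bray-Curtis dissimilarity, in descending order with cumulative percentages.
#' With more than two groups every group pair is analysed.
#'
#' @param x Wide count tibble.
#' @param metadata Sample metadata with `sample_id` and the grouping column.
#' @param group Grouping column name (default `"period"`).
#' @return Tibble with `comparison`, `otu_id`, `contribution`, `pct`,
#'   `cum_pct`, plus attribute `mean_dissimilarity` (named by comparison).
#' @export
simper_analysis <- function(x, metadata, group = "period") {
  m <- counts_matrix(x)
  g <- as.character(metadata[[group]][match(colnames(m), metadata$sample_id)])
  if (anyNA(g)) abort("metadata does not cover all samples")
  levs <- unique(g)
  if (length(levs) < 2) abort("need at least two groups")
  combos <- utils::combn(levs, 2)
  mean_bc <- numeric(0)
  res <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    g1 <- which(g == combos[1, k]); g2 <- which(g == combos[2, k])
    contrib <- Reduce(`+`, lapply(g1, function(i) {
      rowSums(vapply(g2, function(j) simper_pair(m[, i], m[, j]),
                     numeric(nrow(m))))
    })) / (length(g1) * length(g2))
    label <- paste(combos[, k], collapse = " vs ")
    mean_bc[label] <<- sum(contrib)
    out <- tibble::tibble(
      comparison = label,
      otu_id = rownames(m),
      contribution = unname(contrib),
      pct = 100 * unname(contrib) / sum(contrib)
    )
    out <- dplyr::arrange(out, dplyr::desc(.data$contribution))
    out$cum_pct <- cumsum(out$pct)
    out
  })
  attr(res, "mean_dissimilarity") <- mean_bc
  res
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper triangles of two sample-matched distance matrices
#' (Spearman by default) and assesses significance by simultaneously permuting
#' the rows and columns of the second matrix.
#'
#' @param d_a,d_b `dist` objects (or square matrices) over the same samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Tibble with `statistic`, `p_value`, `n_permutations`.
#' @export
mantel_test <- function(d_a, d_b, method = c("spearman", "pearson"),
                        n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  ma <- dist_to_matrix(d_a)
  mb <- dist_to_matrix(d_b)
  if (!identical(dim(ma), dim(mb))) abort("distance matrices must match")
  if (!is.null(rownames(ma)) && !is.null(rownames(mb))) {
    if (!identical(rownames(ma), rownames(mb))) {
      if (!setequal(rownames(ma), rownames(mb))) abort("sample sets differ")
      mb <- mb[rownames(ma), rownames(ma)]
    }
  }
  ut <- upper.tri(ma)
  va <- ma[ut]
  if (method == "spearman") va <- rank(va)
  corr <- function(mat) {
    vb <- mat[ut]
    if (method == "spearman") vb <- rank(vb)
    stats::cor(va, vb)
  }
  obs <- corr(mb)
  n <- nrow(ma)
  stats_perm <- with_local_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample(n)
    corr(mb[idx, idx])
  }, numeric(1)))
  p_value <- (1 + sum(stats_perm >= obs - 1e-12)) / (1 + n_perm)
  tibble::tibble(statistic = obs, p_value = p_value, n_permutations = n_perm)
}

#' Environmental distance matrix for one variable
#'
#' Absolute pairwise differences of a (transformed) metadata variable.
#' Numeric variables are `log(x + 1)` transformed by default, except pH which
#' is used raw; the ordered factors period and depth are coded ordinally
#' before differencing. Samples with a missing value are dropped pairwise and
#' the number removed is attached as attribute `n_dropped`.
#'
#' @param metadata Sample metadata tibble with `sample_id`.
#' @param variable Column name.
#' @param transform `"auto"` (log1p except pH and factors), `"log1p"`,
#'   `"log10p1"` or `"none"`.
#' @return `dist` over the retained samples.
#' @export
env_distance <- function(metadata, variable,
                         transform = c("auto", "log1p", "log10p1", "none")) {
  transform <- match.arg(transform)
  if (!variable %in% names(metadata)) abort(paste0("no such variable: ", variable))
  v <- metadata[[variable]]
  ids <- metadata$sample_id
  if (is.factor(v) || is.character(v)) {
    v <- as.numeric(factor(v, levels = if (is.factor(v)) levels(v) else unique(v)))
  } else {
    do_log <- switch(transform,
                     auto = !grepl("^ph$", variable, ignore.case = TRUE),
                     log1p = TRUE, log10p1 = TRUE, none = FALSE)
    if (do_log) v <- if (transform == "log10p1") log10(v + 1) else log1p(v)
  }
  keep <- is.finite(v)
  d <- stats::as.dist(abs(outer(v[keep], v[keep], "-")))
  attr(d, "Labels") <- ids[keep]
  attr(d, "n_dropped") <- sum(!keep)
  d
}

#' Mantel screen of community distance against environmental variables
#'
#' Runs [mantel_test()] of a community distance matrix against
#' [env_distance()] for each requested variable, mirroring a
#' variable-by-subcommunity Mantel table.
#'
#' @param d Community `dist`.
#' @param metadata Sample metadata.
#' @param variables Character vector of metadata columns.
#' @param ... Passed to [mantel_test()].
#' @return Tibble with `variable`, `statistic`, `p_value`.
#' @export
mantel_env_screen <- function(d, metadata, variables, ...) {
  ids <- attr(stats::as.dist(dist_to_matrix(d)), "Labels") %||% rownames(dist_to_matrix(d))
  purrr::map_dfr(variables, function(v) {
    de <- env_distance(metadata, v)
    common <- intersect(ids, attr(de, "Labels"))
    dm <- dist_to_matrix(d)[common, common]
    dem <- dist_to_matrix(de)[common, common]
    res <- mantel_test(dm, dem, ...)
    tibble::add_column(res, variable = v, .before = 1)
  })
}

indval_components <- function(relm, g) {
  levs <- unique(g)
  # group mean relative abundance (OTUs x groups)
  gm <- sapply(levs, function(lv) rowMeans(relm[, g == lv, drop = FALSE]))
  a <- gm / pmax(rowSums(gm), .Machine$double.eps)
  b <- sapply(levs, function(lv) rowMeans(relm[, g == lv, drop = FALSE] > 0))
  list(levels = levs, a = a, b = b, stat = sqrt(a * b))
}

#' Indicator-value (IndVal) screening of group-associated OTUs
#'
#' For each OTU and group g: specificity `A` is the group mean relative
#' abundance divided by the sum of group means (group-size equalised), and
#' fidelity `B` is the fraction of g's samples in which the OTU occurs. The
#' indicator statistic is `sqrt(A * B)`; the best (argmax) group is reported.
#' P-values come from permuting sample labels (the permuted statistic is the
#' best-group statistic of the permuted table). Records are filtered to
#' `stat > stat_threshold` and `p_value < p_threshold` unless `filter = FALSE`.
#'
#' @param x Wide count tibble.
#' @param metadata Sample metadata with `sample_id` and the grouping column.
#' @param group Grouping column name (default `"period"`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param stat_threshold Indicator-value cutoff (default 0.7).
#' @param p_threshold Significance cutoff (default 0.05).
#' @param filter Apply the thresholds (default `TRUE`).
#' @return Tibble with `otu_id`, `best_group`, `A`, `B`, `stat`, `p_value`;
#'   OTUs absent everywhere are skipped (count in attribute `n_skipped`).
#' @export
indval <- function(x, metadata, group = "period", n_perm = 999, seed = 1L,
                   stat_threshold = 0.7, p_threshold = 0.05, filter = TRUE) {
  m <- counts_matrix(x)
  g <- as.character(metadata[[group]][match(colnames(m), metadata$sample_id)])
  if (anyNA(g)) abort("metadata does not cover all samples")
  if (length(unique(g)) < 2) abort("need at least two groups")
  present <- rowSums(m) > 0
  n_skipped <- sum(!present)
  m <- m[present, , drop = FALSE]
  relm <- sweep(m, 2, colSums(m), "/")
  comp <- indval_components(relm, g)
  best <- max.col(comp$stat, ties.method = "first")
  obs <- comp$stat[cbind(seq_len(nrow(relm)), best)]
  exceed <- rep(0, nrow(relm))
  with_local_seed(seed, {
    for (i in seq_len(n_perm)) {
      gp <- sample(g)
      sp <- indval_components(relm, gp)$stat
      exceed <- exceed + (apply(sp, 1, max) >= obs - 1e-12)
    }
  })
  p_value <- (1 + exceed) / (1 + n_perm)
  out <- tibble::tibble(
    otu_id = rownames(m),
    best_group = comp$levels[best],
    A = comp$a[cbind(seq_len(nrow(relm)), best)],
    B = comp$b[cbind(seq_len(nrow(relm)), best)],
    stat = unname(obs),
    p_value = unname(p_value)
  )
  if (filter) out <- out[out$stat > stat_threshold & out$p_value < p_threshold, ]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Count strict indicators per group
#'
#' @param indicators Output of [indval()].
#' @return Tibble with one row per group plus a `total` row.
#' @export
indicator_counts <- function(indicators) {
  per <- dplyr::count(indicators, .data$best_group, name = "n_indicators")
  dplyr::bind_rows(
    per,
    tibble::tibble(best_group = "total", n_indicators = sum(per$n_indicators))
  )
}
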