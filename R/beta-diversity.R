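#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities between samples,
#' `1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, via [vegan::vegdist()].
#'
#' @param x Wide count tibble.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(x) {
  m <- counts_matrix(x)
  if (ncol(m) < 2) abort("need at least two samples")
  if (any(colSums(m) <= 0)) {
    abort(paste0("zero-total sample(s): ",
                 paste(colnames(m)[colSums(m) <= 0], collapse = ", ")))
  }
  vegan::vegdist(t(m), method = "bray")
}

#' Partition Bray-Curtis dissimilarity for one sample pair
#'
#' Decomposes abundance-based dissimilarity into the balanced-variation
#' component (substitution of individuals of some species by individuals of
#' others) and the abundance-gradient component (uniform loss of individuals
#' from one sample to the other). With `A = sum(min)`, `B = sum(x - min)`,
#' `C = sum(y - min)`:
#' `total = (B + C) / (2A + B + C)`, `balanced = min(B, C) / (A + min(B, C))`,
#' `gradient = total - balanced`. The two components add exactly to the total.
#'
#' @param x,y Count vectors on the same OTU axis.
#' @return Tibble with `total`, `balanced`, `gradient`.
#' @export
partition_bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must share the OTU axis")
  if (sum(x) <= 0 || sum(y) <= 0) abort("both samples need positive totals")
  a <- sum(pmin(x, y))
  b <- sum(x) - a
  cc <- sum(y) - a
  total <- (b + cc) / (2 * a + b + cc)
  balanced <- if (min(b, cc) == 0) 0 else min(b, cc) / (a + min(b, cc))
  tibble::tibble(total = total, balanced = balanced, gradient = total - balanced)
}

#' Pairwise Bray-Curtis partition over all sample pairs
#'
#' @param x Wide count tibble.
#' @return Long tibble with `sample_i`, `sample_j`, `total`, `balanced`,
#'   `gradient` for every unordered sample pair.
#' @export
bray_partition_pairs <- function(x) {
  m <- counts_matrix(x)
  n <- ncol(m)
  pairs <- utils::combn(n, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    out <- partition_bray_curtis(m[, i], m[, j])
    tibble::add_column(out,
                       sample_i = colnames(m)[i],
                       sample_j = colnames(m)[j], .before = 1)
  })
}

#' Time-lag regression of community dissimilarity
#'
#' Regresses pairwise dissimilarity on the absolute difference in sampling
#' date index over all unordered sample pairs (ordinary least squares). A
#' positive slope indicates directional community change; significance is the
#' regression t test on the slope.
#'
#' @param d `dist` of pairwise dissimilarities.
#' @param metadata Sample metadata with `sample_id` and the date column.
#' @param date_col Column holding the sampling-event ordinal (default
#'   `"date_index"`).
#' @param sqrt_lag Regress on the square root of the lag instead (classic
#'   time-lag-analysis variant; default `FALSE`).
#' @return Object of class `timelag_fit` wrapping the `lm` fit, with the pair
#'   table in `$pairs`.
#' @export
time_lag_regression <- function(d, metadata, date_col = "date_index",
                                sqrt_lag = FALSE) {
  dm <- dist_to_matrix(d)
  dates <- metadata[[date_col]][match(rownames(dm), metadata$sample_id)]
  if (anyNA(dates)) abort("metadata does not cover all samples")
  lagm <- abs(outer(dates, dates, "-"))
  pairs <- tibble::tibble(
    sample_i = rownames(dm)[row(dm)[upper.tri(dm)]],
    sample_j = colnames(dm)[col(dm)[upper.tri(dm)]],
    lag = upper_vec(lagm),
    dissimilarity = upper_vec(dm)
  )
  if (length(unique(pairs$lag)) < 3) abort("need at least three distinct lags")
  pairs$x <- if (sqrt_lag) sqrt(pairs$lag) else pairs$lag
  fit <- stats::lm(dissimilarity ~ x, data = pairs)
  sm <- summary(fit)
  out <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n_pairs = nrow(pairs),
    sqrt_lag = sqrt_lag,
    lm = fit,
    pairs = pairs[, c("sample_i", "sample_j", "lag", "dissimilarity")]
  )
  class(out) <- "timelag_fit"
  out
}

#' @export
print.timelag_fit <- function(x, ...) {
  cat("Time-lag regression of community dissimilarity\n")
  cat(sprintf("  slope %.4f per lag unit (P = %.3g), R^2 = %.3f, %d pairs\n",
              x$slope, x$p_value, x$r_squared, x$n_pairs))
  invisible(x)
}

#' @export
tidy.timelag_fit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("intercept", "lag"),
    estimate = sm[, 1], std_error = sm[, 2],
    statistic = sm[, 3], p_value = sm[, 4]
  )
}

#' @export
glance.timelag_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, p_value = x$p_value,
                 n_pairs = x$n_pairs)
}

#' @export
autoplot.timelag_fit <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$lag, .data$dissimilarity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "Time lag (sampling events)",
                  y = "Bray-Curtis dissimilarity")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Wraps [vegan::metaMDS()] with a fixed seed; coordinates are centred and the
#' Kruskal stress-1 of the best solution is attached.
#'
#' @param d `dist` object.
#' @param k Number of dimensions (default 2).
#' @param seed Integer seed for the random restarts.
#' @param trymax Maximum random restarts (default 20).
#' @return Tibble of sample coordinates (`sample_id`, `NMDS1`, ...) with
#'   attributes `stress` and `converged`.
#' @export
nmds_ordination <- function(d, k = 2, seed = 1L, trymax = 20) {
  if (k < 2) abort("k must be >= 2")
  fit <- with_local_seed(seed,
    vegan::metaMDS(stats::as.dist(dist_to_matrix(d)), k = k, trace = 0,
                   trymax = trymax))
  pts <- vegan::scores(fit, display = "sites")
  out <- tibble::as_tibble(pts)
  out <- tibble::add_column(out, sample_id = rownames(pts), .before = 1)
  attr(out, "stress") <- fit$stress
  attr(out, "converged") <- isTRUE(fit$converged) || fit$converged > 0
  out
}

#' Levins' niche breadth per OTU
#'
#' `B_j = 1 / sum_i P_ij^2`, where `P_ij` is the fraction of OTU j's reads
#' found in sample i. B ranges from 1 (all reads in one sample) to the number
#' of samples (perfectly even use).
#'
#' @param x Wide count or relative-abundance tibble.
#' @param otus Optional subset of OTU IDs.
#' @return Tibble with `otu_id`, `breadth`, `n_samples_present`, `defined`;
#'   OTUs absent everywhere get `NA` breadth and `defined = FALSE`.
#' @export
niche_breadth <- function(x, otus = NULL) {
  m <- counts_matrix(x)
  if (!is.null(otus)) m <- m[rownames(m) %in% otus, , drop = FALSE]
  tot <- rowSums(m)
  p <- sweep(m, 1, ifelse(tot > 0, tot, 1), "/")
  b <- 1 / rowSums(p^2)
  tibble::tibble(
    otu_id = rownames(m),
    breadth = unname(ifelse(tot > 0, b, NA_real_)),
    n_samples_present = unname(as.integer(rowSums(m > 0))),
    defined = unname(tot > 0)
  )
}

#' Abundance-occupancy relationship
#'
#' Occupancy (fraction of samples with a positive count) regressed on
#' log10 mean relative abundance, with the Spearman rank correlation reported
#' alongside the OLS fit.
#'
#' @param x Wide count tibble.
#' @return Object of class `occupancy_fit` with `$data`, `$spearman_rho`,
#'   `$spearman_p`, `$slope`, `$intercept`, `$r_squared`, `$p_value`.
#' @export
abundance_occupancy <- function(x) {
  m <- counts_matrix(x)
  rel <- sweep(m, 2, colSums(m), "/")
  dat <- tibble::tibble(
    otu_id = rownames(m),
    mean_rel = unname(rowMeans(rel)),
    occupancy = unname(rowMeans(m > 0))
  )
  dat <- dat[dat$mean_rel > 0, ]
  if (length(unique(dat$occupancy)) < 3) {
    abort("occupancy is (near-)constant; relationship undefined")
  }
  fit <- stats::lm(occupancy ~ log10(mean_rel), data = dat)
  sm <- summary(fit)
  ct <- suppressWarnings(
    stats::cor.test(dat$mean_rel, dat$occupancy, method = "spearman"))
  out <- list(
    data = dat,
    spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
    slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared, p_value = sm$coefficients[2, 4]
  )
  class(out) <- "occupancy_fit"
  out
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("Abundance-occupancy relationship\n")
  cat(sprintf("  Spearman rho = %.3f (P = %.3g); OLS slope %.3f, R^2 = %.3f\n",
              x$spearman_rho, x$spearman_p, x$slope, x$r_squared))
  invisible(x)
}

#' @export
glance.occupancy_fit <- function(x, ...) {
  tibble::tibble(spearman_rho = x$spearman_rho, spearman_p = x$spearman_p,
                 slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, p_value = x$p_value)
}
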