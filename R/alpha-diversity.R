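#' Per-sample alpha-diversity indices
#'
#' Computes observed richness, Shannon-Wiener diversity (natural log),
#' Gini-Simpson (1 - D), Pielou's evenness and the Chao1 and ACE richness
#' estimators for every sample. Shannon and Simpson come from
#' [vegan::diversity()]; ACE from [vegan::estimateR()] (equal to observed
#' richness when no species has 10 or fewer individuals, so the rare class is
#' empty); Chao1 is the classic estimator `S + F1^2 / (2 F2)` (falling back
#' to `S + F1 (F1 - 1) / 2` when there are no doubletons, and to `S` when
#' there is at most one singleton). A one-species sample has undefined
#' evenness; it is reported as 1 by convention and flagged.
#'
#' @param x Wide count tibble.
#' @return Tibble with one row per sample: `sample_id`, `richness`, `shannon`,
#'   `simpson`, `pielou`, `chao1`, `ace`, `pielou_flagged`.
#' @export
alpha_diversity <- function(x) {
  m <- counts_matrix(x)
  if (any(colSums(m) <= 0)) abort("all-zero sample")
  comm <- t(m)  # vegan wants samples as rows
  shannon <- vegan::diversity(comm, index = "shannon")
  simpson <- vegan::diversity(comm, index = "simpson")
  richness <- rowSums(comm > 0)
  est <- t(vegan::estimateR(round(comm)))
  chao1 <- vapply(seq_len(nrow(comm)), function(i) {
    chao1_classic(round(comm[i, ]))
  }, numeric(1))
  ace <- ifelse(is.nan(est[, "S.ACE"]), richness, est[, "S.ACE"])
  pielou_flag <- richness == 1
  pielou <- ifelse(pielou_flag, 1, shannon / log(richness))
  tibble::tibble(
    sample_id = colnames(m),
    richness = as.integer(richness),
    shannon = unname(shannon),
    simpson = unname(simpson),
    pielou = unname(pielou),
    chao1 = unname(chao1),
    ace = unname(ace),
    pielou_flagged = unname(pielou_flag)
  )
}

chao1_classic <- function(counts) {
  s <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s + f1^2 / (2 * f2)
  else if (f1 > 1) s + f1 * (f1 - 1) / 2
  else s
}

#' Truncated Preston log-normal fit of the pooled species-abundance curve
#'
#' Pools counts over samples (or accepts a single abundance vector), bins them
#' into doubling octaves with the standard half-split of boundary counts, and
#' fits a Gaussian to octave frequencies truncated at the veil line
#' ([vegan::prestonfit()]). Extrapolated richness is the area under the
#' untruncated Gaussian ([vegan::veiledspec()]); `sampled_fraction` is
#' observed over extrapolated richness, i.e. the share of the regional pool
#' the survey recovered.
#'
#' @param x Wide count tibble or a numeric abundance vector.
#' @return Object of class `preston_fit` with `mode`, `width`, `s0`, `s_obs`,
#'   `s_est`, `sampled_fraction` and the underlying vegan fit.
#' @export
preston_fit <- function(x) {
  ab <- if (is.numeric(x) && is.null(dim(x))) x else rowSums(counts_matrix(x))
  ab <- ab[ab > 0]
  octaves <- unique(pmax(0, ceiling(log2(ab))))
  if (length(octaves) < 3) abort("need at least three occupied octaves for a Preston fit")
  fit <- vegan::prestonfit(ab, tiesplit = TRUE)
  veiled <- vegan::veiledspec(fit)
  out <- list(
    mode = unname(fit$coefficients["mode"]),
    width = unname(fit$coefficients["width"]),
    s0 = unname(fit$coefficients["S0"]),
    s_obs = length(ab),
    s_est = unname(veiled["Extrapolated"]),
    sampled_fraction = length(ab) / unname(veiled["Extrapolated"]),
    vegan_fit = fit
  )
  class(out) <- "preston_fit"
  out
}

#' @export
print.preston_fit <- function(x, ...) {
  cat("Truncated Preston log-normal fit\n")
  cat(sprintf("  mode %.3f, width %.3f, S0 %.2f\n", x$mode, x$width, x$s0))
  cat(sprintf("  observed richness %d, extrapolated %.1f (%.1f%% sampled)\n",
              x$s_obs, x$s_est, 100 * x$sampled_fraction))
  invisible(x)
}

#' @export
glance.preston_fit <- function(x, ...) {
  tibble::tibble(mode = x$mode, width = x$width, s0 = x$s0,
                 s_obs = x$s_obs, s_est = x$s_est,
                 sampled_fraction = x$sampled_fraction)
}

#' Two-way fixed-effects ANOVA
#'
#' Crossed two-factor ANOVA with interaction on a per-sample response, using
#' type-II sums of squares (robust when the design is mildly unbalanced; for a
#' balanced design the types coincide).
#'
#' @param data Data frame holding the response and both factors.
#' @param value Response column name.
#' @param factor_a,factor_b Factor column names.
#' @return Tibble with `effect`, `df`, `sum_sq`, `f_statistic`, `p_value`.
#' @export
two_way_anova <- function(data, value, factor_a, factor_b) {
  a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]])
  if (nlevels(a) < 2 || nlevels(b) < 2) abort("both factors need at least two levels")
  cells <- table(a, b)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("empty design cell: %s x %s",
                  rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  df <- data.frame(y = data[[value]], a = a, b = b)
  fit <- stats::lm(y ~ a * b, data = df)
  tab <- car::Anova(fit, type = 2)
  effects <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "Residuals")
  tibble::tibble(
    effect = effects,
    df = tab$Df,
    sum_sq = tab$`Sum Sq`,
    f_statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`
  )
}

#' Two-way ANOVA over all alpha-diversity indices
#'
#' Convenience wrapper running [two_way_anova()] for each index column of an
#' [alpha_diversity()] table against two metadata factors (typically period
#' and depth).
#'
#' @param alpha Output of [alpha_diversity()].
#' @param metadata Sample metadata with `sample_id` and both factors.
#' @param factor_a,factor_b Metadata column names (defaults `"period"`,
#'   `"depth"`).
#' @return Long tibble with `index`, `effect`, `df`, `f_statistic`, `p_value`.
#' @export
alpha_anova <- function(alpha, metadata, factor_a = "period", factor_b = "depth") {
  joined <- dplyr::inner_join(alpha, metadata, by = "sample_id")
  indices <- intersect(c("richness", "shannon", "simpson", "pielou", "chao1", "ace"),
                       names(alpha))
  purrr::map_dfr(indices, function(idx) {
    res <- two_way_anova(joined, idx, factor_a, factor_b)
    res <- res[res$effect != "Residuals", c("effect", "df", "f_statistic", "p_value")]
    tibble::add_column(res, index = idx, .before = 1)
  })
}
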