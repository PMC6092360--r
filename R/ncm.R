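#' Sloan neutral-model occurrence frequency
#'
#' Predicted occurrence frequency of a taxon with metacommunity mean relative
#' abundance `p` in local communities assembled neutrally with immigration:
#' `1 - pbeta(d, Nm * p, Nm * (1 - p))`, where `Nm` is metacommunity size
#' times immigration rate and `d` the detection limit (the smallest relative
#' abundance detectable, typically one read over the sequencing depth).
#' Boundary abundances p = 0 / p = 1 return 0 / 1.
#'
#' @param p Mean relative abundance (vectorised).
#' @param Nm Positive scalar.
#' @param d Detection limit in (0, 1).
#' @return Predicted occurrence frequencies in `[0, 1]`.
#' @export
ncm_predict <- function(p, Nm, d) {
  if (Nm <= 0) abort("Nm must be positive")
  if (d <= 0 || d >= 1) abort("detection limit must lie in (0, 1)")
  out <- ifelse(p <= 0, 0,
                ifelse(p >= 1, 1,
                       1 - stats::pbeta(d, Nm * p, Nm * (1 - p))))
  as.numeric(out)
}

ncm_sse <- function(log_nm, p, obs, d) {
  sum((obs - ncm_predict(p, exp(log_nm), d))^2)
}

#' Fit the Sloan neutral community model
#'
#' Estimates `Nm` by bounded nonlinear least squares of predicted versus
#' observed occurrence frequency across OTUs. Observed frequency is occupancy
#' (fraction of samples with a positive count); `p` is the mean relative
#' abundance across samples, zeros included. The detection limit defaults to
#' one read at the common sequencing depth (`d = 1/N`). Optimisation runs over
#' `log(Nm)` within `[1, 1e7]` from three deterministic starting points.
#' A 95% Wilson binomial envelope around the fitted curve partitions OTUs
#' into those occurring more often (`above`), as often (`within`) or less
#' often (`below`) than the neutral expectation. `r_squared` is
#' `1 - SSE/SStot` and is deliberately not clamped at zero.
#'
#' @param x Wide count tibble (typically rarefied).
#' @param d Detection limit; default `1/N` with `N` the (median) column total.
#' @param conf Envelope confidence level (default 0.95).
#' @return Object of class `ncm_fit`: `Nm`, `r_squared`, `N`, `d`, and a
#'   per-OTU tibble `$otus` (`otu_id`, `p`, `obs_freq`, `pred_freq`, `lower`,
#'   `upper`, `partition`).
#' @export
ncm_fit <- function(x, d = NULL, conf = 0.95) {
  m <- counts_matrix(x)
  n_samples <- ncol(m)
  N <- stats::median(colSums(m))
  if (is.null(d)) d <- 1 / N
  rel <- sweep(m, 2, colSums(m), "/")
  p <- rowMeans(rel)
  obs <- rowMeans(m > 0)
  keep <- p > 0
  fit <- ncm_fit_freq(p[keep], obs[keep], d = d, n_samples = n_samples,
                      conf = conf, otu_ids = rownames(m)[keep])
  fit$N <- N
  fit
}

#' Fit the Sloan model to occupancy-abundance pairs directly
#'
#' The fitting core of [ncm_fit()], usable when mean relative abundances and
#' observed occurrence frequencies are already at hand.
#'
#' @param p Mean relative abundances (positive).
#' @param obs_freq Observed occurrence frequencies in `[0, 1]`.
#' @param d Detection limit in (0, 1).
#' @param n_samples Number of samples behind the frequencies (for the Wilson
#'   envelope).
#' @param conf Envelope confidence level (default 0.95).
#' @param otu_ids Optional identifiers.
#' @return An `ncm_fit` object (with `N = NA`).
#' @export
ncm_fit_freq <- function(p, obs_freq, d, n_samples, conf = 0.95,
                         otu_ids = NULL) {
  if (length(p) < 3) abort("too few OTUs with positive abundance")
  if (any(p <= 0)) abort("p must be positive")
  obs <- obs_freq
  starts <- log(c(10, 1e3, 1e5))
  fits <- lapply(starts, function(s) {
    stats::nlminb(s, ncm_sse, lower = log(1), upper = log(1e7),
                  p = p, obs = obs, d = d)
  })
  ok <- vapply(fits, function(f) f$convergence %in% c(0, 1), logical(1))
  if (!any(ok)) {
    abort(sprintf("Nm optimisation failed to converge (bounds [1, 1e7], best residual %.4g)",
                  min(vapply(fits, `[[`, numeric(1), "objective"))))
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  Nm <- exp(best$par)
  pred <- ncm_predict(p, Nm, d)
  sse <- sum((obs - pred)^2)
  sstot <- sum((obs - mean(obs))^2)
  r_squared <- 1 - sse / sstot
  ci <- wilson_interval(pred, n_samples, conf)
  partition <- dplyr::case_when(
    obs > ci$upper ~ "above",
    obs < ci$lower ~ "below",
    TRUE ~ "within"
  )
  out <- list(
    Nm = Nm, r_squared = r_squared, N = NA_real_, d = d, conf = conf,
    n_samples = n_samples,
    otus = tibble::tibble(
      otu_id = otu_ids %||% paste0("OTU", seq_along(p)),
      p = unname(p), obs_freq = unname(obs),
      pred_freq = unname(pred), lower = ci$lower, upper = ci$upper,
      partition = partition
    )
  )
  class(out) <- "ncm_fit"
  out
}

# Wilson score interval for a proportion estimated from n trials.
wilson_interval <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' @export
print.ncm_fit <- function(x, ...) {
  frac <- table(factor(x$otus$partition, levels = c("above", "within", "below")))
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  Nm = %.1f, R^2 = %.3f (N = %d reads, d = %.2e)\n",
              x$Nm, x$r_squared, round(x$N), x$d))
  cat(sprintf("  partition: %d above / %d within / %d below the envelope\n",
              frac["above"], frac["within"], frac["below"]))
  invisible(x)
}

#' @export
tidy.ncm_fit <- function(x, ...) x$otus

#' @export
glance.ncm_fit <- function(x, ...) {
  frac <- prop.table(table(factor(x$otus$partition,
                                  levels = c("above", "within", "below"))))
  tibble::tibble(Nm = x$Nm, r_squared = x$r_squared, N = x$N, d = x$d,
                 n_otus = nrow(x$otus),
                 frac_above = unname(frac["above"]),
                 frac_within = unname(frac["within"]),
                 frac_below = unname(frac["below"]))
}

#' @export
autoplot.ncm_fit <- function(object, ...) {
  dat <- object$otus[order(object$otus$p), ]
  ggplot2::ggplot(dat, ggplot2::aes(log10(.data$p), .data$obs_freq)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$partition), alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_freq)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = "dashed") +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = "Occurrence frequency",
                  colour = "vs neutral envelope")
}
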