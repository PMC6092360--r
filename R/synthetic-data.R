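# Community simulators. All generators are deterministic under `seed` and
# return their ground truth alongside the data so every downstream stage can
# be tested against known structure.

rdirichlet_one <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

lognormal_sad <- function(n_otus, meanlog, sdlog) {
  p <- stats::rlnorm(n_otus, meanlog = meanlog, sdlog = sdlog)
  p / sum(p)
}

sample_names <- function(n) sprintf("S%02d", seq_len(n))
otu_names <- function(n) sprintf("OTU%04d", seq_len(n))

#' Simulate a neutrally assembled OTU table
#'
#' Draws metacommunity relative abundances from a log-normal species-abundance
#' distribution, then assembles each sample as a Dirichlet-multinomial draw
#' with concentration `Nm * p` — the sampling kernel implied by the Sloan
#' neutral model's diffusion limit — at a fixed sequencing depth. Small `Nm`
#' produces strong ecological drift (rare taxa dropping out of samples);
#' large `Nm` makes samples converge to the metacommunity.
#'
#' The default log-normal shape (`sad_sdlog = 2.5`) gives the long-tailed
#' abundance structure typical of eukaryotic plankton surveys: roughly 2% of
#' OTUs classify abundant and ~90% rare at the default thresholds.
#'
#' @param n_otus Number of OTUs (default 2000).
#' @param n_samples Number of samples (default 18).
#' @param depth Reads per sample (default 10000).
#' @param Nm Neutral immigration-times-size parameter (default 500).
#' @param sad_meanlog,sad_sdlog Log-normal SAD parameters (defaults 0, 2.5).
#' @param seed Integer seed.
#' @return List with `table` (wide count tibble), `metacommunity`
#'   (tibble `otu_id`, `p`) and `params`.
#' @export
simulate_neutral_table <- function(n_otus = 2000, n_samples = 18,
                                   depth = 10000, Nm = 500,
                                   sad_meanlog = 0, sad_sdlog = 2.5,
                                   seed = 1L) {
  if (Nm <= 0) abort("Nm must be positive")
  with_local_seed(seed, {
    p <- lognormal_sad(n_otus, sad_meanlog, sad_sdlog)
    counts <- vapply(seq_len(n_samples), function(j) {
      x <- rdirichlet_one(Nm * p)
      stats::rmultinom(1, size = depth, prob = x)[, 1]
    }, numeric(n_otus))
    rownames(counts) <- otu_names(n_otus)
    colnames(counts) <- sample_names(n_samples)
    list(
      table = matrix_to_table(counts),
      metacommunity = tibble::tibble(otu_id = otu_names(n_otus), p = p),
      params = list(n_otus = n_otus, n_samples = n_samples, depth = depth,
                    Nm = Nm, sad_meanlog = sad_meanlog, sad_sdlog = sad_sdlog,
                    seed = seed)
    )
  })
}

#' Simulate a three-period successional community
#'
#' Builds one metacommunity per period by a directional random walk on log
#' abundances (each period step adds independent Gaussian perturbations of
#' standard deviation `turnover_rate`), plants `n_indicators` period-specific
#' indicator OTUs whose abundance is raised to `indicator_effect` times the
#' mean OTU abundance within their period only (so typically-rare taxa become
#' clearly detectable there and stay rare elsewhere), and then draws samples
#' per period with the neutral Dirichlet-multinomial kernel. The default design mirrors a
#' 3 periods x 3 depths x 2 dates layout (18 samples, date index 1-6).
#'
#' @param n_otus Number of OTUs (default 2000).
#' @param n_periods Number of succession periods (default 3).
#' @param n_depths Depth layers per sampling event (default 3).
#' @param n_dates Sampling dates per period (default 2).
#' @param depth Reads per sample (default 10000).
#' @param Nm Neutral parameter within periods (default 500).
#' @param turnover_rate SD of the log-abundance walk per period step
#'   (default 1; 0 switches succession off).
#' @param n_indicators Planted indicator OTUs per period (default 20).
#' @param indicator_effect Within-period abundance of an indicator as a
#'   multiple of the mean OTU abundance (default 10).
#' @param sad_meanlog,sad_sdlog Log-normal SAD parameters (defaults 0, 2.5).
#' @param seed Integer seed.
#' @return List with `table`, `metadata` (tibble `sample_id`, `period`,
#'   `depth_layer`, `date_index`), `indicators` (tibble `otu_id`, `period`)
#'   and `params`.
#' @export
simulate_succession <- function(n_otus = 2000, n_periods = 3, n_depths = 3,
                                n_dates = 2, depth = 10000, Nm = 500,
                                turnover_rate = 1, n_indicators = 20,
                                indicator_effect = 10,
                                sad_meanlog = 0, sad_sdlog = 2.5, seed = 1L) {
  if (n_periods < 2) abort("need at least two periods")
  if (n_indicators * n_periods > n_otus) abort("more indicators than OTUs")
  with_local_seed(seed, {
    base_log <- log(lognormal_sad(n_otus, sad_meanlog, sad_sdlog))
    period_names <- paste0("period", seq_len(n_periods))
    ind_ids <- matrix(sample.int(n_otus, n_indicators * n_periods),
                      nrow = n_periods)
    meta_p <- vector("list", n_periods)
    logp <- base_log
    for (t in seq_len(n_periods)) {
      if (t > 1 && turnover_rate > 0) {
        logp <- logp + stats::rnorm(n_otus, sd = turnover_rate)
      }
      w <- exp(logp)
      if (n_indicators > 0) {
        w[ind_ids[t, ]] <- indicator_effect * mean(w)
      }
      meta_p[[t]] <- w / sum(w)
    }
    per_period <- n_depths * n_dates
    n_samples <- per_period * n_periods
    counts <- matrix(0, n_otus, n_samples)
    metadata <- tibble::tibble(
      sample_id = sample_names(n_samples),
      period = factor(rep(period_names, each = per_period),
                      levels = period_names, ordered = TRUE),
      depth_layer = factor(rep(rep(c("surface", "middle", "bottom"),
                                   length.out = n_depths), n_dates * n_periods)[seq_len(n_samples)],
                           levels = c("surface", "middle", "bottom")),
      date_index = rep(seq_len(n_dates * n_periods), each = n_depths)[seq_len(n_samples)]
    )
    for (j in seq_len(n_samples)) {
      t <- as.integer(metadata$period[j])
      x <- rdirichlet_one(Nm * meta_p[[t]])
      counts[, j] <- stats::rmultinom(1, size = depth, prob = x)[, 1]
    }
    rownames(counts) <- otu_names(n_otus)
    colnames(counts) <- metadata$sample_id
    indicators <- tibble::tibble(
      otu_id = otu_names(n_otus)[as.vector(t(ind_ids))],
      period = rep(period_names, each = n_indicators)
    )
    list(
      table = matrix_to_table(counts), metadata = metadata,
      indicators = indicators,
      params = list(n_otus = n_otus, n_periods = n_periods, depth = depth,
                    Nm = Nm, turnover_rate = turnover_rate,
                    n_indicators = n_indicators,
                    indicator_effect = indicator_effect, seed = seed)
    )
  })
}

#' Simulate correlated OTU blocks tied to environmental drivers
#'
#' Plants `n_modules` blocks of co-varying OTUs: each module has one latent
#' factor per sample, and member OTUs' log abundances load on it so that the
#' latent share of their log-scale variance is `rho`. Environmental variables
#' are noisy copies of the latents (one per module by default), so the
#' correlation structure of both the OTU-OTU and OTU-environment screens is
#' block-wise by construction. Remaining OTUs fluctuate independently.
#'
#' @param n_otus Total OTUs (default 200).
#' @param n_modules Number of planted modules (default 4).
#' @param otus_per_module Members per module (default 30).
#' @param n_samples Number of samples (default 18).
#' @param depth Reads per sample (default 10000).
#' @param rho Latent share of log-abundance variance within a module, in
#'   (0, 1) (default 0.9).
#' @param amplitude Log-scale SD of the structured variation (default 2).
#' @param env_noise_sd Noise SD added to the latent to form each environmental
#'   variable (default 0.3).
#' @param seed Integer seed.
#' @return List with `table`, `modules` (tibble `otu_id`, `module`; 0 =
#'   background), `metadata` (tibble `sample_id`, `env1`...), `latents` and
#'   `params`.
#' @export
simulate_modular_counts <- function(n_otus = 200, n_modules = 4,
                                    otus_per_module = 30, n_samples = 18,
                                    depth = 10000, rho = 0.9, amplitude = 2,
                                    env_noise_sd = 0.3, seed = 1L) {
  if (n_modules < 2) abort("need at least two modules")
  if (otus_per_module * n_modules > n_otus) abort("modules exceed the OTU pool")
  if (rho <= 0 || rho >= 1) abort("rho must lie in (0, 1)")
  with_local_seed(seed, {
    module <- rep(0L, n_otus)
    module[seq_len(otus_per_module * n_modules)] <-
      rep(seq_len(n_modules), each = otus_per_module)
    latents <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
    base <- stats::rnorm(n_otus, mean = log(30), sd = 0.5)
    lam <- amplitude * sqrt(rho)
    eps_sd <- amplitude * sqrt(1 - rho)
    loadsign <- sample(c(-1, 1), n_otus, replace = TRUE)
    logab <- matrix(0, n_otus, n_samples)
    for (i in seq_len(n_otus)) {
      structured <- if (module[i] > 0) loadsign[i] * lam * latents[module[i], ] else 0
      logab[i, ] <- base[i] + structured + stats::rnorm(n_samples, sd = eps_sd)
    }
    counts <- vapply(seq_len(n_samples), function(j) {
      w <- exp(logab[, j])
      stats::rmultinom(1, size = depth, prob = w / sum(w))[, 1]
    }, numeric(n_otus))
    rownames(counts) <- otu_names(n_otus)
    colnames(counts) <- sample_names(n_samples)
    metadata <- tibble::tibble(sample_id = sample_names(n_samples))
    for (mm in seq_len(n_modules)) {
      metadata[[paste0("env", mm)]] <-
        latents[mm, ] + stats::rnorm(n_samples, sd = env_noise_sd)
    }
    list(
      table = matrix_to_table(counts),
      modules = tibble::tibble(otu_id = otu_names(n_otus), module = module),
      metadata = metadata,
      latents = latents,
      params = list(n_otus = n_otus, n_modules = n_modules,
                    otus_per_module = otus_per_module, n_samples = n_samples,
                    depth = depth, rho = rho, amplitude = amplitude,
                    env_noise_sd = env_noise_sd, seed = seed)
    )
  })
}
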