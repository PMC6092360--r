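#' Prevalence/abundance prefilter before network construction
#'
#' Retains OTUs present in strictly more than `min_samples` samples AND with
#' strictly more than `min_reads` total reads, reducing spurious correlations
#' from sparse profiles.
#'
#' @param x Wide count tibble.
#' @param min_samples Occupancy threshold, exclusive (default 6).
#' @param min_reads Total-read threshold, exclusive (default 20).
#' @return Filtered count tibble with attribute `n_dropped`.
#' @export
network_prefilter <- function(x, min_samples = 6, min_reads = 20) {
  m <- counts_matrix(x)
  keep <- rowSums(m > 0) > min_samples & rowSums(m) > min_reads
  if (!any(keep)) abort("no OTUs pass the network prefilter")
  out <- matrix_to_table(m[keep, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Build a co-occurrence network by correlation screening
#'
#' Computes all pairwise Spearman rank correlations between OTU abundance
#' profiles (midrank ties), with P from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))`. Pairs with `|r| > r_threshold` and
#' `p < p_threshold` become edges of a simple undirected graph; the
#' correlation sign is kept as an edge attribute. OTUs left without any edge
#' are dropped from the reported network (their number is recorded), as are
#' constant profiles whose correlation is undefined.
#'
#' @param x Wide count tibble (usually after [network_prefilter()]).
#' @param r_threshold Absolute-correlation cutoff, exclusive (default 0.8).
#' @param p_threshold P-value cutoff, exclusive (default 0.01).
#' @param classes Optional [classify_otus()] output to label nodes.
#' @return Object of class `co_network` with `$graph` (igraph), `$edges`,
#'   `$nodes`, `$n_input_otus`, `$n_isolated`, `$n_constant`.
#' @export
correlation_screen <- function(x, r_threshold = 0.8, p_threshold = 0.01,
                               classes = NULL) {
  m <- counts_matrix(x)
  n <- ncol(m)
  if (n < 4) abort("need at least four samples")
  sds <- apply(m, 1, stats::sd)
  n_constant <- sum(sds == 0)
  m <- m[sds > 0, , drop = FALSE]
  r <- stats::cor(t(m), method = "spearman")
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  pval[abs(r) >= 1] <- 0
  hit <- abs(r) > r_threshold & pval < p_threshold
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  rvals <- r[idx]
  edges <- tibble::tibble(
    from = rownames(m)[idx[, 1]],
    to = rownames(m)[idx[, 2]],
    r = rvals,
    p = pval[idx],
    sign = ifelse(rvals > 0, "positive", "negative")
  )
  node_ids <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = node_ids))
  nodes <- tibble::tibble(otu_id = node_ids)
  if (!is.null(classes)) {
    nodes$rollup <- as.character(classes$rollup[match(node_ids, classes$otu_id)])
  }
  out <- list(
    graph = g, edges = edges, nodes = nodes,
    n_input_otus = nrow(m) + n_constant,
    n_isolated = nrow(m) - length(node_ids),
    n_constant = n_constant,
    r_threshold = r_threshold, p_threshold = p_threshold
  )
  class(out) <- "co_network"
  out
}

#' @export
print.co_network <- function(x, ...) {
  cat("Co-occurrence network\n")
  cat(sprintf("  %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  cat(sprintf("  screen: |r| > %g, P < %g; %d of %d input OTUs isolated\n",
              x$r_threshold, x$p_threshold, x$n_isolated, x$n_input_otus))
  invisible(x)
}

#' Node-level topology of a co-occurrence network
#'
#' Degree, unnormalised shortest-path betweenness, closeness (within each
#' node's connected component) and eigenvector centrality, all on the
#' unweighted, unsigned simple graph.
#'
#' @param net A `co_network`.
#' @return Tibble with `otu_id`, `degree`, `betweenness`, `closeness`,
#'   `eigenvector` (plus `rollup` when available).
#' @export
node_topology <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) abort("empty network")
  out <- tibble::tibble(
    otu_id = igraph::V(g)$name,
    degree = unname(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                             normalized = FALSE)),
    closeness = unname(suppressWarnings(igraph::closeness(g, mode = "all"))),
    eigenvector = unname(igraph::eigen_centrality(g, directed = FALSE)$vector)
  )
  if ("rollup" %in% names(net$nodes)) {
    out$rollup <- net$nodes$rollup[match(out$otu_id, net$nodes$otu_id)]
  }
  out
}

#' Louvain module detection
#'
#' Multilevel (Louvain) community detection on the unsigned graph at
#' resolution 1. Modules are relabelled in descending size order and flagged
#' "major" when they hold more than `major_size` nodes.
#'
#' @param net A `co_network`.
#' @param seed Integer seed (Louvain is order/stochasticity sensitive).
#' @param major_size Major-module size threshold, exclusive (default 40).
#' @return `net` with `$modules` (tibble `otu_id`, `module`, `major`) and
#'   `$modularity` filled in.
#' @export
detect_modules <- function(net, seed = 1L, major_size = 40) {
  g <- net$graph
  if (igraph::ecount(g) < 1) abort("network has no edges")
  comm <- with_local_seed(seed, igraph::cluster_louvain(g, resolution = 1))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  module <- unname(relabel[as.character(memb)])
  net$modules <- tibble::tibble(
    otu_id = igraph::V(g)$name,
    module = as.integer(module),
    major = as.integer(table(module)[as.character(module)]) > major_size
  )
  net$modularity <- igraph::modularity(g, memb)
  net
}

#' Global topology of a co-occurrence network
#'
#' Modularity (from [detect_modules()], run if absent), average local
#' clustering coefficient (isolated/degree-1 nodes contribute zero), average
#' shortest path length over the largest connected component, and the R^2 of
#' an OLS fit of log(frequency) on log(degree) over the positive-count degree
#' histogram (a regression-style test of scale-free structure).
#'
#' @param net A `co_network` (modules detected or not).
#' @param seed Seed used if modules must be detected.
#' @return One-row tibble: `n_nodes`, `n_edges`, `n_positive`, `n_negative`,
#'   `modularity`, `clustering`, `avg_path_length`, `power_law_r_squared`.
#' @export
global_topology <- function(net, seed = 1L) {
  if (is.null(net$modules)) net <- detect_modules(net, seed = seed)
  g <- net$graph
  tibble::tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_positive = sum(net$edges$sign == "positive"),
    n_negative = sum(net$edges$sign == "negative"),
    modularity = net$modularity,
    clustering = graph_clustering(g),
    avg_path_length = lcc_path_length(g),
    power_law_r_squared = power_law_r2(igraph::degree(g))
  )
}

#' @export
glance.co_network <- function(x, ...) global_topology(x)

graph_clustering <- function(g) {
  mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
}

lcc_path_length <- function(g) {
  comp <- igraph::components(g)
  if (max(comp$csize) < 2) return(NA_real_)
  biggest <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == biggest))
  igraph::mean_distance(sub, directed = FALSE)
}

power_law_r2 <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  if (length(tab) < 3) return(NA_real_)
  x <- log(as.numeric(names(tab)))
  y <- log(as.numeric(tab))
  summary(stats::lm(y ~ x))$r.squared
}

#' Erdos-Renyi null ensemble for global topology
#'
#' Draws `n_random` G(n, m) random graphs with exactly the observed node and
#' edge counts, recomputes modularity, average clustering and average path
#' length on each, and reports the null mean, sd, z-score and empirical
#' percentile of the observed values.
#'
#' @param net A `co_network` (modules detected or not).
#' @param n_random Ensemble size (default 1000).
#' @param seed Integer seed.
#' @return Tibble with `metric`, `observed`, `null_mean`, `null_sd`, `z`,
#'   `percentile`.
#' @export
er_null_ensemble <- function(net, n_random = 1000, seed = 1L) {
  g <- net$graph
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m < 1) abort("network has no edges")
  if (m > choose(n, 2)) abort("edge count exceeds the simple-graph maximum")
  obs <- global_topology(net, seed = seed)
  nulls <- with_local_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      rg <- igraph::sample_gnm(n, m)
      c(modularity = igraph::modularity(rg, igraph::membership(igraph::cluster_louvain(rg))),
        clustering = graph_clustering(rg),
        avg_path_length = lcc_path_length(rg))
    }, numeric(3))
  })
  metrics <- c("modularity", "clustering", "avg_path_length")
  purrr::map_dfr(metrics, function(met) {
    null_vals <- nulls[met, ]
    o <- obs[[met]]
    tibble::tibble(
      metric = met, observed = o,
      null_mean = mean(null_vals), null_sd = stats::sd(null_vals),
      z = (o - mean(null_vals)) / stats::sd(null_vals),
      percentile = mean(null_vals < o)
    )
  })
}

#' Keystone taxa by the degree/betweenness rule
#'
#' Keystones are nodes with degree strictly above `degree_min` and
#' betweenness strictly below `betweenness_max` (raw path counts): highly
#' connected OTUs that are not mere bridges, posited to stabilise community
#' structure.
#'
#' @param stats Output of [node_topology()].
#' @param classes Optional [classify_otus()] output for roll-up labels.
#' @param degree_min Degree threshold, exclusive (default 100).
#' @param betweenness_max Betweenness threshold, exclusive (default 5000).
#' @return Tibble of keystone nodes (possibly empty).
#' @export
keystone_taxa <- function(stats, classes = NULL, degree_min = 100,
                          betweenness_max = 5000) {
  out <- stats[stats$degree > degree_min & stats$betweenness < betweenness_max, ]
  if (!is.null(classes)) {
    out$rollup <- as.character(classes$rollup[match(out$otu_id, classes$otu_id)])
  }
  out
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' For each node, `z` is the z-score of its within-module degree relative to
#' its module (0 when the module's within-degrees have zero spread), and
#' `P = 1 - sum_s (k_is / k_i)^2` over modules s. Roles: module hub
#' (`z >= z_threshold`, `P < p_threshold`), connector (`P >= p_threshold`,
#' `z < z_threshold`), network hub (both), else peripheral.
#'
#' @param net A `co_network` with modules detected.
#' @param z_threshold Hub threshold on z (default 2.5).
#' @param p_threshold Connector threshold on P (default 0.62).
#' @return Tibble with `otu_id`, `module`, `z`, `p_coef`, `role`.
#' @export
zi_pi <- function(net, z_threshold = 2.5, p_threshold = 0.62) {
  if (is.null(net$modules)) abort("run detect_modules() first")
  g <- net$graph
  memb <- net$modules$module[match(igraph::V(g)$name, net$modules$otu_id)]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(adj)
  mods <- sort(unique(memb))
  # per-node degree into each module
  kin <- sapply(mods, function(mm) rowSums(adj[, memb == mm, drop = FALSE]))
  own <- kin[cbind(seq_along(memb), match(memb, mods))]
  z <- numeric(length(memb))
  for (mm in mods) {
    sel <- memb == mm
    mu <- mean(own[sel]); sdv <- stats::sd(own[sel])
    z[sel] <- if (is.na(sdv) || sdv == 0) 0 else (own[sel] - mu) / sdv
  }
  p_coef <- ifelse(k > 0, 1 - rowSums((kin / pmax(k, 1))^2), NA_real_)
  role <- dplyr::case_when(
    k == 0 ~ "peripheral",
    z >= z_threshold & p_coef >= p_threshold ~ "network hub",
    z >= z_threshold ~ "module hub",
    p_coef >= p_threshold ~ "connector",
    TRUE ~ "peripheral"
  )
  tibble::tibble(
    otu_id = igraph::V(g)$name,
    module = memb, z = unname(z), p_coef = unname(p_coef), role = unname(role),
    isolated = unname(k == 0)
  )
}

#' Zi-Pi plane plot
#'
#' @param zipi Output of [zi_pi()].
#' @param z_threshold,p_threshold Role thresholds to draw (defaults 2.5, 0.62).
#' @return A ggplot.
#' @export
plot_zipi <- function(zipi, z_threshold = 2.5, p_threshold = 0.62) {
  ggplot2::ggplot(zipi, ggplot2::aes(.data$p_coef, .data$z, colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = z_threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = p_threshold, linetype = "dashed") +
    ggplot2::labs(x = "Participation coefficient (P)",
                  y = "Within-module degree z-score (z)")
}

#' Module-environment association counts
#'
#' For each network module and environmental variable, counts the member OTUs
#' whose abundance profile passes the same Spearman screen used for the
#' network edges (`|r| > r_threshold`, `p < p_threshold`) against the
#' variable. Constant variables are skipped.
#'
#' @param x Wide count tibble (the table the network was built from).
#' @param net A `co_network` with modules detected.
#' @param metadata Sample metadata with `sample_id` and the variables.
#' @param variables Character vector of metadata columns.
#' @param r_threshold,p_threshold Screen thresholds (defaults 0.8, 0.01).
#' @return Tibble with `module`, `variable`, `n_edges`.
#' @export
module_env_association <- function(x, net, metadata, variables,
                                   r_threshold = 0.8, p_threshold = 0.01) {
  if (is.null(net$modules)) abort("run detect_modules() first")
  m <- counts_matrix(x)
  ord <- match(colnames(m), metadata$sample_id)
  if (anyNA(ord)) abort("metadata does not cover all samples")
  n <- ncol(m)
  mods <- net$modules
  purrr::map_dfr(variables, function(v) {
    env <- metadata[[v]][ord]
    if (length(unique(env)) < 2) {
      warn(paste0("constant variable skipped: ", v))
      return(NULL)
    }
    hits <- vapply(mods$otu_id, function(id) {
      prof <- m[id, ]
      if (stats::sd(prof) == 0) return(FALSE)
      r <- stats::cor(prof, env, method = "spearman")
      t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p <- if (abs(r) >= 1) 0 else 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
      abs(r) > r_threshold && p < p_threshold
    }, logical(1))
    out <- dplyr::count(tibble::tibble(module = mods$module[hits]),
                        .data$module, name = "n_edges")
    if (nrow(out)) tibble::add_column(out, variable = v, .after = 1) else NULL
  })
}

#' Export network edges as TSV
#'
#' @param net A `co_network`.
#' @param path Output path.
#' @return The edge tibble, invisibly.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(net$edges, path, progress = FALSE)
  invisible(net$edges)
}
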