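#' Run the full abundant/rare community analysis pipeline
#'
#' Orchestrates the stages in dependency order on a counts + metadata input
#' (or on a simulated community when `counts` is `NULL`): optional singleton
#' removal and rarefaction, abundance classification, alpha diversity with the
#' period x depth ANOVA, Bray-Curtis partition and time-lag regression,
#' ANOSIM, Mantel screen and IndVal indicators, the neutral-model fit, and
#' the co-occurrence network with modules, Zi-Pi roles and keystones. Stage
#' outputs are written as TSV/JSON under `out_dir` together with a manifest
#' recording seeds, thresholds and dropped items; re-running with the same
#' inputs and seed reproduces the outputs.
#'
#' @param counts Wide count tibble, a path to a counts TSV, or `NULL` to run
#'   on a simulated succession community.
#' @param metadata Metadata tibble or TSV path (`sample_id`, `period`,
#'   `date_index`, environmental columns). Ignored when `counts` is `NULL`.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; stage seeds are derived from it.
#' @param rarefaction_depth Depth for rarefaction; `NULL` uses the minimum
#'   sample total; `NA` skips rarefaction.
#' @param env_vars Environmental columns for the Mantel screen and
#'   module-environment counts; default: all numeric metadata columns except
#'   `date_index`.
#' @param n_perm Permutations for ANOSIM/Mantel/IndVal (default 999).
#' @param n_null Erdos-Renyi null networks (default 1000).
#' @param stages Character vector selecting stages; default all.
#' @return Invisible list of the in-memory stage results.
#' @export
run_pipeline <- function(counts = NULL, metadata = NULL, out_dir = "raretaxa-out",
                         seed = 1L, rarefaction_depth = NULL, env_vars = NULL,
                         n_perm = 999, n_null = 1000,
                         stages = c("classify", "alpha", "beta", "tests",
                                    "ncm", "network")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, n_perm = n_perm, n_null = n_null,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (is.null(counts)) {
    sim <- simulate_succession(seed = derive_seed(seed, "simulate"))
    counts <- sim$table
    metadata <- sim$metadata
    manifest$simulated <- sim$params
  } else {
    if (is.character(counts)) counts <- read_otu_table(counts)
    if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  }
  validate_otu_table(counts)
  res <- list(metadata = metadata)

  counts <- remove_singletons(counts)
  manifest$singletons_removed <- attr(counts, "n_dropped")
  if (!isTRUE(is.na(rarefaction_depth))) {
    depth <- rarefaction_depth %||% min(colSums(counts_matrix(counts)))
    counts <- rarefy_counts(counts, depth, seed = derive_seed(seed, "rarefy"))
    counts <- drop_empty_otus(counts)
    manifest$rarefaction_depth <- depth
    manifest$empty_after_rarefaction <- attr(counts, "n_dropped")
  }
  res$counts <- counts
  write_otu_table(counts, file.path(out_dir, "counts.tsv"))
  rel <- relative_abundance(counts)

  if ("classify" %in% stages) {
    res$classes <- classify_otus(rel)
    readr::write_tsv(res$classes, file.path(out_dir, "classification.tsv"),
                     progress = FALSE)
    readr::write_tsv(class_summary(res$classes, counts),
                     file.path(out_dir, "class_summary.tsv"), progress = FALSE)
    venn <- shared_otu_counts(counts, metadata)
    jsonlite::write_json(stats::setNames(as.list(venn$n_otus), venn$region),
                         file.path(out_dir, "venn.json"), auto_unbox = TRUE)
  }
  if ("alpha" %in% stages) {
    res$alpha <- alpha_diversity(counts)
    readr::write_tsv(res$alpha, file.path(out_dir, "alpha.tsv"), progress = FALSE)
    if (all(c("period", "depth_layer") %in% names(metadata))) {
      res$alpha_anova <- alpha_anova(res$alpha, metadata,
                                     factor_a = "period", factor_b = "depth_layer")
      readr::write_tsv(res$alpha_anova, file.path(out_dir, "alpha_anova.tsv"),
                       progress = FALSE)
    }
  }
  if ("beta" %in% stages) {
    d <- bray_curtis(counts)
    res$bray_curtis <- d
    utils::write.table(as.matrix(d), file.path(out_dir, "bray_curtis.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    res$partition <- bray_partition_pairs(counts)
    readr::write_tsv(res$partition, file.path(out_dir, "bray_partition.tsv"),
                     progress = FALSE)
    if ("date_index" %in% names(metadata)) {
      res$timelag <- time_lag_regression(d, metadata)
      readr::write_tsv(glance(res$timelag), file.path(out_dir, "timelag.tsv"),
                       progress = FALSE)
    }
    res$nmds <- nmds_ordination(d, seed = derive_seed(seed, "nmds"))
    readr::write_tsv(res$nmds, file.path(out_dir, "nmds.tsv"), progress = FALSE)
  }
  if ("tests" %in% stages && "period" %in% names(metadata)) {
    d <- res$bray_curtis %||% bray_curtis(counts)
    grp <- metadata$period[match(attr(d, "Labels"), metadata$sample_id)]
    res$anosim <- anosim_test(d, grp, n_perm = n_perm,
                              seed = derive_seed(seed, "anosim"))
    readr::write_tsv(res$anosim, file.path(out_dir, "anosim.tsv"), progress = FALSE)
    res$simper <- simper_analysis(counts, metadata)
    readr::write_tsv(res$simper, file.path(out_dir, "simper.tsv"), progress = FALSE)
    vars <- env_vars %||% setdiff(
      names(metadata)[vapply(metadata, is.numeric, logical(1))], "date_index")
    if (length(vars)) {
      res$mantel <- mantel_env_screen(d, metadata, vars, n_perm = n_perm,
                                      seed = derive_seed(seed, "mantel"))
      readr::write_tsv(res$mantel, file.path(out_dir, "mantel.tsv"), progress = FALSE)
    }
    res$indicators <- indval(counts, metadata, n_perm = n_perm,
                             seed = derive_seed(seed, "indval"))
    readr::write_tsv(res$indicators, file.path(out_dir, "indicators.tsv"),
                     progress = FALSE)
  }
  if ("ncm" %in% stages) {
    res$ncm <- ncm_fit(counts)
    jsonlite::write_json(as.list(glance(res$ncm)), file.path(out_dir, "ncm.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_tsv(tidy(res$ncm), file.path(out_dir, "ncm_otus.tsv"),
                     progress = FALSE)
  }
  if ("network" %in% stages) {
    pre <- tryCatch(network_prefilter(counts), error = function(e) NULL)
    if (is.null(pre)) {
      manifest$network <- "skipped: no OTUs passed the prefilter"
    } else {
      net <- correlation_screen(pre, classes = res$classes)
      net <- detect_modules(net, seed = derive_seed(seed, "louvain"))
      res$network <- net
      write_edge_list(net, file.path(out_dir, "edges.tsv"))
      res$node_stats <- node_topology(net)
      readr::write_tsv(res$node_stats, file.path(out_dir, "node_topology.tsv"),
                       progress = FALSE)
      res$global <- global_topology(net)
      readr::write_tsv(res$global, file.path(out_dir, "global_topology.tsv"),
                       progress = FALSE)
      res$keystones <- keystone_taxa(res$node_stats, res$classes)
      readr::write_tsv(res$keystones, file.path(out_dir, "keystones.tsv"),
                       progress = FALSE)
      res$zipi <- zi_pi(net)
      readr::write_tsv(res$zipi, file.path(out_dir, "zipi.tsv"), progress = FALSE)
      res$er_null <- er_null_ensemble(net, n_random = n_null,
                                      seed = derive_seed(seed, "ernull"))
      readr::write_tsv(res$er_null, file.path(out_dir, "er_null.tsv"),
                       progress = FALSE)
      manifest$network_isolated_dropped <- net$n_isolated
    }
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(res)
}
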