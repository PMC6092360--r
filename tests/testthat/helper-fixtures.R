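# Small fixtures built in code; all randomness is locally seeded.

make_table <- function(m, otu_ids = NULL, sample_ids = NULL) {
  if (is.null(rownames(m))) rownames(m) <- otu_ids %||% sprintf("OTU%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sample_ids %||% sprintf("S%02d", seq_len(ncol(m)))
  out <- tibble::as_tibble(m)
  tibble::add_column(out, otu_id = rownames(m), .before = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

table_matrix <- function(tbl) {
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl[[1]]
  m
}

random_table <- function(n_otus, n_samples, seed, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_otus * n_samples, lambda = runif(n_otus, 1, max_count)),
              n_otus, n_samples)
  # keep column totals positive
  m[1, colSums(m) == 0] <- 1
  make_table(m)
}

simple_metadata <- function(sample_ids, period) {
  tibble::tibble(sample_id = sample_ids,
                 period = factor(period, levels = unique(period), ordered = TRUE))
}

# wrap an igraph into the package's network container
as_co_network <- function(g) {
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- paste0("N", seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g)
  net <- list(
    graph = g,
    edges = tibble::tibble(from = el[, 1], to = el[, 2],
                           r = rep(1, nrow(el)), p = rep(0, nrow(el)),
                           sign = rep("positive", nrow(el))),
    nodes = tibble::tibble(otu_id = igraph::V(g)$name),
    n_input_otus = igraph::vcount(g), n_isolated = 0L, n_constant = 0L,
    r_threshold = 0.8, p_threshold = 0.01
  )
  class(net) <- "co_network"
  net
}

with_seed_local <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# independent permutation generator used by the exact-ANOSIM oracle
# (iterative insertion, unlike the implementation's recursive construction)
perms_iter <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- do.call(rbind, lapply(seq_len(k), function(pos) {
      left <- out[, seq_len(pos - 1), drop = FALSE]
      right <- if (pos <= k - 1) out[, pos:(k - 1), drop = FALSE] else out[, 0, drop = FALSE]
      cbind(left, k, right)
    }))
  }
  out
}

anosim_oracle_stat <- function(dm, g) {
  v <- dm[upper.tri(dm)]
  rk <- rank(v)
  within <- outer(g, g, "==")[upper.tri(dm)]
  (mean(rk[!within]) - mean(rk[within])) / (length(v) / 2)
}

# distance matrix from explicit pair values (samples a, b, ... in order)
dist_from_pairs <- function(n, values, labels = letters[seq_len(n)]) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- values
  m <- m + t(m)
  stats::as.dist(m)
}
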