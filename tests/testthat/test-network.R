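test_that("prefilter applies strict occupancy and read thresholds", {
  m <- rbind(
    keep = c(rep(3, 7), rep(0, 11)),        # 7 samples, 21 reads
    few_samples = c(rep(4, 6), rep(0, 12)), # 6 samples (not more) -> dropped
    few_reads = c(rep(2, 10), rep(0, 8))    # 10 samples but 20 reads -> dropped
  )
  colnames(m) <- paste0("S", 1:18)
  out <- network_prefilter(make_table(m, otu_ids = rownames(m)))
  expect_equal(out$otu_id, "keep")
  expect_equal(attr(out, "n_dropped"), 2L)
  expect_error(network_prefilter(make_table(m[2:3, ], otu_ids = c("a", "b"))),
               "prefilter")
})

test_that("correlation screen keeps only strong significant pairs with signs", {
  n <- 9
  base <- c(3, 1, 4, 1, 5, 9, 2, 6, 8)
  m <- rbind(
    up = base,
    up2 = base * 2 + 1,          # perfectly monotone with 'up': r = 1
    down = max(base) + 1 - base, # anti-monotone: r = -1
    # rank pattern at exactly rho = 0.8 against 1..9 (three distance-2 swaps)
    edge08 = c(3, 2, 1, 6, 5, 4, 9, 8, 7),
    ramp = 1:9
  )
  colnames(m) <- paste0("S", 1:n)
  net <- correlation_screen(make_table(m, otu_ids = rownames(m)))
  key <- paste(net$edges$from, net$edges$to)
  expect_true("up up2" %in% key || "up2 up" %in% key)
  e_pos <- net$edges[net$edges$from %in% c("up", "up2") & net$edges$to %in% c("up", "up2"), ]
  expect_equal(e_pos$r, 1)
  expect_equal(e_pos$sign, "positive")
  e_neg <- net$edges[(net$edges$from == "up" & net$edges$to == "down") |
                     (net$edges$from == "down" & net$edges$to == "up"), ]
  expect_equal(e_neg$r, -1)
  expect_equal(e_neg$sign, "negative")
  # spearman(edge08, ramp) is exactly 0.8: P < 0.01 but |r| not > 0.8 -> no edge
  expect_equal(cor(m["edge08", ], m["ramp", ], method = "spearman"), 0.8,
               tolerance = 1e-12)
  expect_false(any((net$edges$from == "edge08" & net$edges$to == "ramp") |
                   (net$edges$from == "ramp" & net$edges$to == "edge08")))
})

test_that("the edge set is invariant to OTU input order and run-to-run", {
  sim <- simulate_modular_counts(n_otus = 80, otus_per_module = 15, seed = 8)
  net1 <- correlation_screen(sim$table)
  net2 <- correlation_screen(sim$table[sample(nrow(sim$table)), ])
  canon <- function(e) {
    k <- ifelse(e$from < e$to, paste(e$from, e$to), paste(e$to, e$from))
    sort(k)
  }
  expect_identical(canon(net1$edges), canon(net2$edges))
  net3 <- correlation_screen(sim$table)
  expect_identical(net1$edges, net3$edges)
})

test_that("node topology matches closed-form values on canonical graphs", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  nt <- node_topology(as_co_network(star))
  expect_equal(nt$degree[1], 4)
  expect_equal(nt$betweenness[1], choose(4, 2))
  expect_equal(nt$betweenness[-1], rep(0, 4))
  comp <- igraph::make_full_graph(5)
  ntc <- node_topology(as_co_network(comp))
  expect_true(all(ntc$betweenness == 0))
  ring <- igraph::make_ring(6)
  ntr <- node_topology(as_co_network(ring))
  expect_lt(diff(range(ntr$eigenvector)), 1e-9)
})

test_that("module detection and modularity behave on planted structure", {
  two_tri <- igraph::graph_from_literal(a - b, b - c, c - a, d - e, e - f, f - d)
  net <- detect_modules(as_co_network(two_tri), seed = 1)
  expect_equal(length(unique(net$modules$module)), 2L)
  expect_equal(net$modularity, 0.5, tolerance = 1e-12)
  full <- detect_modules(as_co_network(igraph::make_full_graph(8)), seed = 1)
  expect_equal(length(unique(full$modules$module)), 1L)
  expect_lt(abs(full$modularity), 1e-9)
})

test_that("global topology matches hand-computed values on tiny graphs", {
  tri <- as_co_network(igraph::make_full_graph(3))
  g <- global_topology(tri, seed = 1)
  expect_equal(g$clustering, 1)
  expect_equal(g$avg_path_length, 1)
  path <- as_co_network(igraph::make_graph(~ a - b, b - c))
  gp <- global_topology(path, seed = 1)
  expect_equal(gp$clustering, 0)
  expect_equal(gp$avg_path_length, 4 / 3, tolerance = 1e-12)
  # exact power-law degree histogram -> r_squared = 1
  degs <- rep(c(1, 2, 4), times = c(64, 16, 4))  # count = 64 * k^-2
  expect_equal(raretaxa:::power_law_r2(degs), 1, tolerance = 1e-12)
})

test_that("Erdos-Renyi nulls conserve edges and expose planted structure", {
  sim <- simulate_modular_counts(seed = 11)
  net <- detect_modules(correlation_screen(network_prefilter(sim$table)), seed = 1)
  nul <- er_null_ensemble(net, n_random = 200, seed = 5)
  expect_equal(nul$percentile[nul$metric == "modularity"], 1)  # beats all nulls
  nul2 <- er_null_ensemble(net, n_random = 200, seed = 5)
  expect_identical(nul, nul2)  # reproducible ensemble
  # complete-graph edge case: every null is the complete graph
  comp <- as_co_network(igraph::make_full_graph(6))
  nulc <- er_null_ensemble(comp, n_random = 20, seed = 2)
  expect_equal(nulc$null_sd[nulc$metric == "clustering"], 0)
  expect_equal(nulc$null_mean[nulc$metric == "clustering"], 1)
})

test_that("keystone rule applies strict thresholds", {
  fake <- tibble::tibble(
    otu_id = c("a", "b", "c", "d"),
    degree = c(120, 100, 150, 101),
    betweenness = c(3000, 10, 5000, 4999)
  )
  ks <- keystone_taxa(fake)
  expect_setequal(ks$otu_id, c("a", "d"))  # 100 and 5000 are excluded bounds
})

test_that("Zi-Pi roles follow the connectivity algebra", {
  # two 4-cliques joined by a single bridge node pair
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(1, 5))
  igraph::V(g)$name <- paste0("N", 1:8)
  net <- detect_modules(as_co_network(g), seed = 1)
  zp <- zi_pi(net)
  # all edges inside own module -> P = 0 for pure members
  pure <- zp[!zp$otu_id %in% c("N1", "N5"), ]
  expect_true(all(pure$p_coef == 0))
  # bridge nodes split 3:1 across modules -> P = 1 - (9+1)/16
  expect_equal(zp$p_coef[zp$otu_id == "N1"], 1 - (9 + 1) / 16, tolerance = 1e-12)
  # equal within-degrees in a module -> z = 0 by the sd = 0 convention
  clique <- detect_modules(as_co_network(igraph::make_full_graph(4)), seed = 1)
  expect_true(all(zi_pi(clique)$z == 0))
})

test_that("module-environment associations concentrate on the loaded module", {
  sim <- simulate_modular_counts(seed = 11)
  pre <- network_prefilter(sim$table)
  net <- detect_modules(correlation_screen(pre), seed = 1)
  assoc <- module_env_association(pre, net, sim$metadata, paste0("env", 1:4))
  expect_true(all(assoc$n_edges >= 1))
  # each variable's hits land in few detected modules (planted concentration)
  per_var <- table(assoc$variable)
  expect_true(all(per_var <= 2))
  # counts are bounded by module size
  msize <- table(net$modules$module)
  expect_true(all(assoc$n_edges <= msize[as.character(assoc$module)]))
  # a noise variable finds (almost) nothing
  set.seed(1)
  meta2 <- sim$metadata
  meta2$noise <- rnorm(nrow(meta2))
  assoc2 <- module_env_association(pre, net, meta2, "noise")
  expect_true(nrow(assoc2) == 0 || sum(assoc2$n_edges) <= 2)
})
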