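test_that("ANOSIM R matches hand-derived values on small configurations", {
  # groups {a,b},{c,d}: within 1 and 2, between 3..6 -> R = 1
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- 1; dm["c", "d"] <- 2
  dm["a", "c"] <- 3; dm["a", "d"] <- 4; dm["b", "c"] <- 5; dm["b", "d"] <- 6
  dm <- dm + t(dm)
  res <- anosim_test(as.dist(dm), c("g1", "g1", "g2", "g2"), n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  # all distances equal -> complete ties -> R = 0
  dm2 <- matrix(1, 4, 4); diag(dm2) <- 0
  rownames(dm2) <- colnames(dm2) <- letters[1:4]
  res2 <- anosim_test(as.dist(dm2), c("g1", "g1", "g2", "g2"), n_perm = 99, seed = 1)
  expect_equal(res2$statistic, 0)
  expect_error(anosim_test(as.dist(dm), c("g1", "g1", "g1", "g2")), "at least two")
})

test_that("ANOSIM agrees with vegan and negative R occurs under shuffled labels", {
  tbl <- random_table(30, 9, seed = 55)
  d <- bray_curtis(tbl)
  g <- rep(c("x", "y", "z"), each = 3)
  ours <- anosim_test(d, g, n_perm = 199, seed = 1)
  ref <- vegan::anosim(d, g, permutations = 199)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  # scan shuffles for a negative statistic (possible under random grouping)
  set.seed(2)
  stats <- replicate(50, anosim_test(d, sample(g), n_perm = 0 + 9, seed = 1)$statistic)
  expect_lt(min(stats), 0)
})

test_that("exact ANOSIM p equals the enumerated permutation tail", {
  set.seed(31)
  for (rep in 1:3) {
    dm <- matrix(0, 6, 6)
    dm[upper.tri(dm)] <- runif(15)
    dm <- dm + t(dm)
    rownames(dm) <- colnames(dm) <- paste0("S", 1:6)
    g <- c("a", "a", "a", "b", "b", "b")
    res <- anosim_test(as.dist(dm), g, exact = TRUE)
    # oracle: enumerate all 720 label permutations independently
    perms <- perms_iter(6)
    obs <- anosim_oracle_stat(dm, g)
    tail_p <- mean(apply(perms, 1, function(p) anosim_oracle_stat(dm, g[p])) >= obs - 1e-12)
    expect_equal(res$p_value, tail_p, tolerance = 1e-12)
    expect_equal(res$n_permutations, factorial(6))
  }
})

test_that("SIMPER contributions reassemble pair dissimilarities and sum to 100%", {
  # two one-OTU samples on disjoint OTUs -> 50% each
  m <- cbind(s1 = c(2, 0), s2 = c(0, 2))
  meta <- simple_metadata(c("s1", "s2"), c("g1", "g2"))
  res <- simper_analysis(make_table(m), meta, group = "period")
  expect_equal(sort(res$pct), c(50, 50))
  expect_equal(unname(attr(res, "mean_dissimilarity")), 1)
  # random tables: per-pair decomposition is exact, percentages sum to 100
  tbl <- random_table(20, 6, seed = 77)
  mm <- table_matrix(tbl)
  d <- as.matrix(bray_curtis(tbl))
  for (pair in list(c(1, 2), c(3, 6))) {
    contrib <- simper_pair(mm[, pair[1]], mm[, pair[2]])
    expect_equal(sum(contrib), d[pair[1], pair[2]], tolerance = 1e-12)
  }
  meta6 <- simple_metadata(colnames(mm), rep(c("g1", "g2"), each = 3))
  res6 <- simper_analysis(tbl, meta6, group = "period")
  expect_equal(sum(res6$pct), 100, tolerance = 1e-9)
  expect_equal(max(res6$cum_pct), 100, tolerance = 1e-9)
  # an OTU identical across all samples contributes nothing
  const_tbl <- make_table(rbind(const = rep(4, 6), varying = c(1, 9, 2, 8, 3, 7)))
  resc <- simper_analysis(const_tbl, meta6, group = "period")
  expect_equal(resc$contribution[resc$otu_id == "const"], 0)
})

test_that("SIMPER average agrees with vegan's between-group decomposition", {
  tbl <- random_table(15, 8, seed = 13)
  meta <- simple_metadata(colnames(table_matrix(tbl)), rep(c("g1", "g2"), each = 4))
  ours <- simper_analysis(tbl, meta, group = "period")
  comm <- t(table_matrix(tbl))
  ref <- summary(vegan::simper(comm, rep(c("g1", "g2"), each = 4),
                               permutations = 0))$g1_g2
  got <- ours$contribution[match(rownames(ref), ours$otu_id)]
  expect_equal(got, unname(ref$average), tolerance = 1e-10)
})

test_that("Mantel statistic hits its exact extremes and matches vegan", {
  tbl <- random_table(25, 8, seed = 3)
  d <- bray_curtis(tbl)
  same <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(same$statistic, 1, tolerance = 1e-12)
  # rank reversal of the same distances -> rho = -1
  dm <- as.matrix(d)
  rev_m <- matrix(0, nrow(dm), ncol(dm), dimnames = dimnames(dm))
  rev_m[upper.tri(rev_m)] <- max(dm) + min(dm[upper.tri(dm)]) - dm[upper.tri(dm)]
  rev_m <- rev_m + t(rev_m)
  rev_res <- mantel_test(d, rev_m, n_perm = 99, seed = 1)
  expect_equal(rev_res$statistic, -1, tolerance = 1e-12)
  ref <- vegan::mantel(d, bray_curtis(random_table(25, 8, seed = 4)),
                       method = "spearman", permutations = 99)
  ours <- mantel_test(d, bray_curtis(random_table(25, 8, seed = 4)),
                      n_perm = 99, seed = 2)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("environmental distances follow the transform rules", {
  meta <- tibble::tibble(
    sample_id = c("A", "B"),
    pH = c(7, 9),
    TOC = c(0, 9),
    period = factor(c("p1", "p3"), levels = c("p1", "p2", "p3"), ordered = TRUE)
  )
  expect_equal(as.matrix(env_distance(meta, "pH"))["A", "B"], 2)
  expect_equal(as.matrix(env_distance(meta, "TOC"))["A", "B"], log(10),
               tolerance = 1e-12)
  expect_equal(as.matrix(env_distance(meta, "period"))["A", "B"], 2)
  same <- tibble::tibble(sample_id = c("A", "B", "C"), x = c(2, 2, 2))
  expect_true(all(as.matrix(env_distance(same, "x")) == 0))
  # missing values drop pairwise with a logged count
  mis <- tibble::tibble(sample_id = c("A", "B", "C"), x = c(1, NA, 3))
  dmis <- env_distance(mis, "x")
  expect_equal(attr(dmis, "n_dropped"), 1L)
  expect_equal(attr(dmis, "Labels"), c("A", "C"))
})

test_that("IndVal components behave as specified on archetypal OTUs", {
  # OTU only in group 1, present in all its samples -> A = B = stat = 1
  # fill keeps every column total at 15 so relative abundances stay comparable
  m <- rbind(perfect = c(5, 5, 5, 0, 0, 0),
             everywhere = c(2, 2, 2, 2, 2, 2),
             fill = c(8, 8, 8, 13, 13, 13))
  colnames(m) <- paste0("S", 1:6)
  meta <- simple_metadata(paste0("S", 1:6), rep(c("g1", "g2"), each = 3))
  res <- indval(make_table(m, otu_ids = rownames(m)), meta, group = "period",
                n_perm = 199, seed = 1, filter = FALSE)
  perf <- res[res$otu_id == "perfect", ]
  expect_equal(c(perf$A, perf$B, perf$stat), c(1, 1, 1))
  expect_gte(perf$p_value, 1 / 200)  # permutation floor
  ev <- res[res$otu_id == "everywhere", ]
  expect_equal(ev$stat, sqrt(0.5), tolerance = 1e-9)
})

test_that("IndVal equals an independent direct-formula recomputation", {
  worst <- 0
  for (s in 1:200) {
    tbl <- random_table(8, 9, seed = 4000 + s, max_count = 10)
    g <- rep(c("g1", "g2", "g3"), each = 3)
    meta <- simple_metadata(colnames(table_matrix(tbl)), g)
    res <- indval(tbl, meta, group = "period", n_perm = 0 + 9, seed = 1,
                  filter = FALSE)
    m <- table_matrix(tbl)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    rel <- sweep(m, 2, colSums(m), "/")
    for (i in seq_len(nrow(m))) {
      means <- tapply(rel[i, ], g, mean)
      bs <- tapply(rel[i, ] > 0, g, mean)
      stats_g <- sqrt(means / sum(means) * bs)
      worst <- max(worst, abs(max(stats_g) - res$stat[res$otu_id == rownames(m)[i]]))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("planted period indicators are recovered with high sensitivity", {
  sens <- sapply(1:3, function(k) {
    sim <- simulate_succession(seed = 900 + k)
    hits <- indval(sim$table, sim$metadata, n_perm = 199, seed = k)
    mean(sim$indicators$otu_id %in% hits$otu_id)
  })
  expect_gte(mean(sens), 0.9)
})

test_that("indicator_counts totals per-group indicator tallies", {
  fake <- tibble::tibble(otu_id = paste0("o", 1:6),
                         best_group = c("p1", "p1", "p2", "p3", "p3", "p3"))
  ic <- indicator_counts(fake)
  expect_equal(ic$n_indicators[ic$best_group == "total"], 6L)
  expect_equal(ic$n_indicators[ic$best_group == "p3"], 3L)
})
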