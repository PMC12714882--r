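test_that("ASPL matches enumeration on canonical graphs and a Floyd-Warshall oracle", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(aspl(k4), 1)
  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(aspl(path3), 4 / 3)
  expect_error(aspl(matrix(0, 3, 3)), "no edges")
  for (s in 1:5) {
    net <- semantic_network(random_similarity(12, seed = 60 + s))
    expect_equal(aspl(net), oracle_aspl(edge_structure(net)))
  }
})

test_that("global clustering matches triad enumeration", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(global_cc(tri), 1)
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(global_cc(star), 0)
  for (s in 1:5) {
    set.seed(s)
    a <- matrix(rbinom(100, 1, 0.4), 10, 10)
    a <- 1 * ((a + t(a)) > 0); diag(a) <- 0
    if (sum(a) == 0) next
    expect_equal(global_cc(a), oracle_global_cc(a))
  }
})

test_that("Louvain modularity approaches the exhaustive-partition optimum", {
  # whole-graph community on a clique has Q = 0
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(modularity_q(k5, seed = 1)$q, 0)
  # two disjoint triangles: brute force over all partitions gives 0.5
  two_tri <- matrix(0, 6, 6)
  two_tri[1:3, 1:3] <- 1; two_tri[4:6, 4:6] <- 1; diag(two_tri) <- 0
  expect_equal(oracle_best_modularity(two_tri), 0.5)
  expect_equal(modularity_q(two_tri, seed = 1)$q, 0.5)
  # random weighted graphs, n = 7: Louvain within tolerance of the optimum
  hits <- 0; total <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    w <- matrix(0, 7, 7)
    w[upper.tri(w)] <- rbinom(21, 1, 0.5) * runif(21)
    w <- w + t(w)
    if (sum(w) == 0) next
    total <- total + 1
    qbest <- oracle_best_modularity(w)
    qlv <- modularity_q(w, seed = s)$q
    expect_lte(qlv, qbest + 1e-9)
    if (qlv >= qbest - 0.02) hits <- hits + 1
  }
  expect_gte(hits / total, 0.95)
})

test_that("strength and Zhang clustering match the direct-summation oracle", {
  # equal-weight triangle: normalized weights 1, fully closed
  tri <- matrix(0.6, 3, 3); diag(tri) <- 0
  lm_ <- local_metrics(tri)
  expect_equal(lm_$local_cc, rep(1, 3))
  expect_equal(lm_$strength, rep(1.2, 3))
  # star center has no neighbor-neighbor edges
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 0.5
  expect_equal(local_metrics(star)$local_cc, rep(0, 4))
  # weighted 4-node graphs against the brute-force triple sum
  for (s in 1:6) {
    set.seed(300 + s)
    w <- matrix(0, 4, 4)
    w[upper.tri(w)] <- runif(6)
    w <- w + t(w)
    lm2 <- local_metrics(w)
    expect_equal(lm2$local_cc, oracle_zhang(w), tolerance = 1e-10)
    expect_equal(lm2$strength, rowSums(w))
  }
})

test_that("Erdos-Renyi baselines have the forced and expected behavior", {
  # p = 1: every replicate is complete
  d1 <- er_baseline(6, 15, reps = 20, seed = 4)
  expect_true(all(d1$aspl$values == 1))
  expect_true(all(d1$cc$values == 1))
  # local-average CC of G(n, p) concentrates near p
  n <- 20; p <- 0.3
  m <- p * n * (n - 1) / 2
  d <- er_baseline(n, m, reps = 300, seed = 11)
  se <- sd(d$cc$values) / sqrt(d$cc$replicates)
  expect_lt(abs(mean(d$cc$values) - p), 3 * se + 0.01)
  # seeded runs are bit-reproducible
  d2 <- er_baseline(n, m, reps = 50, seed = 123)
  d3 <- er_baseline(n, m, reps = 50, seed = 123)
  expect_identical(d2$aspl$values, d3$aspl$values)
  expect_identical(d2$q$values, d3$q$values)
  expect_error(er_baseline(10, 0), "probability")
})

test_that("z-tests follow the closed form", {
  dist <- metric_distribution(c(1, 2, 3, 4, 5), "aspl", "random-baseline")
  zt <- z_test(3, dist)
  expect_equal(zt$statistic, 0)
  expect_equal(zt$p, 1)
  zt2 <- z_test(3 + sd(1:5), dist)
  expect_equal(zt2$statistic, 1)
  expect_equal(zt2$p, 2 * pnorm(-1))
  expect_error(z_test(1, metric_distribution(c(2, 2), "x", "bootstrap")),
               "degenerate")
})

test_that("pooled and paired t-tests match textbook formulas", {
  a <- c(2.1, 2.5, 1.9, 2.2); b <- c(1.4, 1.8, 1.6, 1.2)
  te <- pooled_t_test(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(te$statistic, unname(ref$statistic))
  expect_equal(te$df, unname(ref$parameter))
  expect_equal(te$p, ref$p.value)
  sp <- sqrt(((3) * var(a) + (3) * var(b)) / 6)
  expect_equal(te$d, (mean(a) - mean(b)) / sp)
  # identical samples: t = 0, d = 0
  t0 <- pooled_t_test(a, a)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$d, 0)
  # means 1 vs 0 with pooled SD 1 -> d = 1
  set.seed(8)
  x <- rnorm(5000); x <- (x - mean(x)) / sd(x)
  expect_equal(pooled_t_test(x + 1, x)$d, 1, tolerance = 1e-12)

  pt <- paired_t_test(a, b)
  refp <- t.test(a, b, paired = TRUE)
  expect_equal(pt$statistic, unname(refp$statistic))
  expect_equal(pt$p, refp$p.value)
  expect_equal(paired_t_test(a, a)$statistic, 0)
  delta <- 0.7
  expect_equal(paired_t_test(a + delta + rnorm(4, 0, 1e-6), a)$mean_diff,
               delta, tolerance = 1e-3)
})

test_that("local-metric comparison requires equated node sets", {
  la <- data.frame(word = c("a", "b"), strength = c(1, 2), local_cc = c(0.1, 0.2))
  lb <- data.frame(word = c("a", "c"), strength = c(1, 2), local_cc = c(0.1, 0.2))
  expect_error(compare_local_metrics(la, lb), "not match")
  lb$word <- c("a", "b")
  out <- compare_local_metrics(la, lb)
  expect_equal(out$strength$statistic, 0)
})

test_that("bootstrap with proportion 1 reproduces the full-network metrics", {
  set.seed(21)
  lst <- setNames(lapply(1:14, function(i) sample(letters[1:9], sample(4:8, 1))),
                  paste0("p", 1:14))
  m <- filter_min_producers(make_rm(lst), 2)
  bt <- bootstrap_networks(m, m, reps = 5, proportion = 1, seed = 9)
  net <- semantic_network(m)
  expect_true(all(bt$distributions$aspl$a$values == aspl(net)))
  expect_true(all(bt$distributions$cc$a$values == global_cc(net)))
  expect_equal(sd(bt$distributions$aspl$a$values), 0)
  expect_equal(bt$tests$aspl$statistic, 0)
})

test_that("bootstrap requires equated inputs and respects the seed", {
  set.seed(22)
  lst_a <- setNames(lapply(1:8, function(i) sample(letters[1:10], sample(5:9, 1))),
                    paste0("p", 1:8))
  lst_b <- setNames(lapply(1:8, function(i) sample(letters[3:12], sample(5:9, 1))),
                    paste0("q", 1:8))
  a <- filter_min_producers(make_rm(lst_a), 2)
  b <- filter_min_producers(make_rm(lst_b), 2)
  expect_error(bootstrap_networks(a, b, reps = 2), "not node-equated")
  eq <- equate_nodes(a, b)
  b1 <- bootstrap_networks(eq$a, eq$b, reps = 8, seed = 5)
  b2 <- bootstrap_networks(eq$a, eq$b, reps = 8, seed = 5)
  expect_identical(b1$distributions$q$b$values, b2$distributions$q$b$values)
})

test_that("adding an edge never increases ASPL", {
  for (s in 1:6) {
    set.seed(400 + s)
    n <- 9
    g <- igraph::sample_gnp(n, 0.35)
    while (!igraph::is_connected(g)) g <- igraph::sample_gnp(n, 0.35)
    a <- as.matrix(igraph::as_adjacency_matrix(g))
    before <- aspl(a)
    miss <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
    if (nrow(miss) == 0) next
    pick <- miss[sample(nrow(miss), 1), ]
    a[pick[1], pick[2]] <- a[pick[2], pick[1]] <- 1
    expect_lte(aspl(a), before)
  }
})
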