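test_that("ground-truth lexicons are connected, reproducible block graphs", {
  lex <- ground_truth_lexicon(n_words = 30, n_blocks = 3, seed = 5)
  expect_true(isSymmetric(lex$weights))
  expect_equal(unname(diag(lex$weights)), rep(0, 30))
  nz <- lex$weights[upper.tri(lex$weights)]
  expect_true(all(nz[nz > 0] <= 1))
  g <- igraph::graph_from_adjacency_matrix((lex$weights > 0) * 1, mode = "undirected")
  expect_true(igraph::is_connected(g))
  # bit-reproducible under the same seed
  lex2 <- ground_truth_lexicon(n_words = 30, n_blocks = 3, seed = 5)
  expect_identical(lex$weights, lex2$weights)
  # single block: all weights near w_in
  l1 <- ground_truth_lexicon(n_words = 10, n_blocks = 1, w_in = 0.7,
                             w_out = 0.2, jitter = 0.05, seed = 2)
  ww <- l1$weights[upper.tri(l1$weights)]
  expect_true(all(abs(ww - 0.7) <= 0.05 + 1e-12))
})

test_that("the planted partition is more modular than a degree-matched rewiring", {
  lex <- ground_truth_lexicon(seed = 9)
  q_planted <- oracle_modularity(lex$weights, lex$blocks)
  # rewire the binary structure preserving degrees, reassign the weights
  g <- igraph::graph_from_adjacency_matrix((lex$weights > 0) * 1, mode = "undirected")
  set.seed(10)
  gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 500))
  wr <- as.matrix(igraph::as_adjacency_matrix(gr)) * 1.0
  wvals <- lex$weights[upper.tri(lex$weights) & lex$weights > 0]
  wr[upper.tri(wr) & wr > 0] <- sample(wvals, sum(wr[upper.tri(wr)] > 0), replace = TRUE)
  wr[lower.tri(wr)] <- t(wr)[lower.tri(wr)]
  q_rewired <- oracle_modularity(wr, lex$blocks)
  expect_gt(q_planted, q_rewired)
})

test_that("degradation is identity at 0, a spanning skeleton at 1, binomial in between", {
  lex <- ground_truth_lexicon(n_words = 20, n_blocks = 2, seed = 3)
  expect_identical(degrade_network(lex, 0)$weights, lex$weights)
  d1 <- degrade_network(lex, 1, seed = 4)
  g <- igraph::graph_from_adjacency_matrix((d1$weights > 0) * 1, mode = "undirected")
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::ecount(g), 19)   # tree on 20 nodes
  # removal count is binomial(m, p) on average
  m <- sum(lex$weights[upper.tri(lex$weights)] > 0)
  p <- 0.3
  removed <- vapply(1:100, function(s) {
    d <- degrade_network(lex, p, seed = s)
    m - sum(d$weights[upper.tri(d$weights)] > 0)
  }, 1)
  se <- sqrt(p * (1 - p) * m) / sqrt(100)
  expect_lt(abs(mean(removed) - p * m), 4 * se + 1)
})

test_that("participants emit first-visit walks with recoverable injected noise", {
  lex <- ground_truth_lexicon(n_words = 25, n_blocks = 5, seed = 6)
  pf <- group_profile("g", n = 2, list_mean = 10, list_sd = 2,
                      perseveration = 0.3, intrusion = 0.2, variant = 0.3)
  dict <- default_dictionary()
  set.seed(77)
  for (i in 1:20) {
    sim <- simulate_participant(lex, pf, dict)
    expect_false(any(duplicated(sim$true_words)))
    d <- fluency_data("p", "g", list(sim$responses))
    log <- clean_fluency(d, dict)$log$counts
    expect_equal(log$perseverations, unname(sim$injected["perseverations"]))
    expect_equal(log$intrusions, unname(sim$injected["intrusions"]))
    expect_equal(log$variants, unname(sim$injected["variants"]))
    expect_equal(log$retained, length(sim$true_words))
  }
  # single-word lexicon: exactly one response
  l1 <- structure(list(words = "dog", weights = matrix(0, 1, 1), blocks = 1L),
                  class = "ground_truth_lexicon")
  pf0 <- group_profile("g", n = 2, list_mean = 5, list_sd = 1,
                       perseveration = 0, intrusion = 0, variant = 0)
  expect_equal(length(simulate_participant(l1, pf0, dict)$true_words), 1)
})

test_that("jump probability 1 yields near-uniform first responses", {
  lex <- ground_truth_lexicon(n_words = 10, n_blocks = 2, seed = 8)
  pf <- group_profile("g", n = 2, list_mean = 3, list_sd = 0.1, jump = 1,
                      perseveration = 0, intrusion = 0, variant = 0)
  set.seed(55)
  firsts <- replicate(600, simulate_participant(lex, pf)$true_words[2])
  tab <- table(factor(firsts, levels = lex$words))
  # second emission under pure teleporting is uniform over the lexicon
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("cohort simulation is deterministic and orders group counts by construction", {
  pf <- list(a = group_profile("a", n = 8, list_mean = 12, list_sd = 2),
             b = group_profile("b", n = 8, list_mean = 12, list_sd = 2))
  co1 <- simulate_cohort(pf, seed = 101)
  co2 <- simulate_cohort(pf, seed = 101)
  expect_identical(co1$data$responses, co2$data$responses)
  expect_identical(co1$data$covariates, co2$data$covariates)
  expect_named(co1$manifest, co1$data$participant)

  # decreasing walk-length means produce strictly ordered group mean counts
  prof <- list(hi = group_profile("hi", n = 30, list_mean = 18, list_sd = 3),
               mid = group_profile("mid", n = 30, list_mean = 11, list_sd = 3),
               lo = group_profile("lo", n = 30, list_mean = 6, list_sd = 3))
  ok <- 0
  for (s in 1:40) {
    co <- simulate_cohort(prof, seed = s)
    cts <- response_counts(clean_fluency(co$data)$data)
    mu <- tapply(cts$count, cts$group, mean)
    if (mu["hi"] > mu["mid"] && mu["mid"] > mu["lo"]) ok <- ok + 1
  }
  expect_gte(ok / 40, 0.95)
})

test_that("identical profiles give equal mean counts within Monte-Carlo error", {
  pf <- list(a = group_profile("a", n = 60, list_mean = 15, list_sd = 4),
             b = group_profile("b", n = 60, list_mean = 15, list_sd = 4))
  diffs <- vapply(1:12, function(s) {
    co <- simulate_cohort(pf, seed = 1000 + s)
    cts <- response_counts(clean_fluency(co$data)$data)
    mu <- tapply(cts$count, cts$group, mean)
    se <- sqrt(sum(tapply(cts$count, cts$group, var) / 60))
    (mu["a"] - mu["b"]) / se
  }, 1)
  # standardized differences behave like a null z: most within 2 SEs
  expect_gte(mean(abs(diffs) < 2), 0.85)
})

test_that("network degradation grades with profile severity across cohorts", {
  # mean metrics over seeded cohorts order control -> fluent-like ->
  # nonfluent-like: longer paths, less clustering, more modular
  groups <- c("control", "fluent", "nonfluent")
  pf <- default_profiles()[groups]
  arr <- array(NA, c(3, 3, 12), dimnames = list(c("aspl", "cc", "q"), groups, NULL))
  for (s in 1:12) {
    co <- simulate_cohort(pf, seed = 7000 + s)
    cl <- clean_fluency(co$data)
    for (g in groups) {
      m <- filter_min_producers(response_matrix(cl$data[cl$data$group == g]))
      net <- semantic_network(m)
      gm <- global_metrics(net, seed = s)
      arr[, g, s] <- c(gm$aspl, gm$cc, gm$q)
    }
  }
  mu <- apply(arr, c(1, 2), mean)
  expect_lt(mu["aspl", "control"], mu["aspl", "fluent"])
  expect_lt(mu["aspl", "fluent"], mu["aspl", "nonfluent"])
  expect_gt(mu["cc", "control"], mu["cc", "fluent"])
  expect_gt(mu["cc", "fluent"], mu["cc", "nonfluent"])
  expect_lt(mu["q", "control"], mu["q", "fluent"])
  expect_lt(mu["q", "fluent"], mu["q", "nonfluent"])
})
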