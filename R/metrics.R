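#' Average shortest path length
#'
#' Mean hop-count distance over all unordered pairs of nodes, computed on
#' the unweighted TMFG backbone (edge presence, not weight). On
#' disconnected graphs (possible for Erdos-Renyi null replicates) only
#' connected pairs enter the average.
#'
#' @param net a `semantic_network`, an igraph graph, or an adjacency matrix.
#' @return A single number `>= 1` for any graph with an edge.
#' @export
aspl <- function(net) {
  g <- .as_backbone(net)
  if (igraph::ecount(g) == 0L) stop("undefined metric: network has no edges")
  d <- igraph::distances(g, weights = NA)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  mean(d)
}

#' Global clustering coefficient
#'
#' Mean over nodes of the unweighted local clustering coefficient; nodes
#' of degree below 2 contribute zero.
#'
#' @inheritParams aspl
#' @return A number in `[0, 1]`.
#' @export
global_cc <- function(net) {
  g <- .as_backbone(net)
  if (igraph::vcount(g) < 3L) stop("need at least 3 nodes")
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Modularity via seeded Louvain optimization
#'
#' Runs Louvain community detection on the weighted adjacency with a fixed
#' number of restarts (vertex-order permutations) under the given seed and
#' keeps the best Q.
#'
#' @param net a `semantic_network` or weighted adjacency matrix.
#' @param seed integer seed (restarts permute vertex order deterministically).
#' @param restarts number of Louvain restarts (default 10).
#' @param weighted use edge weights (default TRUE; the Erdos-Renyi null
#'   uses unweighted graphs).
#' @return A list with `q` (best modularity) and `membership` (integer
#'   community assignment in original node order).
#' @export
modularity_q <- function(net, seed = 1, restarts = 10, weighted = TRUE) {
  g <- if (weighted && (inherits(net, "semantic_network") || is.matrix(net))) {
    .as_weighted_graph(net)
  } else {
    .as_backbone(net)
  }
  if (igraph::ecount(g) == 0L) stop("undefined metric: network has no edges")
  w <- if (weighted && !is.null(igraph::E(g)$weight)) igraph::E(g)$weight else NULL
  if (!is.null(w) && all(w == 0)) w <- NULL   # degenerate: fall back to structure
  n <- igraph::vcount(g)
  best_q <- -Inf
  best_mem <- rep(1L, n)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      perm <- sample.int(n)
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp, weights = if (is.null(w)) NULL else igraph::E(gp)$weight)
      q <- igraph::modularity(cl)
      if (q > best_q) {
        best_q <- q
        mem <- igraph::membership(cl)
        best_mem[perm] <- as.integer(mem)
      }
    }
  })
  list(q = best_q, membership = best_mem)
}

#' Global metrics of a semantic network
#'
#' Computes the three global metrics used throughout the group
#' comparisons: average shortest path length (ASPL) and clustering
#' coefficient (CC) on the unweighted TMFG backbone, and modularity (Q)
#' from seeded Louvain on the weighted adjacency. The unweighted/weighted
#' conventions can be toggled.
#'
#' @param net a `semantic_network`.
#' @param seed seed for the Louvain restarts.
#' @param restarts Louvain restarts.
#' @param weighted_q use edge weights for modularity (default TRUE).
#' @return A list with `aspl`, `cc`, `q` and `membership`.
#' @export
global_metrics <- function(net, seed = NULL, restarts = 10, weighted_q = TRUE) {
  md <- modularity_q(net, seed = seed %||% 1, restarts = restarts,
                     weighted = weighted_q)
  list(aspl = aspl(net), cc = global_cc(net), q = md$q,
       membership = md$membership)
}

#' Local node metrics: strength and Zhang weighted clustering
#'
#' Node strength is the sum of incident edge weights. The local weighted
#' clustering coefficient follows Zhang & Horvath: with weights rescaled
#' by the network maximum (`u = w / max(w)`),
#' `cc_i = sum_{j != k} u_ij u_jk u_ki / ((sum_j u_ij)^2 - sum_j u_ij^2)`.
#' Nodes whose denominator is zero (isolated or single-neighbor nodes)
#' get a local clustering of 0.
#'
#' @param net a `semantic_network` or weighted adjacency matrix.
#' @return A data frame with columns `word`, `strength`, `local_cc`
#'   (rows in network node order).
#' @export
local_metrics <- function(net) {
  w <- if (inherits(net, "semantic_network")) net$adjacency else as.matrix(net)
  words <- colnames(w) %||% paste0("w", seq_len(ncol(w)))
  strength <- rowSums(w)
  mx <- max(w)
  if (mx <= 0) {
    return(data.frame(word = words, strength = strength, local_cc = 0))
  }
  u <- w / mx
  num <- diag(u %*% u %*% u)         # ordered (j, k) pairs, as in the formula
  su <- rowSums(u)
  su2 <- rowSums(u^2)
  den <- su^2 - su2
  cc <- ifelse(den > 0, num / den, 0)
  data.frame(word = words, strength = strength, local_cc = cc,
             stringsAsFactors = FALSE)
}

#' A named sample of a graph metric
#'
#' Container for reference distributions: random-graph baselines,
#' bootstrap samples, or percolation-iteration integrals.
#'
#' @param values numeric sample.
#' @param metric metric name (e.g. `"aspl"`).
#' @param provenance one of `"random-baseline"`, `"bootstrap"`,
#'   `"percolation"`.
#' @param seed the seed the sample was generated under (or `NULL`).
#' @return An object of class `metric_distribution`.
#' @export
metric_distribution <- function(values, metric, provenance, seed = NULL) {
  structure(list(values = as.numeric(values), metric = metric,
                 provenance = provenance, seed = seed,
                 replicates = length(values)),
            class = "metric_distribution")
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat(sprintf("%s distribution of %s: %d replicates, mean %.4f (sd %.4f)\n",
              x$provenance, x$metric, x$replicates,
              mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' @export
mean.metric_distribution <- function(x, ...) mean(x$values)

#' Erdos-Renyi reference distributions
#'
#' Generates `reps` G(n, p) random graphs with `p = 2m / (n (n - 1))`
#' (matching the observed network's density) and computes ASPL (over
#' connected pairs), global CC, and Louvain Q for each, establishing the
#' null distributions that the observed metrics are z-tested against.
#'
#' @param n node count.
#' @param m edge count of the observed network.
#' @param reps number of random graphs (default 1000).
#' @param seed integer seed; the run is fully reproducible.
#' @param restarts Louvain restarts per replicate (default 2; the null
#'   graphs are small and unweighted).
#' @return A list of three [metric_distribution]s: `aspl`, `cc`, `q`.
#' @export
er_baseline <- function(n, m, reps = 1000, seed = NULL, restarts = 2) {
  if (n < 3) stop("need at least 3 nodes")
  p <- 2 * m / (n * (n - 1))
  if (p <= 0 || p > 1) stop("edge probability out of (0, 1]: ", p)
  out <- matrix(NA_real_, reps, 3, dimnames = list(NULL, c("aspl", "cc", "q")))
  with_seed(seed, {
    for (r in seq_len(reps)) {
      g <- igraph::sample_gnp(n, p)
      out[r, "aspl"] <- if (igraph::ecount(g) > 0) {
        d <- igraph::distances(g)
        d <- d[upper.tri(d)]
        mean(d[is.finite(d)])
      } else NA_real_
      out[r, "cc"] <- igraph::transitivity(g, type = "localaverage",
                                           isolates = "zero")
      out[r, "q"] <- if (igraph::ecount(g) > 0) {
        qb <- -Inf
        for (k in seq_len(restarts)) {
          cl <- igraph::cluster_louvain(g)
          qb <- max(qb, igraph::modularity(cl))
        }
        qb
      } else NA_real_
    }
  })
  lapply(stats::setNames(colnames(out), colnames(out)), function(mt) {
    metric_distribution(out[, mt][!is.na(out[, mt])], mt,
                        "random-baseline", seed)
  })
}

#' One-sample z-test of an observed metric against a reference distribution
#'
#' `z = (observed - mean) / sd` with a two-sided normal p value.
#'
#' @param observed observed metric value.
#' @param dist a [metric_distribution].
#' @return A list of class `stat_result` with `statistic`, `z`, `p`,
#'   `mean`, `sd`.
#' @export
z_test <- function(observed, dist) {
  v <- if (inherits(dist, "metric_distribution")) dist$values else as.numeric(dist)
  if (length(v) < 2 || stats::sd(v) == 0) {
    stop("degenerate reference distribution (zero spread)")
  }
  z <- (observed - mean(v)) / stats::sd(v)
  structure(list(kind = "z", statistic = z, df = NA_real_,
                 p = 2 * stats::pnorm(-abs(z)),
                 mean = mean(v), sd = stats::sd(v), observed = observed),
            class = "stat_result")
}

#' Pooled-variance two-sample t-test with Cohen's d
#'
#' Student's t with `df = n_a + n_b - 2`, the test used for all
#' distribution-level group contrasts (bootstrap metric distributions,
#' percolation integrals). Cohen's d uses the pooled SD.
#'
#' @param a,b numeric samples or [metric_distribution]s.
#' @return A `stat_result` with `statistic`, `df`, `p`, `d`, and the two
#'   sample means/SDs.
#' @export
pooled_t_test <- function(a, b) {
  av <- if (inherits(a, "metric_distribution")) a$values else as.numeric(a)
  bv <- if (inherits(b, "metric_distribution")) b$values else as.numeric(b)
  na <- length(av); nb <- length(bv)
  if (na < 2 || nb < 2) stop("degenerate input: need >= 2 values per sample")
  sp2 <- ((na - 1) * stats::var(av) + (nb - 1) * stats::var(bv)) / (na + nb - 2)
  if (sp2 == 0) {
    # two identical constant samples (e.g. bootstrap with proportion 1)
    if (isTRUE(all.equal(mean(av), mean(bv)))) {
      return(structure(list(kind = "t", statistic = 0, df = na + nb - 2,
                            p = 1, d = 0, mean_a = mean(av), sd_a = 0,
                            mean_b = mean(bv), sd_b = 0),
                       class = "stat_result"))
    }
    stop("degenerate input: zero pooled variance with unequal means")
  }
  tval <- (mean(av) - mean(bv)) / sqrt(sp2 * (1 / na + 1 / nb))
  structure(list(kind = "t", statistic = tval, df = na + nb - 2,
                 p = 2 * stats::pt(-abs(tval), na + nb - 2),
                 d = (mean(av) - mean(bv)) / sqrt(sp2),
                 mean_a = mean(av), sd_a = stats::sd(av),
                 mean_b = mean(bv), sd_b = stats::sd(bv)),
            class = "stat_result")
}

#' Paired t-test with Cohen's d for paired designs
#'
#' Used for node-matched contrasts (local metrics, per-time-step
#' activation) across equated networks; `d` is the mean difference divided
#' by the SD of differences.
#'
#' @param a,b numeric vectors matched element-wise.
#' @return A `stat_result`.
#' @export
paired_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired samples differ in length")
  dd <- a - b
  n <- length(dd)
  sd_d <- stats::sd(dd)
  if (n < 2) stop("degenerate input")
  tval <- if (sd_d == 0) 0 else mean(dd) / (sd_d / sqrt(n))
  structure(list(kind = "paired-t", statistic = tval, df = n - 1,
                 p = if (sd_d == 0) 1 else 2 * stats::pt(-abs(tval), n - 1),
                 d = if (sd_d == 0) 0 else mean(dd) / sd_d,
                 mean_diff = mean(dd)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  if (x$kind == "z") {
    cat(sprintf("z = %.3f, p = %.3g (reference mean %.4f, sd %.4f)\n",
                x$statistic, x$p, x$mean, x$sd))
  } else {
    cat(sprintf("%s(%s) = %.3f, p = %.3g%s\n", x$kind,
                format(x$df), x$statistic, x$p,
                if (!is.null(x$d)) sprintf(", d = %.3f", x$d) else ""))
  }
  invisible(x)
}

#' Paired comparison of local metrics between equated networks
#'
#' @param a,b data frames from [local_metrics()] over identical word sets.
#' @return A list with `strength` and `local_cc` paired-t `stat_result`s.
#' @export
compare_local_metrics <- function(a, b) {
  if (!identical(a$word, b$word)) stop("node sets do not match (networks not equated)")
  list(strength = paired_t_test(a$strength, b$strength),
       local_cc = paired_t_test(a$local_cc, b$local_cc))
}

#' Node-wise bootstrap of partial semantic networks
#'
#' Repeatedly draws a random half (by default) of the shared word set,
#' restricts both groups' response matrices to that subset, re-estimates
#' each group's network (cosine + TMFG) and records ASPL, CC and Q. The
#' same word subset is used for both groups within a replicate, so the
#' paired sampling variability reflects node composition, not vocabulary
#' differences. Each metric's two distributions are then compared with a
#' pooled t-test.
#'
#' @param a,b node-equated [response_matrix] objects (identical columns).
#' @param reps bootstrap replicates (default 1000).
#' @param proportion fraction of shared words per draw (default 0.5;
#'   `ceiling(proportion * n)` words, sampled without replacement).
#' @param seed integer seed.
#' @param restarts Louvain restarts per replicate network (default 5).
#' @return A list of class `bootstrap_comparison`: `distributions` (per
#'   metric, per group [metric_distribution]s) and `tests` (per metric
#'   pooled-t `stat_result`s).
#' @export
bootstrap_networks <- function(a, b, reps = 1000, proportion = 0.5,
                               seed = NULL, restarts = 5) {
  if (!identical(colnames(a), colnames(b))) {
    stop("matrices are not node-equated (different word sets)")
  }
  n <- ncol(a)
  k <- ceiling(proportion * n)
  if (k < 4) stop("subset too small for TMFG: ", k, " words")
  metrics <- c("aspl", "cc", "q")
  res <- list(a = matrix(NA_real_, reps, 3, dimnames = list(NULL, metrics)),
              b = matrix(NA_real_, reps, 3, dimnames = list(NULL, metrics)))
  with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, k))
      for (gname in c("a", "b")) {
        m <- (if (gname == "a") a else b)[, idx, drop = FALSE]
        net <- semantic_network(structure(m, class = c("response_matrix", "matrix")))
        gm <- global_metrics(net, seed = sample.int(.Machine$integer.max, 1),
                             restarts = restarts)
        res[[gname]][r, ] <- c(gm$aspl, gm$cc, gm$q)
      }
    }
  })
  dists <- lapply(stats::setNames(metrics, metrics), function(mt) {
    list(a = metric_distribution(res$a[, mt], mt, "bootstrap", seed),
         b = metric_distribution(res$b[, mt], mt, "bootstrap", seed))
  })
  tests <- lapply(dists, function(d) pooled_t_test(d$a, d$b))
  structure(list(distributions = dists, tests = tests,
                 reps = reps, proportion = proportion, seed = seed),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf("Node-wise bootstrap comparison (%d replicates, proportion %.2f)\n",
              x$reps, x$proportion))
  for (mt in names(x$tests)) {
    te <- x$tests[[mt]]
    cat(sprintf("  %-5s A: %.3f (%.3f)  B: %.3f (%.3f)  t(%d) = %.2f, p = %.3g, d = %.2f\n",
                mt, te$mean_a, te$sd_a, te$mean_b, te$sd_b,
                te$df, te$statistic, te$p, te$d))
  }
  invisible(x)
}

#' Write metric distributions as CSV
#'
#' One column per metric, one row per replicate; provenance and seed are
#' recorded in a comment header line.
#'
#' @param dists named list of [metric_distribution]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distributions <- function(dists, path) {
  df <- as.data.frame(lapply(dists, function(d) d$values))
  prov <- unique(vapply(dists, function(d) d$provenance, ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", paste(prov, collapse = ","),
                    "; seed: ", dists[[1]]$seed %||% "NULL"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# --- internal graph coercions -------------------------------------------

.as_backbone <- function(net) {
  if (inherits(net, "semantic_network")) return(as_igraph(net, weighted = FALSE))
  if (inherits(net, "igraph")) return(net)
  if (is.matrix(net)) {
    return(igraph::graph_from_adjacency_matrix((net != 0) * 1, mode = "undirected"))
  }
  stop("cannot interpret network object")
}

.as_weighted_graph <- function(net) {
  if (inherits(net, "semantic_network")) return(as_igraph(net, weighted = TRUE))
  if (inherits(net, "igraph")) return(net)
  if (is.matrix(net)) {
    return(igraph::graph_from_adjacency_matrix(net, mode = "undirected",
                                               weighted = TRUE))
  }
  stop("cannot interpret network object")
}
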