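#' Enumerate k-cliques of a semantic network with their intensities
#'
#' A k-clique is a fully connected set of k nodes of the (unweighted)
#' TMFG backbone; its intensity is the geometric mean of its edge weights,
#' the standard weighted clique-percolation convention.
#'
#' @param net a `semantic_network` or weighted adjacency matrix.
#' @param k clique size (default 3, the most sensitive choice).
#' @return A data frame with one row per clique: columns `n1..nk` (node
#'   indices), `intensity`, and a `words` attribute.
#' @export
clique_intensities <- function(net, k = 3) {
  stopifnot(k >= 3)
  w <- if (inherits(net, "semantic_network")) net$adjacency else as.matrix(net)
  structure_m <- if (inherits(net, "semantic_network")) {
    edge_structure(net)
  } else w != 0
  g <- igraph::graph_from_adjacency_matrix(structure_m * 1, mode = "undirected")
  cl <- igraph::cliques(g, min = k, max = k)
  words <- colnames(w) %||% paste0("w", seq_len(ncol(w)))
  if (length(cl) == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, k + 1))
    names(out) <- c(paste0("n", seq_len(k)), "intensity")
    attr(out, "words") <- words
    return(out)
  }
  nodes <- t(vapply(cl, function(x) sort(as.integer(x)), integer(k)))
  pairs <- utils::combn(k, 2)
  inten <- apply(nodes, 1, function(nd) {
    ws <- w[cbind(nd[pairs[1, ]], nd[pairs[2, ]])]
    geometric_mean(ws)
  })
  ord <- do.call(order, as.data.frame(nodes))
  out <- as.data.frame(nodes[ord, , drop = FALSE])
  names(out) <- paste0("n", seq_len(k))
  out$intensity <- inten[ord]
  attr(out, "words") <- words
  out
}

#' Clique communities at an intensity threshold
#'
#' Cliques whose intensity falls below the threshold are dropped; the
#' survivors are merged into communities: two k-cliques are adjacent when
#' they share k - 1 nodes, and a community is a connected component of
#' that clique-adjacency graph. A community's node set is the union of
#' its cliques' nodes.
#'
#' @param cliques data frame from [clique_intensities()].
#' @param threshold intensity threshold I; cliques with
#'   `intensity < threshold` are removed.
#' @return A list of integer vectors (node indices), one per community,
#'   ordered by their smallest member.
#' @export
clique_communities <- function(cliques, threshold) {
  k <- sum(grepl("^n[0-9]+$", names(cliques)))
  keep <- cliques$intensity >= threshold
  nodes <- as.matrix(cliques[keep, seq_len(k), drop = FALSE])
  nc <- nrow(nodes)
  if (nc == 0L) return(list())
  # union-find over cliques; adjacency = sharing k - 1 nodes
  parent <- seq_len(nc)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nc > 1L) {
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        if (length(intersect(nodes[i, ], nodes[j, ])) == k - 1L) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(nc), find, 1L)
  comms <- lapply(split(seq_len(nc), roots), function(ix) {
    sort(unique(as.vector(nodes[ix, , drop = FALSE])))
  })
  comms[order(vapply(comms, min, 1L))]
}

#' Connected-node curve across the intensity sweep
#'
#' For each threshold I on the grid, counts the nodes that belong to at
#' least one surviving k-clique community (equivalently, to at least one
#' clique with intensity >= I). The count is non-increasing in I: the
#' curve tracks how the network fragments as weaker cliques are removed.
#'
#' @param net a `semantic_network` or weighted adjacency matrix.
#' @param k clique size (default 3).
#' @param thresholds intensity grid (default 0.01 to 1 in steps of 0.01).
#' @return An object of class `percolation_curve`: data frame with
#'   columns `threshold` and `connected_nodes`, plus attributes `n_nodes`
#'   and `step`.
#' @export
percolation_curve <- function(net, k = 3,
                              thresholds = seq(0.01, 1, by = 0.01)) {
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0) || any(thresholds > 1)) {
    stop("threshold grid must be strictly increasing within (0, 1]")
  }
  cl <- clique_intensities(net, k)
  n <- length(attr(cl, "words"))
  kk <- sum(grepl("^n[0-9]+$", names(cl)))
  # a node survives at I iff the max intensity over its cliques is >= I
  node_max <- rep(-Inf, n)
  if (nrow(cl) > 0) {
    idx <- unlist(cl[seq_len(kk)], use.names = FALSE)
    ints <- rep(cl$intensity, times = kk)
    agg <- tapply(ints, idx, max)
    node_max[as.integer(names(agg))] <- agg
  }
  counts <- vapply(thresholds, function(th) sum(node_max >= th), 1L)
  structure(data.frame(threshold = thresholds, connected_nodes = counts),
            class = c("percolation_curve", "data.frame"),
            n_nodes = n, step = if (length(thresholds) > 1) diff(thresholds)[1] else thresholds[1])
}

#' Percolation integral: area under the connected-node curve
#'
#' Left Riemann sum of the connected-node counts over the intensity grid
#' (count x step, summed). Lower integrals mean the network loses
#' clique-connected nodes at lower intensities, i.e. fragments sooner and
#' is less resilient.
#'
#' @param curve a [percolation_curve].
#' @return A single number in `[0, n * grid span]`.
#' @export
percolation_integral <- function(curve) {
  step <- attr(curve, "step") %||% diff(curve$threshold)[1]
  sum(curve$connected_nodes * step)
}

#' Iterated percolation comparison between two groups
#'
#' Each iteration resamples participants with replacement within each
#' group, re-estimates that group's network on the fixed equated word set
#' (cosine + TMFG), and computes the percolation integral. If a resample
#' leaves a word with zero producers the replicate is redrawn (and
#' counted). The two integral distributions are compared with a pooled
#' t-test (`df = 2 * iterations - 2`).
#'
#' @param a,b node-equated [response_matrix] objects.
#' @param iterations resampling iterations (default 500).
#' @param k clique size (default 3).
#' @param thresholds intensity grid (see [percolation_curve()]).
#' @param seed integer seed.
#' @param mode `"participant-bootstrap"` (default) or `"node-subsample"`
#'   (half of the words per iteration, shared between groups).
#' @return A list of class `percolation_comparison`: `integrals` (two
#'   [metric_distribution]s), `test` (pooled-t `stat_result`), `redraws`.
#' @export
percolation_comparison <- function(a, b, iterations = 500, k = 3,
                                   thresholds = seq(0.01, 1, by = 0.01),
                                   seed = NULL,
                                   mode = c("participant-bootstrap",
                                            "node-subsample")) {
  mode <- match.arg(mode)
  if (!identical(colnames(a), colnames(b))) {
    stop("matrices are not node-equated (different word sets)")
  }
  res <- list(a = numeric(iterations), b = numeric(iterations))
  redraws <- 0L
  one_integral <- function(m) {
    net <- semantic_network(structure(m, class = c("response_matrix", "matrix")))
    percolation_integral(percolation_curve(net, k, thresholds))
  }
  # the per-iteration seed does not depend on the group, so identical
  # inputs yield identical resamples (and a == b gives t = 0 exactly)
  for (it in seq_len(iterations)) {
    it_seed <- derive_seed(seed %||% 0, paste0("percolation-iter-", it))
    if (mode == "participant-bootstrap") {
      for (gname in c("a", "b")) {
        m0 <- if (gname == "a") a else b
        with_seed(it_seed, {
          repeat {
            rows <- sample.int(nrow(m0), nrow(m0), replace = TRUE)
            m <- m0[rows, , drop = FALSE]
            if (all(colSums(m) > 0)) break
            redraws <- redraws + 1L
          }
        })
        res[[gname]][it] <- one_integral(m)
      }
    } else {
      with_seed(it_seed, {
        nw <- ncol(a)
        idx <- sort(sample.int(nw, ceiling(nw / 2)))
      })
      res$a[it] <- one_integral(a[, idx, drop = FALSE])
      res$b[it] <- one_integral(b[, idx, drop = FALSE])
    }
  }
  dists <- list(a = metric_distribution(res$a, "percolation_integral",
                                        "percolation", seed),
                b = metric_distribution(res$b, "percolation_integral",
                                        "percolation", seed))
  structure(list(integrals = dists, test = pooled_t_test(dists$a, dists$b),
                 iterations = iterations, mode = mode, redraws = redraws),
            class = "percolation_comparison")
}

#' @export
print.percolation_comparison <- function(x, ...) {
  te <- x$test
  cat(sprintf("Percolation comparison (%d iterations, %s)\n",
              x$iterations, x$mode))
  cat(sprintf("  integral A: %.2f (%.2f)  B: %.2f (%.2f)  t(%d) = %.2f, p = %.3g\n",
              te$mean_a, te$sd_a, te$mean_b, te$sd_b, te$df, te$statistic, te$p))
  if (x$redraws > 0) cat("  redrawn resamples:", x$redraws, "\n")
  invisible(x)
}
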