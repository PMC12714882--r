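#' Cosine similarity between words of a binary response matrix
#'
#' For binary occurrence data the cosine similarity of two words is the
#' co-producer count divided by the geometric mean of the two producer
#' counts: `sim(i, j) = n_ij / sqrt(n_i * n_j)`. Values lie in `[0, 1]`;
#' zero means the two words never co-occur across participants. The
#' diagonal is set to zero (self-similarity carries no information for
#' network estimation).
#'
#' @param m a binary [response_matrix] (participants x words).
#' @return A symmetric numeric matrix with zero diagonal and the word
#'   labels of `m` as dimnames.
#' @export
cosine_similarity <- function(m) {
  m <- unclass(m)
  storage.mode(m) <- "double"
  ncounts <- colSums(m)
  if (any(ncounts == 0)) {
    stop("zero-producer column(s): ", paste(colnames(m)[ncounts == 0][1:3], collapse = ", "))
  }
  co <- crossprod(m)                 # n_ij
  s <- co / sqrt(outer(ncounts, ncounts))
  diag(s) <- 0
  s
}

# cache of quadruple/pair index tables used by the TMFG seed search,
# keyed by node count (combn is the expensive part, the lookups are cheap)
.tmfg_cache <- new.env(parent = emptyenv())

.tmfg_quads <- function(n) {
  key <- as.character(n)
  if (!is.null(.tmfg_cache[[key]])) return(.tmfg_cache[[key]])
  q <- utils::combn(n, 4L)
  pairs <- utils::combn(4L, 2L)
  idx <- lapply(seq_len(6L), function(p) {
    cbind(q[pairs[1, p], ], q[pairs[2, p], ])
  })
  val <- list(quads = q, pair_idx = idx)
  if (n <= 120L) .tmfg_cache[[key]] <- val
  val
}

#' Triangulated maximally filtered graph (TMFG)
#'
#' Greedy planar sparsification of a weighted similarity matrix. The seed
#' is the 4-node clique with the largest total edge weight; nodes are then
#' inserted one at a time, each chosen (with its host triangular face) to
#' maximize the summed similarity to the face's three vertices. The result
#' is a maximal planar graph with exactly `3n - 6` edges, connected, with
#' the original similarities retained as edge weights. Ties are broken
#' toward the lowest node index and then the earliest-created face, so the
#' construction is deterministic.
#'
#' @param w symmetric similarity matrix with zero diagonal, `n >= 3`
#'   (`n = 3` returns the triangle).
#' @return A list with `adjacency` (weighted, symmetric, zero diagonal),
#'   `faces` (integer matrix, one triangular face per row, a planar
#'   embedding certificate), and `seed_clique` (the 4 seed node indices,
#'   or the triangle for `n = 3`).
#' @export
tmfg <- function(w) {
  w <- as.matrix(w)
  n <- nrow(w)
  if (n < 3L) stop("too few nodes for TMFG: need at least 3, got ", n)
  if (!isSymmetric(unname(w), tol = 1e-10)) stop("similarity matrix must be symmetric")
  diag(w) <- 0
  adj <- matrix(0, n, n, dimnames = dimnames(w))
  if (n == 3L) {
    adj <- w
    return(list(adjacency = adj, faces = matrix(1:3, nrow = 1),
                seed_clique = 1:3))
  }
  qt <- .tmfg_quads(n)
  tot <- numeric(ncol(qt$quads))
  for (p in qt$pair_idx) tot <- tot + w[p]
  best <- which.max(tot)            # ties: first in combn order = lowest indices
  seed <- qt$quads[, best]
  for (i in 1:3) for (j in (i + 1):4) {
    a <- seed[i]; b <- seed[j]
    adj[a, b] <- w[a, b]; adj[b, a] <- w[b, a]
  }
  faces <- rbind(seed[c(1, 2, 3)], seed[c(1, 2, 4)],
                 seed[c(1, 3, 4)], seed[c(2, 3, 4)])
  remaining <- setdiff(seq_len(n), seed)
  # gains[v, f] = summed similarity of node v to the vertices of face f
  gains <- matrix(-Inf, n, 4L)
  for (f in 1:4) gains[remaining, f] <- rowSums(w[remaining, faces[f, ], drop = FALSE])
  n_faces <- 4L
  while (length(remaining)) {
    sub <- gains[remaining, seq_len(n_faces), drop = FALSE]
    best_val <- max(sub)
    hit <- which(sub == best_val, arr.ind = TRUE)
    # lowest node index first, then earliest face
    hit <- hit[order(remaining[hit[, 1]], hit[, 2]), , drop = FALSE]
    v <- remaining[hit[1, 1]]
    f <- hit[1, 2]
    tri <- faces[f, ]
    adj[v, tri] <- w[v, tri]
    adj[tri, v] <- w[tri, v]
    new_faces <- rbind(c(v, tri[1], tri[2]), c(v, tri[1], tri[3]),
                       c(v, tri[2], tri[3]))
    faces[f, ] <- new_faces[1, ]
    faces <- rbind(faces, new_faces[2:3, ])
    remaining <- setdiff(remaining, v)
    if (length(remaining)) {
      if (ncol(gains) < n_faces + 2L) {
        gains <- cbind(gains, matrix(-Inf, n, max(8L, n_faces)))
      }
      for (fi in c(f, n_faces + 1L, n_faces + 2L)) {
        gains[remaining, fi] <- rowSums(w[remaining, faces[fi, ], drop = FALSE])
      }
    }
    n_faces <- n_faces + 2L
  }
  list(adjacency = adj, faces = faces[seq_len(n_faces), , drop = FALSE],
       seed_clique = seed)
}

#' Estimate a semantic network from fluency responses
#'
#' The central estimator: converts a binary response matrix into a
#' weighted, undirected semantic network by computing cosine similarities
#' between words and sparsifying them with the triangulated maximally
#' filtered graph. The returned object carries the retained edge weights
#' (used by the percolation analysis) and the planar-embedding face list.
#'
#' A pre-computed similarity matrix may be supplied instead of a response
#' matrix, e.g. to estimate a network from an externally derived
#' relatedness matrix.
#'
#' @param x a [response_matrix], or a symmetric similarity matrix with
#'   zero diagonal (square numeric matrix with identical dimnames).
#' @param ... currently unused.
#' @return An object of class `semantic_network` with elements `words`,
#'   `similarity`, `adjacency` (TMFG-filtered weighted adjacency),
#'   `faces`, `group` and `call`. Methods: [print.semantic_network()],
#'   [summary.semantic_network()], [plot.semantic_network()],
#'   [simulate.semantic_network()], [as.matrix.semantic_network()].
#' @examples
#' set.seed(1)
#' m <- matrix(rbinom(80, 1, 0.5), 10, 8,
#'             dimnames = list(paste0("p", 1:10), letters[1:8]))
#' m <- m[, colSums(m) > 0]
#' net <- semantic_network(structure(m, class = c("response_matrix", "matrix")))
#' net
#' @export
semantic_network <- function(x, ...) {
  cl <- match.call()
  if (inherits(x, "response_matrix")) {
    sim <- cosine_similarity(x)
    grp <- attr(x, "group")
  } else {
    x <- as.matrix(x)
    if (nrow(x) != ncol(x)) stop("x must be a response_matrix or a square similarity matrix")
    sim <- x
    diag(sim) <- 0
    grp <- NULL
  }
  fit <- tmfg(sim)
  structure(list(words = colnames(sim) %||% paste0("w", seq_len(ncol(sim))),
                 similarity = sim, adjacency = fit$adjacency,
                 faces = fit$faces, seed_clique = fit$seed_clique,
                 group = grp, call = cl),
            class = "semantic_network")
}

#' @export
print.semantic_network <- function(x, ...) {
  n <- length(x$words)
  cat("Semantic network (cosine + TMFG)\n")
  if (!is.null(x$group)) cat("  group:", x$group, "\n")
  cat("  nodes:", n, " edges:", n_edges(x), "(3n - 6 =", 3 * n - 6, ")\n")
  cat("  mean edge weight:", format(mean(edge_weights(x)), digits = 3), "\n")
  invisible(x)
}

#' Number of retained edges of a semantic network
#' @param net a `semantic_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) {
  ut <- upper.tri(net$adjacency)
  sum(edge_structure(net)[ut])
}

# logical adjacency: which edges were retained by the filter (weight may be 0
# when two retained words never co-occur, so structure is tracked via faces)
edge_structure <- function(net) {
  n <- length(net$words)
  s <- matrix(FALSE, n, n)
  f <- net$faces
  for (i in seq_len(nrow(f))) {
    tri <- f[i, ]
    s[tri[1], tri[2]] <- s[tri[2], tri[1]] <- TRUE
    s[tri[1], tri[3]] <- s[tri[3], tri[1]] <- TRUE
    s[tri[2], tri[3]] <- s[tri[3], tri[2]] <- TRUE
  }
  s
}

#' Edge weights of a semantic network
#' @param net a `semantic_network`.
#' @return Numeric vector of retained edge weights (upper triangle order).
#' @export
edge_weights <- function(net) {
  ut <- upper.tri(net$adjacency)
  net$adjacency[ut][edge_structure(net)[ut]]
}

#' @export
as.matrix.semantic_network <- function(x, ...) x$adjacency

#' Convert a semantic network to an igraph graph
#'
#' @param net a `semantic_network`.
#' @param weighted if `TRUE` (default) edge weights are attached as the
#'   `weight` attribute; if `FALSE` the unweighted TMFG backbone is
#'   returned (all retained edges, including zero-weight ones).
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net, weighted = TRUE) {
  stopifnot(inherits(net, "semantic_network"))
  s <- edge_structure(net)
  g <- igraph::graph_from_adjacency_matrix(s * 1, mode = "undirected")
  igraph::V(g)$name <- net$words
  if (weighted) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$weight <- net$adjacency[el]
  }
  g
}

#' @export
summary.semantic_network <- function(object, seed = NULL, ...) {
  gm <- global_metrics(object, seed = seed)
  lm_ <- local_metrics(object)
  out <- list(network = object, global = gm,
              strength = summary(lm_$strength),
              local_cc = summary(lm_$local_cc))
  class(out) <- "summary.semantic_network"
  out
}

#' @export
print.summary.semantic_network <- function(x, ...) {
  print(x$network)
  cat(sprintf("  ASPL = %.3f, CC = %.3f, Q = %.3f (%d communities)\n",
              x$global$aspl, x$global$cc, x$global$q,
              length(unique(x$global$membership))))
  cat("  node strength: median", format(stats::median(x$strength), digits = 3),
      " local CC: median", format(stats::median(x$local_cc), digits = 3), "\n")
  invisible(x)
}

#' Plot a semantic network
#'
#' Draws the TMFG backbone with edge width proportional to weight and
#' nodes colored by Louvain community.
#'
#' @param x a `semantic_network`.
#' @param seed seed for the layout and community detection.
#' @param vertex.size,vertex.label.cex passed to [igraph::plot.igraph()].
#' @param ... further arguments passed to [igraph::plot.igraph()].
#' @export
plot.semantic_network <- function(x, seed = 1, vertex.size = 6,
                                  vertex.label.cex = 0.6, ...) {
  g <- as_igraph(x, weighted = TRUE)
  gm <- global_metrics(x, seed = seed)
  lay <- with_seed(seed, igraph::layout_with_fr(g))
  igraph::plot.igraph(
    g, layout = lay,
    vertex.color = gm$membership,
    vertex.size = vertex.size, vertex.label.cex = vertex.label.cex,
    edge.width = 0.5 + 3 * igraph::E(g)$weight / max(c(igraph::E(g)$weight, 1e-12)),
    ...)
  invisible(x)
}

#' Export a semantic network
#'
#' @param net a `semantic_network`.
#' @param path output path.
#' @param format `"graphml"` or `"edgelist"` (CSV with columns
#'   `word_a, word_b, weight`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net, weighted = TRUE), path, format = "graphml")
  } else {
    g <- as_igraph(net, weighted = TRUE)
    el <- igraph::as_edgelist(g)
    utils::write.csv(data.frame(word_a = el[, 1], word_b = el[, 2],
                                weight = igraph::E(g)$weight),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Import a semantic network from a weighted edge list
#'
#' Reads a CSV written by [write_network()] (`format = "edgelist"`) back
#' into a `semantic_network`-compatible adjacency. The TMFG face list is
#' not recoverable from an edge list, so the result is a plain weighted
#' adjacency matrix.
#'
#' @param path CSV with columns `word_a, word_b, weight`.
#' @return A symmetric weighted adjacency matrix.
#' @export
read_network_edgelist <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  words <- sort(unique(c(df$word_a, df$word_b)))
  adj <- matrix(0, length(words), length(words), dimnames = list(words, words))
  for (i in seq_len(nrow(df))) {
    adj[df$word_a[i], df$word_b[i]] <- df$weight[i]
    adj[df$word_b[i], df$word_a[i]] <- df$weight[i]
  }
  adj
}
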