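# Independent brute-force oracles used to validate the package's
# implementations on small instances. These deliberately share no code
# with the implementations they check.

# random symmetric similarity matrix with distinct weights, zero diagonal
random_similarity <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2)
  w <- w + t(w)
  dimnames(w) <- list(paste0("w", seq_len(n)), paste0("w", seq_len(n)))
  w
}

# greedy TMFG, re-implemented as plain loops over every candidate
oracle_tmfg_edges <- function(w) {
  n <- nrow(w)
  quads <- utils::combn(n, 4)
  best_sum <- -Inf; seed4 <- NULL
  for (c in seq_len(ncol(quads))) {
    q <- quads[, c]
    s <- 0
    for (i in 1:3) for (j in (i + 1):4) s <- s + w[q[i], q[j]]
    if (s > best_sum + 1e-12) { best_sum <- s; seed4 <- q }
  }
  edges <- matrix(FALSE, n, n)
  for (i in seed4) for (j in seed4) if (i != j) edges[i, j] <- TRUE
  faces <- list(seed4[c(1, 2, 3)], seed4[c(1, 2, 4)],
                seed4[c(1, 3, 4)], seed4[c(2, 3, 4)])
  remaining <- setdiff(seq_len(n), seed4)
  while (length(remaining)) {
    best_gain <- -Inf; bv <- NA; bf <- NA
    for (fi in seq_along(faces)) {
      for (v in remaining) {
        g <- sum(w[v, faces[[fi]]])
        better <- g > best_gain + 1e-12
        tie <- abs(g - best_gain) <= 1e-12 &&
          (v < bv || (v == bv && fi < bf))
        if (better || tie) { best_gain <- g; bv <- v; bf <- fi }
      }
    }
    tri <- faces[[bf]]
    for (u in tri) { edges[bv, u] <- TRUE; edges[u, bv] <- TRUE }
    faces[[bf]] <- c(bv, tri[1], tri[2])
    faces[[length(faces) + 1]] <- c(bv, tri[1], tri[3])
    faces[[length(faces) + 1]] <- c(bv, tri[2], tri[3])
    remaining <- setdiff(remaining, bv)
  }
  edges
}

# all-pairs shortest paths by Floyd-Warshall on a binary adjacency
oracle_aspl <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj != 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  v <- d[upper.tri(d)]
  mean(v[is.finite(v)])
}

# mean local clustering by explicit triad counting
oracle_global_cc <- function(adj) {
  a <- (adj != 0) * 1
  n <- nrow(a)
  local <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) { local[i] <- 0; next }
    links <- 0
    for (x in seq_len(k - 1)) for (y in (x + 1):k) {
      if (a[nb[x], nb[y]] == 1) links <- links + 1
    }
    local[i] <- 2 * links / (k * (k - 1))
  }
  mean(local)
}

# Zhang weighted local clustering by explicit triple summation
oracle_zhang <- function(w) {
  u <- w / max(w)
  n <- nrow(u)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j != i && k != i && j != k) num <- num + u[i, j] * u[j, k] * u[k, i]
    }
    den <- sum(u[i, -i])^2 - sum(u[i, -i]^2)
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

# weighted modularity of a partition, direct formula
oracle_modularity <- function(w, membership) {
  m2 <- sum(w)
  if (m2 == 0) return(0)
  k <- rowSums(w)
  q <- 0
  n <- nrow(w)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j]) {
      q <- q + w[i, j] - k[i] * k[j] / m2
    }
  }
  q / m2
}

# enumerate all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_label) {
    i <- length(assign) + 1
    if (i > n) { out[[length(out) + 1]] <<- assign; return() }
    for (lab in seq_len(next_label)) {
      rec(c(assign, lab), max(next_label, lab + 1))
    }
  }
  rec(integer(0), 1)
  out
}

oracle_best_modularity <- function(w) {
  parts <- all_partitions(nrow(w))
  max(vapply(parts, function(p) oracle_modularity(w, p), 0))
}

# all k=3 cliques by triple enumeration
oracle_triangles <- function(adj) {
  a <- (adj != 0)
  n <- nrow(a)
  out <- NULL
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (a[i, j] && a[j, k] && a[i, k]) out <- rbind(out, c(i, j, k))
    }
  }
  out
}

# clique communities by repeated merging over shared pairs
oracle_clique_communities <- function(tris, intensities, threshold) {
  keep <- intensities >= threshold
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0) return(list())
  groups <- lapply(seq_len(nrow(tris)), function(i) i)
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      if (is.null(groups[[i]])) next
      for (j in seq_along(groups)) {
        if (i == j || is.null(groups[[j]])) next
        share <- any(vapply(groups[[i]], function(a) {
          any(vapply(groups[[j]], function(b) {
            length(intersect(tris[a, ], tris[b, ])) == 2
          }, TRUE))
        }, TRUE))
        if (share) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[j] <- list(NULL)
          merged <- TRUE
        }
      }
    }
    if (!merged) break
  }
  groups <- Filter(Negate(is.null), groups)
  comms <- lapply(groups, function(ix) sort(unique(as.vector(tris[ix, , drop = FALSE]))))
  comms[order(vapply(comms, min, 1L))]
}

# planarity certificate for a TMFG network: maximal planar triangulation
# bookkeeping (Euler count, all-triangle faces, each edge on two faces)
expect_planar_triangulation <- function(net) {
  n <- length(net$words)
  faces <- net$faces
  expect_equal(nrow(faces), 2 * n - 4)
  edge_face_count <- matrix(0L, n, n)
  for (r in seq_len(nrow(faces))) {
    tri <- faces[r, ]
    expect_length(unique(tri), 3)
    prs <- rbind(tri[c(1, 2)], tri[c(1, 3)], tri[c(2, 3)])
    for (p in seq_len(3)) {
      i <- prs[p, 1]; j <- prs[p, 2]
      edge_face_count[i, j] <- edge_face_count[i, j] + 1L
      edge_face_count[j, i] <- edge_face_count[j, i] + 1L
    }
  }
  m <- sum(edge_face_count[upper.tri(edge_face_count)] > 0)
  expect_equal(m, 3 * n - 6)
  # every edge lies on exactly two triangular faces
  expect_true(all(edge_face_count[edge_face_count > 0] == 2))
  # Euler: V - E + F = 2 (faces include the outer face in this count)
  expect_equal(n - m + nrow(faces), 2)
}

# small response matrix builder
make_rm <- function(lst, group = "g") {
  response_matrix(fluency_data(names(lst), rep(group, length(lst)), lst))
}
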