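#' Parameters of the spreading-activation simulation
#'
#' Defaults follow the standard settings for diffusion on semantic
#' networks: 100 units of initial activation per seeded node, retention
#' `r = 0.5` (each node keeps half of its activation per step and passes
#' the rest to neighbors in proportion to edge weight), no decay, no
#' suppression threshold, 10 time steps.
#'
#' @param initial activation units given to each seeded node.
#' @param retention proportion of activation a node keeps per step, in `[0, 1]`.
#' @param decay proportion of activation lost per step, in `[0, 1]`.
#' @param suppress activations below this value are zeroed after decay.
#' @param time number of time steps (positive integer).
#' @return A list of class `spread_params`.
#' @export
spread_params <- function(initial = 100, retention = 0.5, decay = 0,
                          suppress = 0, time = 10) {
  stopifnot(initial > 0, retention >= 0, retention <= 1,
            decay >= 0, decay <= 1, suppress >= 0, time >= 0)
  structure(list(initial = initial, retention = retention, decay = decay,
                 suppress = suppress, time = as.integer(time)),
            class = "spread_params")
}

#' One synchronous step of spreading activation
#'
#' Each node keeps a fraction `r` of its activation and diffuses the
#' remaining `1 - r` to its neighbors proportionally to edge weight:
#' `a_i <- r a_i + sum_j (1 - r) a_j w_ij / s_j` where `s_j` is the
#' strength of node j. Nodes with zero strength retain only `r a_i`.
#' Decay multiplies the result by `1 - d`; entries below the suppress
#' threshold are then zeroed. With `d = 0`, `s = 0` and no isolated
#' nodes, the step conserves total activation exactly (the diffusion
#' matrix is column-stochastic).
#'
#' @param net a `semantic_network` or weighted adjacency matrix.
#' @param state nonnegative activation vector, one entry per node.
#' @param params a [spread_params].
#' @return The updated activation vector.
#' @export
spread_step <- function(net, state, params = spread_params()) {
  w <- if (inherits(net, "semantic_network")) net$adjacency else as.matrix(net)
  if (length(state) != nrow(w)) stop("state length does not match node count")
  if (any(state < 0)) stop("negative activation in input state")
  s <- colSums(w)
  r <- params$retention
  share <- ifelse(s > 0, (1 - r) * state / s, 0)
  out <- r * state + as.vector(w %*% share)
  out <- out * (1 - params$decay)
  if (params$suppress > 0) out[out < params$suppress] <- 0
  out
}

#' Simulate spreading activation on a semantic network
#'
#' Two measurement modes are provided. In `"single-seed-sweep"` (the
#' default) one simulation is run per word, seeding only that word with
#' the initial activation and recording every node's activation at every
#' step; this yields a full (seed, node, time) array from which both the
#' seed's own retained activation and the activation received by other
#' words can be read. In `"all-node-init"` a single simulation seeds every
#' node simultaneously.
#'
#' @param net a `semantic_network` (connected; TMFG guarantees this).
#' @param params a [spread_params].
#' @param mode `"single-seed-sweep"` or `"all-node-init"`.
#' @return An object of class `activation_trace`: for the sweep mode an
#'   array `[seed, node, time]` (time indexed `0..t` via dimnames), for
#'   all-node-init a matrix `[node, time]`.
#' @export
simulate_spreading <- function(net, params = spread_params(),
                               mode = c("single-seed-sweep", "all-node-init")) {
  mode <- match.arg(mode)
  w <- if (inherits(net, "semantic_network")) net$adjacency else as.matrix(net)
  n <- nrow(w)
  words <- colnames(w) %||% paste0("w", seq_len(n))
  tt <- params$time
  # precompute the linear step operator: a' = (1-d) * M a, M = rI + (1-r) W D^-1
  s <- colSums(w)
  r <- params$retention
  M <- w %*% diag(ifelse(s > 0, (1 - r) / s, 0), n)
  diag(M) <- diag(M) + r
  M <- (1 - params$decay) * M
  step_fun <- function(a) {
    out <- as.vector(M %*% a)
    if (params$suppress > 0) out[out < params$suppress] <- 0
    out
  }
  tlabs <- as.character(0:tt)
  if (mode == "single-seed-sweep") {
    trace <- array(0, dim = c(n, n, tt + 1),
                   dimnames = list(seed = words, node = words, time = tlabs))
    for (i in seq_len(n)) {
      a <- numeric(n); a[i] <- params$initial
      trace[i, , 1] <- a
      for (k in seq_len(tt)) {
        a <- step_fun(a)
        trace[i, , k + 1] <- a
      }
    }
  } else {
    trace <- matrix(0, n, tt + 1, dimnames = list(node = words, time = tlabs))
    a <- rep(params$initial, n)
    trace[, 1] <- a
    for (k in seq_len(tt)) {
      a <- step_fun(a)
      trace[, k + 1] <- a
    }
  }
  structure(list(mode = mode, activation = trace, params = params,
                 words = words),
            class = "activation_trace")
}

#' @export
print.activation_trace <- function(x, ...) {
  cat("Spreading-activation trace (", x$mode, "), ",
      length(x$words), " words, ", x$params$time, " steps\n", sep = "")
  invisible(x)
}

#' Simulate method for semantic networks
#'
#' Runs the spreading-activation simulation on the network; a thin
#' wrapper around [simulate_spreading()].
#'
#' @param object a `semantic_network`.
#' @param nsim ignored (kept for generic compatibility).
#' @param seed ignored (the simulation is deterministic).
#' @param params a [spread_params].
#' @param mode see [simulate_spreading()].
#' @param ... ignored.
#' @return An `activation_trace`.
#' @export
simulate.semantic_network <- function(object, nsim = 1, seed = NULL,
                                      params = spread_params(),
                                      mode = "single-seed-sweep", ...) {
  simulate_spreading(object, params = params, mode = mode)
}

#' Per-word activation values from a trace
#'
#' Summarizes a trace into a words-by-time matrix. For the sweep mode two
#' readouts are available: `"self"` is each word's activation in its own
#' seeded run (how much activation the seed retains), and `"received"` is
#' the mean activation a word accumulates across the runs seeded at the
#' other words (how much activation reaches it from the rest of the
#' lexicon, the propagation-efficiency readout). For all-node-init traces
#' the readout is the node's activation.
#'
#' @param trace an `activation_trace`.
#' @param measure `"received"` (default) or `"self"`.
#' @return A numeric matrix `[word, time]`, time indexed `0..t`.
#' @export
activation_values <- function(trace, measure = c("received", "self")) {
  measure <- match.arg(measure)
  if (trace$mode == "all-node-init") return(trace$activation)
  a <- trace$activation
  n <- dim(a)[1]
  if (measure == "self") {
    out <- sapply(seq_len(dim(a)[3]), function(k) diag(a[, , k]))
  } else {
    out <- sapply(seq_len(dim(a)[3]), function(k) {
      (colSums(a[, , k]) - diag(a[, , k])) / (n - 1)
    })
  }
  dimnames(out) <- list(trace$words, dimnames(a)$time)
  out
}

#' Compare activation time courses between two equated networks
#'
#' At each time step, a paired t-test across matched words of the two
#' networks' activation values (see [activation_values()] for the
#' readout choices).
#'
#' @param a,b `activation_trace`s over identical word sets, same
#'   parameters and mode.
#' @param measure readout passed to [activation_values()].
#' @return A data frame with one row per time step 1..t: `time`, means of
#'   both groups, `t`, `df`, `p`, `d`.
#' @export
compare_activation <- function(a, b, measure = "received") {
  if (!identical(a$words, b$words)) stop("word sets do not match")
  if (!identical(a$mode, b$mode) || !identical(unclass(a$params), unclass(b$params))) {
    stop("traces differ in mode or parameters")
  }
  va <- activation_values(a, measure)
  vb <- activation_values(b, measure)
  tt <- a$params$time
  rows <- lapply(seq_len(tt), function(k) {
    te <- paired_t_test(va[, k + 1], vb[, k + 1])
    data.frame(time = k, mean_a = mean(va[, k + 1]), mean_b = mean(vb[, k + 1]),
               t = te$statistic, df = te$df, p = te$p, d = te$d)
  })
  do.call(rbind, rows)
}

#' Regress final activation on local network structure
#'
#' Ordinary least squares of each word's final activation on its
#' standardized (z-scored) strength and local clustering coefficient.
#' In healthy-like networks high-degree, low-clustering words end up with
#' the most activation.
#'
#' @param final numeric vector of final activation per word, or an
#'   `activation_trace` (final step, `"received"` readout).
#' @param locals data frame from [local_metrics()] over the same words.
#' @return A list of class `activation_regression` with the fitted model
#'   and a coefficient table (estimate, SE, t, p).
#' @export
regress_activation <- function(final, locals) {
  if (inherits(final, "activation_trace")) {
    av <- activation_values(final)
    final <- av[, ncol(av)]
  }
  if (length(final) != nrow(locals)) stop("length mismatch between activation and local metrics")
  if (stats::sd(locals$strength) == 0 || stats::sd(locals$local_cc) == 0) {
    stop("constant predictor: cannot standardize")
  }
  dat <- data.frame(activation = as.numeric(final),
                    degree = as.numeric(scale(locals$strength)),
                    clustering = as.numeric(scale(locals$local_cc)))
  fit <- stats::lm(activation ~ degree + clustering, data = dat)
  structure(list(fit = fit, coefficients = summary(fit)$coefficients),
            class = "activation_regression")
}

#' @export
print.activation_regression <- function(x, ...) {
  cat("Final activation ~ standardized degree + clustering (OLS)\n")
  stats::printCoefmat(x$coefficients, digits = 3)
  invisible(x)
}

#' Export an activation trace as long-format CSV
#'
#' Columns `seed` (absent for all-node-init), `word`, `time`, `activation`.
#'
#' @param trace an `activation_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (trace$mode == "single-seed-sweep") {
    df <- as.data.frame.table(trace$activation, responseName = "activation")
    names(df) <- c("seed", "word", "time", "activation")
  } else {
    df <- as.data.frame.table(trace$activation, responseName = "activation")
    names(df) <- c("word", "time", "activation")
  }
  df$time <- as.integer(as.character(df$time))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
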