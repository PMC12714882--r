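#' Ground-truth semantic lexicon with community structure
#'
#' Builds the planted weighted network that synthetic participants search:
#' words are grouped into blocks (semantic subcategories, e.g. pets vs.
#' zoo animals), with all within-block pairs connected at a high weight
#' and a sparse set of between-block pairs connected at a lower weight,
#' plus a small uniform jitter. The draw is rejected and re-jittered
#' (with a logged retry count) in the rare case it comes out disconnected.
#'
#' @param n_words number of words (>= 2 per block).
#' @param n_blocks number of subcategory blocks (>= 1).
#' @param w_in,w_out mean within-/between-block edge weight,
#'   `0 < w_out < w_in <= 1`.
#' @param p_between probability that a between-block pair is connected
#'   (within-block pairs are always connected).
#' @param jitter half-width of the uniform weight jitter.
#' @param words optional word labels; defaults to a sample from the
#'   packaged animal lexicon.
#' @param seed integer seed.
#' @return An object of class `ground_truth_lexicon`: `words`, `weights`
#'   (symmetric, zero diagonal, weights in (0, 1]), `blocks` (integer
#'   block assignment), `retries`.
#' @export
ground_truth_lexicon <- function(n_words = 50, n_blocks = 5, w_in = 0.7,
                                 w_out = 0.25, p_between = 0.30,
                                 jitter = 0.1, words = NULL, seed = NULL) {
  stopifnot(n_words >= 2 * n_blocks, w_out > 0, w_out < w_in, w_in <= 1)
  with_seed(seed, {
    if (is.null(words)) {
      pool <- readLines(system.file("extdata", "animal_lexicon.txt",
                                    package = "semfluency"), warn = FALSE)
      if (n_words > length(pool)) stop("n_words exceeds the packaged lexicon")
      words <- sort(sample(pool, n_words))
    }
    blocks <- sort(rep_len(seq_len(n_blocks), n_words))
    n <- n_words
    retries <- 0L
    repeat {
      w <- matrix(0, n, n, dimnames = list(words, words))
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (blocks[i] == blocks[j]) {
            val <- w_in + stats::runif(1, -jitter, jitter)
          } else if (stats::runif(1) < p_between) {
            val <- w_out + stats::runif(1, -jitter, jitter)
          } else next
          val <- min(max(val, 1e-3), 1)
          w[i, j] <- w[j, i] <- val
        }
      }
      g <- igraph::graph_from_adjacency_matrix((w > 0) * 1, mode = "undirected")
      if (igraph::is_connected(g)) break
      retries <- retries + 1L
      if (retries > 100L) stop("could not draw a connected lexicon; raise p_between")
    }
    structure(list(words = words, weights = w, blocks = blocks,
                   retries = retries),
              class = "ground_truth_lexicon")
  })
}

#' @export
print.ground_truth_lexicon <- function(x, ...) {
  cat("Ground-truth lexicon:", length(x$words), "words,",
      length(unique(x$blocks)), "blocks,",
      sum(x$weights[upper.tri(x$weights)] > 0), "edges\n")
  invisible(x)
}

#' Degrade a ground-truth lexicon
#'
#' Removes each edge independently with the given probability, emulating
#' degraded semantic connectivity. If removal disconnects the graph, a
#' minimum spanning set of the removed edges (by descending original
#' weight) is re-added until connectivity is restored; the number of
#' repairs is recorded. With `probability = 1` only the repair skeleton
#' (a spanning tree) survives.
#'
#' @param lex a [ground_truth_lexicon].
#' @param probability per-edge removal probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A degraded `ground_truth_lexicon` (adds `removed_edges` and
#'   `repaired_edges` counts).
#' @export
degrade_network <- function(lex, probability, seed = NULL) {
  stopifnot(probability >= 0, probability <= 1)
  if (probability == 0) return(lex)
  with_seed(seed, {
    w <- lex$weights
    n <- nrow(w)
    ut <- which(upper.tri(w) & w > 0)
    drop <- ut[stats::runif(length(ut)) < probability]
    w[drop] <- 0
    w <- pmin(w, t(w))  # upper-tri removal mirrored to lower
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    repaired <- 0L
    g <- igraph::graph_from_adjacency_matrix((w > 0) * 1, mode = "undirected")
    if (!igraph::is_connected(g)) {
      # re-add removed edges in descending weight until connected
      cand <- drop[order(lex$weights[drop], decreasing = TRUE)]
      for (e in cand) {
        comp <- igraph::components(g)$membership
        ij <- arrayInd(e, dim(w))
        if (comp[ij[1]] != comp[ij[2]]) {
          w[ij[1], ij[2]] <- w[ij[2], ij[1]] <- lex$weights[e]
          g <- igraph::add_edges(g, c(ij[1], ij[2]))
          repaired <- repaired + 1L
          if (igraph::is_connected(g)) break
        }
      }
    }
    out <- lex
    out$weights <- w
    out$removed_edges <- length(drop) - repaired
    out$repaired_edges <- repaired
    out
  })
}

#' Group profile for the synthetic cohort generator
#'
#' Bundles the generative parameters for one participant group: the
#' list-length distribution (how many unique words a participant
#' produces), the random-walk jump (teleport) probability, the fraction
#' of ground-truth edges degraded for the group, the rates of injected
#' noise (perseverations, non-category intrusions, surface variants), and
#' the demographic covariate distributions.
#'
#' @param name group label.
#' @param n cohort size (>= 2).
#' @param list_mean,list_sd mean and SD of the (truncated >= 1) normal
#'   list-length distribution.
#' @param jump per-step teleport probability of the walk.
#' @param degradation per-edge removal probability applied to the
#'   ground-truth lexicon for this group.
#' @param perseveration,intrusion,variant injection rates per produced
#'   word, in `[0, 1]`.
#' @param age_mean,age_sd,edu_mean,edu_sd covariate distributions.
#' @return A list of class `group_profile`.
#' @export
group_profile <- function(name, n, list_mean, list_sd, jump = 0.05,
                          degradation = 0, perseveration = 0.05,
                          intrusion = 0.03, variant = 0.05,
                          age_mean = 60, age_sd = 12,
                          edu_mean = 16, edu_sd = 2.3) {
  stopifnot(n >= 2, list_mean >= 1,
            all(c(jump, degradation, perseveration, intrusion, variant) >= 0),
            all(c(jump, degradation, perseveration, intrusion, variant) <= 1))
  structure(list(name = name, n = n, list_mean = list_mean,
                 list_sd = list_sd, jump = jump, degradation = degradation,
                 perseveration = perseveration, intrusion = intrusion,
                 variant = variant, age_mean = age_mean, age_sd = age_sd,
                 edu_mean = edu_mean, edu_sd = edu_sd),
            class = "group_profile")
}

#' Default group profiles for the synthetic cohorts
#'
#' The four study conditions the generator emulates: healthy controls,
#' the pooled aphasia group, and the fluent/nonfluent subgroups. Cohort
#' sizes, appropriate-response means/SDs and demographic distributions
#' follow the empirical cohorts. The walk-jump (teleport) probability
#' models strategic switching between semantic subcategories and
#' decreases with impairment, while edge degradation increases with it:
#' impaired searchers produce shorter lists that stay trapped inside
#' subcategories of a structurally degraded lexicon, which is what makes
#' their estimated group networks longer-path, less clustered and more
#' modular.
#'
#' @return A named list of [group_profile]s: `control`, `aphasia`,
#'   `fluent`, `nonfluent`.
#' @export
default_profiles <- function() {
  list(
    control = group_profile("control", n = 120, list_mean = 22.47,
                            list_sd = 4.90, jump = 0.20, degradation = 0,
                            perseveration = 0.02, intrusion = 0.02,
                            variant = 0.05, age_mean = 65.57, age_sd = 9.88,
                            edu_mean = 16.49, edu_sd = 2.34),
    aphasia = group_profile("aphasia", n = 127, list_mean = 9.63,
                            list_sd = 5.25, jump = 0.04, degradation = 0.50,
                            perseveration = 0.08, intrusion = 0.06,
                            variant = 0.05, age_mean = 59.50, age_sd = 13.17,
                            edu_mean = 15.70, edu_sd = 2.32),
    fluent = group_profile("fluent", n = 64, list_mean = 11.95,
                           list_sd = 5.08, jump = 0.10, degradation = 0.25,
                           perseveration = 0.06, intrusion = 0.05,
                           variant = 0.05, age_mean = 59.94, age_sd = 12.23,
                           edu_mean = 16.03, edu_sd = 2.33),
    nonfluent = group_profile("nonfluent", n = 63, list_mean = 7.27,
                              list_sd = 4.30, jump = 0.02, degradation = 0.60,
                              perseveration = 0.10, intrusion = 0.08,
                              variant = 0.05, age_mean = 59.06, age_sd = 14.16,
                              edu_mean = 15.34, edu_sd = 2.28))
}

# default pool of non-category tokens used as intrusions
.intrusion_pool <- c("book", "chair", "apple", "table", "car", "tree",
                     "house", "phone", "banana", "cup", "door", "shoe")

# censored weighted random walk over the lexicon: emits each word on its
# first visit, stops after `len` emissions (or a step cap, for safety)
.censored_walk <- function(weights, len, jump) {
  n <- nrow(weights)
  len <- min(len, n)
  visited <- logical(n)
  out <- integer(len)
  cur <- sample.int(n, 1)
  visited[cur] <- TRUE
  out[1] <- cur
  emitted <- 1L
  steps <- 0L
  max_steps <- 200L + 60L * len
  while (emitted < len && steps < max_steps) {
    steps <- steps + 1L
    wrow <- weights[cur, ]
    if (stats::runif(1) < jump || sum(wrow) == 0) {
      cur <- sample.int(n, 1)
    } else {
      cur <- sample.int(n, 1, prob = wrow)
    }
    if (!visited[cur]) {
      visited[cur] <- TRUE
      emitted <- emitted + 1L
      out[emitted] <- cur
    }
  }
  out[seq_len(emitted)]
}

#' Simulate one synthetic fluency participant
#'
#' A censored weighted random walk over the (possibly degraded) lexicon:
#' transitions are weight-proportional with a teleport probability, each
#' word is emitted on first visit only, and the walk stops once the drawn
#' list length is reached. Noise is then injected at the profile's rates:
#' perseverations (a produced word re-inserted later in the list),
#' intrusions (non-category tokens), and surface variants (a produced
#' word replaced by a plural or informal form from the packaged variant
#' map). The injected counts are returned so that cleaning can be
#' validated against ground truth.
#'
#' @param lex a (degraded) [ground_truth_lexicon].
#' @param profile a [group_profile].
#' @param dictionary the [cleaning_dictionary] whose variant map supplies
#'   surface forms.
#' @return A list: `responses` (surface token list), `true_words`
#'   (pre-noise root list), `injected` (counts: perseverations,
#'   intrusions, variants).
#' @export
simulate_participant <- function(lex, profile,
                                 dictionary = default_dictionary()) {
  len <- max(1L, round(stats::rnorm(1, profile$list_mean, profile$list_sd)))
  idx <- .censored_walk(lex$weights, len, profile$jump)
  roots <- lex$words[idx]
  toks <- roots
  # perseverations: re-insert an already-produced root after its position
  n_pers <- stats::rbinom(1, length(roots), profile$perseveration)
  for (p in seq_len(n_pers)) {
    src <- sample.int(length(toks), 1)
    # insertion point strictly after the first occurrence of the root
    first <- match(toks[src], toks)
    pos <- seq(first, length(toks))
    at <- if (length(pos) == 1L) pos else sample(pos, 1)
    toks <- append(toks, toks[first], after = at)
  }
  # intrusions: non-category tokens at random positions
  n_intr <- stats::rbinom(1, length(roots), profile$intrusion)
  for (p in seq_len(n_intr)) {
    toks <- append(toks, sample(.intrusion_pool, 1),
                   after = sample(0:length(toks), 1))
  }
  # surface variants: replace a root occurrence by one of its variants
  variant_lookup <- split(names(dictionary$variants),
                          unname(dictionary$variants))
  n_var <- 0L
  for (j in seq_along(toks)) {
    vs <- variant_lookup[[toks[j]]]
    if (!is.null(vs) && stats::runif(1) < profile$variant) {
      toks[j] <- sample(vs, 1)
      n_var <- n_var + 1L
    }
  }
  list(responses = toks, true_words = roots,
       injected = c(perseverations = n_pers, intrusions = n_intr,
                    variants = n_var))
}

#' Simulate a multi-group fluency cohort
#'
#' Generates a full synthetic dataset in the input dialect of the
#' preprocessing module: one shared ground-truth lexicon, degraded per
#' group according to each profile, then one censored random walk per
#' participant with injected noise. Demographic covariates (age,
#' education) are drawn per profile. The manifest records each
#' participant's true pre-noise list and exact injected-noise counts.
#'
#' @param profiles list of [group_profile]s (>= 1).
#' @param lexicon a [ground_truth_lexicon]; default builds one under the
#'   derived sub-seed.
#' @param seed master seed; all stage seeds are derived from it.
#' @param dictionary [cleaning_dictionary] supplying surface variants.
#' @return A list of class `synthetic_cohort`: `data` (a [fluency_data]
#'   with covariates), `manifest` (per-participant ground truth),
#'   `lexicons` (per-group degraded lexicons), `lexicon` (the shared
#'   ground truth).
#' @export
simulate_cohort <- function(profiles, lexicon = NULL, seed = 1,
                            dictionary = default_dictionary()) {
  stopifnot(length(profiles) >= 1)
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, function(p) p$name, "")
  }
  if (is.null(lexicon)) {
    lexicon <- ground_truth_lexicon(seed = derive_seed(seed, "lexicon"))
  }
  ids <- character(0); grp <- character(0); resp <- list()
  age <- numeric(0); edu <- numeric(0)
  manifest <- list()
  lexicons <- list()
  for (pf in profiles) {
    glex <- degrade_network(lexicon, pf$degradation,
                            seed = derive_seed(seed, paste0("degrade-", pf$name)))
    lexicons[[pf$name]] <- glex
    with_seed(derive_seed(seed, paste0("cohort-", pf$name)), {
      for (i in seq_len(pf$n)) {
        pid <- sprintf("%s_%03d", pf$name, i)
        sim <- simulate_participant(glex, pf, dictionary)
        ids <- c(ids, pid); grp <- c(grp, pf$name)
        resp[[length(resp) + 1L]] <- sim$responses
        age <- c(age, stats::rnorm(1, pf$age_mean, pf$age_sd))
        edu <- c(edu, stats::rnorm(1, pf$edu_mean, pf$edu_sd))
        manifest[[pid]] <- list(group = pf$name,
                                true_words = sim$true_words,
                                injected = as.list(sim$injected))
      }
    })
  }
  dat <- fluency_data(ids, grp, resp,
                      covariates = data.frame(age = age, education = edu))
  structure(list(data = dat, manifest = manifest, lexicons = lexicons,
                 lexicon = lexicon, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic fluency cohort (seed ", x$seed, ")\n", sep = "")
  print(x$data)
  invisible(x)
}

#' Write a synthetic cohort's manifest as JSON
#' @param cohort a `synthetic_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  jsonlite::write_json(cohort$manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
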