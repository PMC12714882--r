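#' Configuration for a two-group comparison run
#'
#' Assembles every knob of the pipeline into one object. Input is either
#' a delimited transcript file (plus the names of the two groups to
#' compare) or a pair of synthetic [group_profile]s. Every stochastic
#' stage derives its own sub-seed from the master seed, so any stage can
#' be reproduced in isolation.
#'
#' @param input path to a transcript file readable by [read_fluency()],
#'   or `NULL` to simulate a cohort from `profiles`.
#' @param profiles list of exactly two [group_profile]s (synthetic mode).
#' @param groups character vector of the two group labels to compare
#'   (defaults to the profile names in synthetic mode).
#' @param seed master seed.
#' @param min_producers producer-count filter threshold.
#' @param er_reps Erdos-Renyi null replicates.
#' @param bootstrap_reps,bootstrap_proportion node-wise bootstrap settings.
#' @param spread a [spread_params].
#' @param percolation_iterations,percolation_k percolation settings.
#' @param covariate_names covariate columns used in the response-count
#'   regression (`NULL` to skip adjustment).
#' @param out_dir optional output directory for serialized artifacts.
#' @param read_args list of extra arguments for [read_fluency()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, profiles = NULL, groups = NULL,
                       seed = 1, min_producers = 2, er_reps = 1000,
                       bootstrap_reps = 1000, bootstrap_proportion = 0.5,
                       spread = spread_params(),
                       percolation_iterations = 500, percolation_k = 3,
                       covariate_names = c("age", "education"),
                       out_dir = NULL, read_args = list()) {
  if (is.null(input) && is.null(profiles)) {
    stop("provide either an input path or two synthetic profiles")
  }
  if (!is.null(profiles)) {
    if (length(profiles) != 2L) stop("exactly two group profiles per run")
    groups <- groups %||% unname(vapply(profiles, function(p) p$name, ""))
  }
  if (is.null(groups) || length(groups) != 2L) {
    stop("exactly two groups per run")
  }
  structure(list(input = input, profiles = profiles, groups = groups,
                 seed = seed, min_producers = min_producers,
                 er_reps = er_reps, bootstrap_reps = bootstrap_reps,
                 bootstrap_proportion = bootstrap_proportion,
                 spread = spread,
                 percolation_iterations = percolation_iterations,
                 percolation_k = percolation_k,
                 covariate_names = covariate_names,
                 out_dir = out_dir, read_args = read_args),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; the `spread` key is a
#' mapping of [spread_params()] arguments and `profiles` a list of
#' [group_profile()] argument mappings.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read configuration files")
  }
  y <- yaml::read_yaml(path)
  if (!is.null(y$spread)) y$spread <- do.call(spread_params, y$spread)
  if (!is.null(y$profiles)) {
    y$profiles <- lapply(y$profiles, function(p) {
      # YAML 1.1 parses a bare `n:` key as a boolean; accept `size` too
      names(p)[names(p) %in% c("FALSE", "size")] <- "n"
      do.call(group_profile, p)
    })
  }
  do.call(run_config, y)
}

#' Run the full two-group semantic-network comparison
#'
#' Executes the pipeline end to end: data acquisition (file or synthetic
#' cohort), cleaning, response-count regression, response matrices with
#' producer filtering and node equating, network estimation (cosine +
#' TMFG), global metrics with Erdos-Renyi z-tests, node-wise bootstrap
#' comparison, local-metric paired tests, spreading-activation comparison
#' and regressions, and the iterated percolation comparison. When
#' `config$out_dir` is set, the report (JSON), metric distributions
#' (CSV) and networks (GraphML) are written there.
#'
#' @param config a [run_config] (or a YAML path accepted by
#'   [read_config()]).
#' @return A list of class `comparison_report`.
#' @export
run_comparison <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  ga <- config$groups[1]; gb <- config$groups[2]

  # --- data ---------------------------------------------------------
  if (!is.null(config$input)) {
    raw <- do.call(read_fluency, c(list(path = config$input), config$read_args))
  } else {
    cohort <- simulate_cohort(config$profiles, seed = derive_seed(seed, "cohort"))
    raw <- cohort$data
  }
  keep <- raw$group %in% config$groups
  raw <- raw[keep]

  # --- preprocessing ------------------------------------------------
  cleaned <- clean_fluency(raw)
  counts <- response_counts(cleaned$data)
  covs <- NULL
  if (!is.null(config$covariate_names) && !is.null(cleaned$data$covariates)) {
    have <- intersect(config$covariate_names, names(cleaned$data$covariates))
    if (length(have)) covs <- cleaned$data$covariates[, have, drop = FALSE]
  }
  count_cmp <- compare_counts(counts, covariates = covs, reference = ga)

  sub <- function(g) {
    d <- cleaned$data[cleaned$data$group == g]
    filter_min_producers(response_matrix(d), config$min_producers)
  }
  eq <- equate_nodes(sub(ga), sub(gb))

  # --- estimation ---------------------------------------------------
  net_a <- semantic_network(eq$a)
  net_b <- semantic_network(eq$b)

  # --- global metrics + random baselines ----------------------------
  gm_a <- global_metrics(net_a, seed = derive_seed(seed, "louvain-a"))
  gm_b <- global_metrics(net_b, seed = derive_seed(seed, "louvain-b"))
  n <- length(net_a$words)
  er <- er_baseline(n, 3 * n - 6, reps = config$er_reps,
                    seed = derive_seed(seed, "er"))
  ztests <- list(
    a = list(aspl = z_test(gm_a$aspl, er$aspl), cc = z_test(gm_a$cc, er$cc),
             q = z_test(gm_a$q, er$q)),
    b = list(aspl = z_test(gm_b$aspl, er$aspl), cc = z_test(gm_b$cc, er$cc),
             q = z_test(gm_b$q, er$q)))

  # --- bootstrap ----------------------------------------------------
  boot <- bootstrap_networks(eq$a, eq$b, reps = config$bootstrap_reps,
                             proportion = config$bootstrap_proportion,
                             seed = derive_seed(seed, "bootstrap"))

  # --- local metrics ------------------------------------------------
  loc_a <- local_metrics(net_a)
  loc_b <- local_metrics(net_b)
  local_tests <- compare_local_metrics(loc_a, loc_b)

  # --- spreading activation -----------------------------------------
  tr_a <- simulate_spreading(net_a, config$spread)
  tr_b <- simulate_spreading(net_b, config$spread)
  act_cmp <- compare_activation(tr_a, tr_b)
  reg_a <- regress_activation(tr_a, loc_a)
  reg_b <- regress_activation(tr_b, loc_b)

  # --- percolation --------------------------------------------------
  perc <- percolation_comparison(eq$a, eq$b,
                                 iterations = config$percolation_iterations,
                                 k = config$percolation_k,
                                 seed = derive_seed(seed, "percolation"))

  report <- structure(list(
    config = config,
    groups = config$groups,
    cleaning_log = cleaned$log,
    counts = counts,
    count_comparison = count_cmp,
    equating = eq$exclusions,
    networks = list(a = net_a, b = net_b),
    global = list(a = gm_a[c("aspl", "cc", "q")], b = gm_b[c("aspl", "cc", "q")]),
    z_tests = ztests,
    bootstrap = boot,
    local = list(a = loc_a, b = loc_b, tests = local_tests),
    activation = list(comparison = act_cmp,
                      regression = list(a = reg_a, b = reg_b)),
    percolation = perc,
    version = as.character(utils::packageVersion("semfluency"))
  ), class = "comparison_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("=== Semantic-network comparison:", x$groups[1], "vs", x$groups[2], "===\n")
  print(x$count_comparison)
  cat("Shared nodes after equating:", x$equating$shared_nodes,
      sprintf("(excluded: %d from %s, %d from %s)\n", x$equating$n_a,
              x$groups[1], x$equating$n_b, x$groups[2]))
  cat(sprintf("Full-network metrics  %s: ASPL %.3f CC %.3f Q %.3f | %s: ASPL %.3f CC %.3f Q %.3f\n",
              x$groups[1], x$global$a$aspl, x$global$a$cc, x$global$a$q,
              x$groups[2], x$global$b$aspl, x$global$b$cc, x$global$b$q))
  print(x$bootstrap)
  cat("Local paired tests: ")
  cat(sprintf("strength t(%d) = %.2f (p = %.3g); local CC t(%d) = %.2f (p = %.3g)\n",
              x$local$tests$strength$df, x$local$tests$strength$statistic,
              x$local$tests$strength$p, x$local$tests$local_cc$df,
              x$local$tests$local_cc$statistic, x$local$tests$local_cc$p))
  late <- x$activation$comparison[x$activation$comparison$time >= 4, ]
  cat(sprintf("Activation (received), late steps: mean t = %.2f, all p < %.3g\n",
              mean(late$t), max(late$p)))
  print(x$percolation)
  invisible(x)
}

# serialize a stat_result into plain lists for JSON
.stat_to_list <- function(s) {
  s <- unclass(s)
  s[!vapply(s, is.function, TRUE)]
}

#' Write a comparison report to disk
#'
#' Produces `report.json` (the numeric results), distribution CSVs for
#' the bootstrap and percolation samples, and GraphML files for both
#' networks.
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    groups = report$groups,
    seed = report$config$seed,
    version = report$version,
    count_comparison = .stat_to_list(report$count_comparison)[
      c("term", "estimate", "se", "t", "df", "p", "n_dropped_listwise")],
    group_mean_counts = as.list(report$count_comparison$group_means),
    equating = report$equating[c("shared_nodes", "n_a", "n_b")],
    global = report$global,
    z_tests = lapply(report$z_tests, function(g) lapply(g, .stat_to_list)),
    bootstrap_tests = lapply(report$bootstrap$tests, .stat_to_list),
    local_tests = lapply(report$local$tests, .stat_to_list),
    activation_comparison = report$activation$comparison,
    activation_regression = list(
      a = as.data.frame(report$activation$regression$a$coefficients),
      b = as.data.frame(report$activation$regression$b$coefficients)),
    percolation = c(.stat_to_list(report$percolation$test),
                    list(iterations = report$percolation$iterations))
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  for (mt in names(report$bootstrap$distributions)) {
    d <- report$bootstrap$distributions[[mt]]
    write_distributions(stats::setNames(list(d$a, d$b), report$groups),
                        file.path(dir, paste0("bootstrap_", mt, ".csv")))
  }
  write_distributions(stats::setNames(report$percolation$integrals[c("a", "b")],
                                      report$groups),
                      file.path(dir, "percolation_integrals.csv"))
  write_network(report$networks$a, file.path(dir, paste0("network_", report$groups[1], ".graphml")))
  write_network(report$networks$b, file.path(dir, paste0("network_", report$groups[2], ".graphml")))
  write_cleaning_log(report$cleaning_log, file.path(dir, "cleaning_log.json"))
  invisible(dir)
}
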