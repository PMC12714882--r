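#' Cleaning dictionary for fluency responses
#'
#' A cleaning dictionary pairs a category lexicon (the set of accepted root
#' words, e.g. animal names) with a variant map that sends surface forms
#' (plurals, diminutives, common misspellings) to their roots. Tokens that
#' are neither roots nor mapped variants are treated as non-category
#' intrusions and removed during cleaning.
#'
#' @param lexicon character vector of accepted root words.
#' @param variants either `NULL`, or a data frame with columns `variant`
#'   and `root`; every `root` must be in `lexicon`.
#' @return An object of class `cleaning_dictionary` with elements
#'   `lexicon` (sorted character vector) and `variants` (named character
#'   vector: names are surface forms, values are roots).
#' @seealso [default_dictionary()] for the packaged animal dictionary.
#' @export
cleaning_dictionary <- function(lexicon, variants = NULL) {
  lexicon <- sort(unique(trimws(tolower(lexicon))))
  lexicon <- lexicon[nzchar(lexicon)]
  if (length(lexicon) == 0L) stop("lexicon is empty")
  vmap <- character(0)
  if (!is.null(variants)) {
    if (!all(c("variant", "root") %in% names(variants))) {
      stop("variants must have columns 'variant' and 'root'")
    }
    v <- trimws(tolower(as.character(variants$variant)))
    r <- trimws(tolower(as.character(variants$root)))
    if (anyDuplicated(v)) stop("variant map is not deterministic: duplicated surface forms")
    bad <- setdiff(r, lexicon)
    if (length(bad)) {
      stop("variant roots not in lexicon: ", paste(utils::head(bad, 5), collapse = ", "))
    }
    vmap <- stats::setNames(r, v)
  }
  structure(list(lexicon = lexicon, variants = vmap),
            class = "cleaning_dictionary")
}

#' Packaged animal-category cleaning dictionary
#'
#' Loads the animal lexicon and variant map shipped with the package. This
#' is a general-purpose English animal dictionary; it is user-replaceable
#' via [cleaning_dictionary()] when a study uses its own scoring lexicon.
#'
#' @return A `cleaning_dictionary`.
#' @export
default_dictionary <- function() {
  lex <- readLines(system.file("extdata", "animal_lexicon.txt",
                               package = "semfluency"), warn = FALSE)
  var <- utils::read.csv(system.file("extdata", "animal_variants.csv",
                                     package = "semfluency"),
                         stringsAsFactors = FALSE)
  cleaning_dictionary(lex, var)
}

#' @export
print.cleaning_dictionary <- function(x, ...) {
  cat("Cleaning dictionary:", length(x$lexicon), "roots,",
      length(x$variants), "mapped variants\n")
  invisible(x)
}

#' Construct a fluency dataset
#'
#' The container for raw or cleaned verbal-fluency transcripts: one record
#' per participant holding the ordered list of produced tokens and a group
#' label. Optional per-participant covariates (e.g. age, education) ride
#' along for the response-count regression.
#'
#' @param participant character vector of unique participant identifiers.
#' @param group character vector of group labels, same length.
#' @param responses list of character vectors (ordered tokens; may be empty).
#' @param covariates optional data frame with one row per participant.
#' @return An object of class `fluency_data`.
#' @export
fluency_data <- function(participant, group, responses, covariates = NULL) {
  participant <- as.character(participant)
  group <- as.character(group)
  stopifnot(length(participant) == length(group),
            length(participant) == length(responses))
  if (anyDuplicated(participant)) stop("duplicate participant identifiers")
  responses <- lapply(responses, function(r) {
    r <- trimws(tolower(as.character(r)))
    r[nzchar(r)]
  })
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(participant))
  }
  structure(list(participant = participant, group = group,
                 responses = responses, covariates = covariates),
            class = "fluency_data")
}

#' @export
print.fluency_data <- function(x, ...) {
  cat("Fluency data:", length(x$participant), "participants,",
      length(unique(x$group)), "group(s)\n")
  tab <- table(x$group)
  for (g in names(tab)) {
    idx <- x$group == g
    cat(sprintf("  %s: n = %d, mean responses = %.2f\n", g, sum(idx),
                mean(lengths(x$responses[idx]))))
  }
  invisible(x)
}

#' @export
length.fluency_data <- function(x) length(x$participant)

#' Subset a fluency dataset by participant
#' @param x a `fluency_data`.
#' @param i index vector over participants.
#' @param ... ignored.
#' @export
`[.fluency_data` <- function(x, i, ...) {
  fluency_data(x$participant[i], x$group[i], x$responses[i],
               if (!is.null(x$covariates)) x$covariates[i, , drop = FALSE])
}

#' Read verbal-fluency transcripts from a delimited file
#'
#' Supports two layouts: wide (one row per participant, responses in one
#' delimited field) and long (one row per token, ordered within
#' participant). Tokens are case-folded and whitespace-trimmed on input.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param sep field separator (default `","`).
#' @param participant,group names of the identifier and group columns.
#' @param responses name of the response-list column (wide format).
#' @param response_sep regular expression splitting tokens within the
#'   response field; the default splits on semicolons or whitespace.
#' @param long if `TRUE`, expect one token per row in column `token`.
#' @param token token column name for long format.
#' @param covariates optional character vector of additional numeric
#'   columns to carry as covariates.
#' @return A [fluency_data] object; token order follows file order.
#' @export
read_fluency <- function(path, sep = ",", participant = "participant",
                         group = "group", responses = "responses",
                         response_sep = "[;[:space:]]+", long = FALSE,
                         token = "token", covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c(participant, group, if (long) token else responses, covariates)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty dataset: ", path, " has a header but no rows")
  if (long) {
    ids <- unique(df[[participant]])
    resp <- lapply(ids, function(p) as.character(df[[token]][df[[participant]] == p]))
    grp <- df[[group]][match(ids, df[[participant]])]
    cov <- if (!is.null(covariates)) {
      df[match(ids, df[[participant]]), covariates, drop = FALSE]
    }
    fluency_data(ids, grp, resp, cov)
  } else {
    resp <- strsplit(trimws(as.character(df[[responses]])), response_sep)
    cov <- if (!is.null(covariates)) df[, covariates, drop = FALSE]
    fluency_data(df[[participant]], df[[group]], resp, cov)
  }
}

#' Write a fluency dataset to CSV (wide format)
#'
#' Responses are joined with semicolons so that [read_fluency()] round-trips
#' the dataset exactly.
#'
#' @param x a `fluency_data`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fluency <- function(x, path) {
  df <- data.frame(participant = x$participant, group = x$group,
                   responses = vapply(x$responses, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  if (!is.null(x$covariates)) df <- cbind(df, x$covariates)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Clean fluency responses against a dictionary
#'
#' Applies the standard fluency scoring rules in a fixed order: surface
#' forms are first standardized to lexicon roots via the variant map; any
#' token that is neither a root nor a mapped variant is removed as a
#' non-category intrusion; any later occurrence of an already-produced root
#' is removed as a perseveration (adjacency is not required). Cleaning is
#' idempotent.
#'
#' @param x a [fluency_data].
#' @param dictionary a [cleaning_dictionary].
#' @return A list of class `cleaned_fluency` with elements `data` (the
#'   cleaned `fluency_data`) and `log` (a `cleaning_log`: per-participant
#'   counts of standardized variants, removed intrusions and removed
#'   perseverations, plus the removed tokens with reasons).
#' @export
clean_fluency <- function(x, dictionary = default_dictionary()) {
  stopifnot(inherits(x, "fluency_data"), inherits(dictionary, "cleaning_dictionary"))
  n <- length(x$participant)
  cleaned <- vector("list", n)
  log_rows <- data.frame(participant = x$participant,
                         raw = lengths(x$responses),
                         retained = 0L, variants = 0L,
                         intrusions = 0L, perseverations = 0L,
                         stringsAsFactors = FALSE)
  removed <- list()
  for (i in seq_len(n)) {
    toks <- x$responses[[i]]
    mapped <- toks
    is_variant <- toks %in% names(dictionary$variants)
    mapped[is_variant] <- unname(dictionary$variants[toks[is_variant]])
    in_lex <- mapped %in% dictionary$lexicon
    keep <- logical(length(toks))
    seen <- character(0)
    reason <- character(length(toks))
    for (j in seq_along(toks)) {
      if (!in_lex[j]) {
        reason[j] <- "non-category"
      } else if (mapped[j] %in% seen) {
        reason[j] <- "perseveration"
      } else {
        keep[j] <- TRUE
        seen <- c(seen, mapped[j])
      }
    }
    cleaned[[i]] <- mapped[keep]
    log_rows$retained[i] <- sum(keep)
    log_rows$variants[i] <- sum(is_variant)   # standardized before any removal
    log_rows$intrusions[i] <- sum(reason == "non-category")
    log_rows$perseverations[i] <- sum(reason == "perseveration")
    if (any(!keep)) {
      removed[[x$participant[i]]] <- data.frame(
        token = toks[!keep], reason = reason[!keep], stringsAsFactors = FALSE)
    }
  }
  out <- fluency_data(x$participant, x$group, cleaned, x$covariates)
  log <- structure(list(counts = log_rows, removed = removed),
                   class = "cleaning_log")
  structure(list(data = out, log = log), class = "cleaned_fluency")
}

#' @export
print.cleaning_log <- function(x, ...) {
  cat("Cleaning log:", nrow(x$counts), "participants\n")
  cat(sprintf("  tokens: %d raw -> %d retained (%d variants standardized, %d intrusions, %d perseverations removed)\n",
              sum(x$counts$raw), sum(x$counts$retained),
              sum(x$counts$variants), sum(x$counts$intrusions),
              sum(x$counts$perseverations)))
  invisible(x)
}

#' @export
print.cleaned_fluency <- function(x, ...) {
  print(x$log)
  print(x$data)
  invisible(x)
}

#' Export a cleaning log as JSON
#' @param log a `cleaning_log`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_log <- function(log, path) {
  jsonlite::write_json(list(counts = log$counts, removed = log$removed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Binary participant-by-word response matrix
#'
#' Converts a cleaned fluency dataset into the estimation substrate: a
#' binary matrix with one row per participant and one column per unique
#' root word, 1 indicating that the participant produced the word at least
#' once. Columns are sorted lexicographically for determinism.
#'
#' @param x a cleaned [fluency_data] (single group recommended).
#' @return A binary matrix of class `response_matrix` with participant row
#'   names, word column names, and a `group` attribute when the dataset
#'   holds a single group.
#' @export
response_matrix <- function(x) {
  stopifnot(inherits(x, "fluency_data"))
  if (anyDuplicated(x$participant)) stop("duplicate participant identifiers")
  words <- sort(unique(unlist(x$responses)))
  if (length(words) == 0L) stop("empty matrix: no responses in dataset")
  m <- matrix(0L, nrow = length(x$participant), ncol = length(words),
              dimnames = list(x$participant, words))
  for (i in seq_along(x$responses)) {
    m[i, unique(x$responses[[i]])] <- 1L
  }
  structure(m, class = c("response_matrix", class(m)),
            group = if (length(unique(x$group)) == 1L) x$group[1] else NULL)
}

#' Keep only words produced by a minimum number of participants
#'
#' Words produced by fewer than `min_producers` participants are dropped;
#' the conventional minimum of two removes single-producer idiosyncrasies
#' before group networks are estimated.
#'
#' @param m a [response_matrix].
#' @param min_producers minimum column sum to retain (default 2).
#' @return The filtered `response_matrix` (row order unchanged).
#' @export
filter_min_producers <- function(m, min_producers = 2) {
  stopifnot(min_producers >= 1)
  keep <- colSums(m) >= min_producers
  if (!any(keep)) stop("empty matrix: no word reaches ", min_producers, " producers")
  out <- m[, keep, drop = FALSE]
  structure(out, class = class(m), group = attr(m, "group"))
}

#' Equate the node sets of two response matrices
#'
#' Restricts both matrices to their shared vocabulary so that the two group
#' networks are built over identical nodes; words unique to either group
#' (idiosyncratic responses) are excluded and reported. Apply producer
#' filtering first; columns are not re-filtered after intersection.
#'
#' @param a,b producer-filtered [response_matrix] objects.
#' @return A list with elements `a` and `b` (matrices over the shared,
#'   lexicographically ordered word set) and `exclusions`, a list with the
#'   per-matrix excluded words and counts.
#' @export
equate_nodes <- function(a, b) {
  shared <- sort(intersect(colnames(a), colnames(b)))
  if (length(shared) == 0L) stop("empty shared lexicon between groups")
  excl_a <- sort(setdiff(colnames(a), shared))
  excl_b <- sort(setdiff(colnames(b), shared))
  list(a = structure(a[, shared, drop = FALSE], class = class(a), group = attr(a, "group")),
       b = structure(b[, shared, drop = FALSE], class = class(b), group = attr(b, "group")),
       exclusions = list(shared_nodes = length(shared),
                         a = excl_a, b = excl_b,
                         n_a = length(excl_a), n_b = length(excl_b)))
}

#' Per-participant appropriate-response counts
#'
#' @param x a cleaned [fluency_data].
#' @return A data frame with `participant`, `group` and `count` (number of
#'   retained tokens).
#' @export
response_counts <- function(x) {
  stopifnot(inherits(x, "fluency_data"))
  data.frame(participant = x$participant, group = x$group,
             count = lengths(x$responses), stringsAsFactors = FALSE)
}

#' Covariate-adjusted group comparison of response counts
#'
#' Ordinary least squares of the appropriate-response count on a group
#' indicator plus covariates; reports the group coefficient with its t
#' statistic and p value. Rows with missing covariates are dropped
#' listwise (the number dropped is reported); zero-variance covariates are
#' dropped with a note, so that with constant covariates the group
#' coefficient reduces to the difference of group means.
#'
#' @param counts data frame from [response_counts()], or a numeric vector.
#' @param group group labels (ignored when `counts` is a data frame).
#' @param covariates optional data frame of numeric covariates.
#' @param reference group label to treat as baseline; default is the first
#'   level in sort order.
#' @return A list of class `count_comparison` with the fitted model, the
#'   group coefficient report, group means, and the listwise-deletion count.
#' @export
compare_counts <- function(counts, group = NULL, covariates = NULL,
                           reference = NULL) {
  if (is.data.frame(counts)) {
    group <- counts$group
    y <- counts$count
  } else {
    y <- as.numeric(counts)
  }
  if (length(unique(group)) < 2L) stop("need at least two groups")
  lev <- sort(unique(group))
  if (!is.null(reference)) lev <- c(reference, setdiff(lev, reference))
  g <- factor(group, levels = lev)
  dat <- data.frame(y = y, group = g)
  dropped_constant <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(v) stats::var(v, na.rm = TRUE) > 0, TRUE)
    dropped_constant <- names(covariates)[!keep]
    covariates <- covariates[, keep, drop = FALSE]
    if (ncol(covariates)) dat <- cbind(dat, covariates)
  }
  complete <- stats::complete.cases(dat)
  n_dropped <- sum(!complete)
  dat <- dat[complete, , drop = FALSE]
  fit <- stats::lm(y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) stop("singular design: collinear predictors")
  sm <- summary(fit)$coefficients
  grow <- grep("^group", rownames(sm))[1]
  structure(list(
    fit = fit,
    term = rownames(sm)[grow],
    estimate = sm[grow, "Estimate"],
    se = sm[grow, "Std. Error"],
    t = sm[grow, "t value"],
    df = fit$df.residual,
    p = sm[grow, "Pr(>|t|)"],
    group_means = tapply(dat$y, dat$group, mean),
    n_dropped_listwise = n_dropped,
    dropped_constant_covariates = dropped_constant
  ), class = "count_comparison")
}

#' @export
print.count_comparison <- function(x, ...) {
  cat("Appropriate-response count comparison (OLS)\n")
  cat("  group means:", paste(sprintf("%s = %.2f", names(x$group_means),
                                      x$group_means), collapse = ", "), "\n")
  cat(sprintf("  %s: beta = %.2f, t(%d) = %.2f, p = %.3g\n",
              x$term, x$estimate, x$df, x$t, x$p))
  if (x$n_dropped_listwise > 0)
    cat("  rows dropped (missing covariates):", x$n_dropped_listwise, "\n")
  invisible(x)
}
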