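#' Derive a stage-specific random seed from a master seed
#'
#' Stochastic stages of the pipeline (null models, bootstrap, percolation
#' iterations, cohort simulation) each draw their own seed from the master
#' seed and a fixed label, so that any stage can be re-run in isolation and
#' reproduce its part of a full pipeline run.
#'
#' @param seed integer master seed.
#' @param label character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(as.double(utf8ToInt(label)) * seq_along(utf8ToInt(label)))
  # simple multiplicative mix kept inside 31 bits
  as.integer((abs(seed) * 69069 + h * 2654435.0) %% 2147483647)
}

# set.seed only when a seed is supplied
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
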