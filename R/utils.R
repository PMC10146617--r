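#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are reproducible without
#' disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed from a global seed
#'
#' A single study seed fans out to per-subject (or per-replicate) substreams
#' so that changing the cohort size does not reshuffle existing subjects.
#' Kept below 2^31 so the result is a valid R integer seed.
#'
#' @param seed global integer seed.
#' @param index positive integer substream index.
#' @return integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a positive integer, got %s", name,
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(as.integer(x))
}
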