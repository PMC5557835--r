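# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded package functions never disturb the global random stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a child seed from a master seed
#'
#' Deterministic per-stage seeds so one pipeline seed fans out to independent
#' stage streams. Kept strictly below 2^31 - 1.
#' @noRd
child_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that both classes are spread
#' as evenly as possible across folds. Uses the current RNG state.
#' @noRd
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    if (length(idx) < k) {
      stopf("class '%s' has %d members, fewer than %d folds", lev,
            length(idx), k)
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}
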