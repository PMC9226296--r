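#' @keywords internal
"_PACKAGE"

# Deterministic seed derivation: every stage draws its RNG stream from the
# single run seed plus a stage tag, so stages are individually reproducible
# and independent of execution order.

#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the package flows from one integer seed. Each pipeline
#' stage (and each subject or repeat within a stage) derives its own seed via
#' a fixed integer hash of the master seed, a stage tag, and an index. The
#' derivation keeps results below 2^31 so they are valid R integer seeds.
#'
#' @param seed master integer seed.
#' @param stage character tag naming the stage (e.g. "cohort", "cv").
#' @param index optional nonnegative integer distinguishing draws within a
#'   stage (subject number, repeat number, ...).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps the result a valid seed
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271) %% m
  s <- (s + h * 7919 + as.numeric(index) * 104729) %% m
  as.integer(s)
}

# Run a thunk under a local RNG state so generators do not disturb the
# caller's stream.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_dim <- function(...) stop(sprintf(...), call. = FALSE)
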