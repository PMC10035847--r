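#' Derive a reproducible child seed
#'
#' Deterministically maps a parent seed plus a purpose string to a new seed,
#' so that nested stochastic steps (e.g. re-clustering a reduced taxon set,
#' per-replicate MCMC chains) are reproducible without sharing one RNG
#' stream. The hash is a polynomial rolling hash of the purpose string,
#' seeded by the parent seed, modulo the Mersenne prime 2^31 - 1.
#'
#' @param seed Integer parent seed.
#' @param purpose Character scalar naming the derived stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "replicate-1")
derive_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(purpose),
            length(purpose) == 1L)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(purpose)) h <- (h * 131 + b) %% m
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `fn()` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
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
  fn()
}

abort_gc <- function(msg, class) {
  rlang::abort(msg, class = c(class, "gcphylo_error"))
}

check_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    abort_gc(sprintf("`%s` must be a probability in %s0, 1%s, got %s",
                     name, if (open_left) "(" else "[",
                     if (open_right) ")" else "]",
                     format(x)), "invalid_spec")
  }
  invisible(x)
}
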