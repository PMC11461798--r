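#' Derive a reproducible sub-seed from a master seed and identifiers
#'
#' All stochastic operations in the package draw their randomness from
#' per-unit sub-streams so that results do not depend on the order in which
#' samples or sample pairs are evaluated. The sub-seed is a deterministic
#' hash of the master seed and one or more string identifiers (sample ids,
#' stream names such as `"tree"` or `"communities"`).
#'
#' @param seed integer master seed.
#' @param ... character identifiers mixed into the hash (coerced with
#'   `as.character`).
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
sub_seed <- function(seed, ...) {
  ids <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(ids)) {
    # 31-bit multiplicative string hash; doubles are exact below 2^53
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Fast row minima of a square distance block with the diagonal masked out.
row_min_offdiag <- function(m) {
  diag(m) <- Inf
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
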