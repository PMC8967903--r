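# Internal helpers: seeded evaluation and deterministic seed fan-out.

# Evaluate `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards. `seed = NULL` evaluates in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a deterministic child seed from a parent seed and a stage tag
#'
#' A single user-facing seed is fanned out to per-stage seeds by hashing the
#' stage tag into the parent seed (iterated polynomial hash modulo 2^31 - 1).
#' The same (seed, tag) pair always yields the same child, and distinct tags
#' give effectively independent streams.
#'
#' @param seed integer parent seed.
#' @param tag character stage label, e.g. `"session3"` or `"decode"`.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag), length(tag) == 1L)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% m
  as.integer(h %% (m - 2)) + 1L
}

# Population variance (divides by n, not n - 1).
pop_var <- function(x) mean((x - mean(x))^2)

# Centered rolling mean with edge truncation.
roll_mean_trunc <- function(x, width) {
  n <- length(x)
  h <- floor(width / 2)
  cs <- cumsum(x)
  hi <- pmin(n, seq_len(n) + h)
  lo <- pmax(1L, seq_len(n) - h)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}
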