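#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from a single master seed through
#' named substreams, so that any stage (schedule, noise, artifacts, word
#' signatures, fold assignment, model initialisation) can be re-run in
#' isolation and still produce the same draws.  The substream seed is a
#' deterministic hash of the master seed, a stream name and an index,
#' reduced modulo 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param stream character name of the substream, e.g. `"noise"`.
#' @param index optional non-negative integer (e.g. subject or trial index)
#'   distinguishing repeated draws within a stream.
#' @return A single integer seed.
#' @export
sub_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + as.numeric(index) %% m) %% m
  # avoid the degenerate seed 0
  as.integer(h) + 1L
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not
#' perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# closed-interval sample index range for a time window [a, b] (seconds
# relative to stimulus onset); both endpoint samples are included, which is
# the convention that makes 0..0.5 s at 256 Hz span 129 samples.
window_indices <- function(t, window) {
  eps <- 1e-9
  which(t >= window[1] - eps & t <= window[2] + eps)
}
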