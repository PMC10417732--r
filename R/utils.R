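#' Derive a child seed for a named generator stream
#'
#' A single user-facing seed fans out to independent per-generator streams,
#' so adding one generator never perturbs the draws of another. The child is
#' a deterministic hash of the parent seed and the stream name, kept below
#' 2^31 so it is always a valid [set.seed()] argument.
#'
#' @param seed parent integer seed.
#' @param stream character stream name, e.g. `"frame"` or `"reads"`.
#' @return integer child seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; doubles stay exact below 2^53
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# lognormal parameterized by its arithmetic mean and CV of the underlying
# normal on the log scale (sdlog); keeps generator configs readable.
rlnorm_mean <- function(n, mean, sdlog) {
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
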