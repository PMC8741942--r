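# Internal helpers shared across modules.

#' @keywords internal
#' @useDynLib rppgaf, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Deterministic 31-bit seed derived from a master seed and an index.
# Knuth-style multiplicative mix; stays within .Machine$integer.max so it is
# a valid argument to set.seed() on every platform.
derive_seed <- function(master_seed, index) {
  m <- 2147483647
  a <- (as.numeric(master_seed) %% m) * 2654435761
  b <- (as.numeric(index) %% m) * 40503
  as.integer((a + b + 12345) %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
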