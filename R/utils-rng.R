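# Seed handling: one root seed per run; every pipeline stage derives its own
# stream from (root seed, stage name) so stages can be re-run in isolation.

#' Derive a stage-specific seed from a root seed
#'
#' Hashes `(seed, stage)` into a deterministic integer below 2^31 via FNV-1a,
#' so each pipeline stage gets an independent, reproducible RNG stream.
#'
#' @param seed Integer root seed.
#' @param stage Character scalar naming the stage (e.g. `"channel"`).
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(1, "channel")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # FNV-1a over the decimal seed digits and the stage name, in double
  # arithmetic (all intermediates stay below 2^53)
  bytes <- utf8ToInt(paste0(format(seed, scientific = FALSE), "/", stage))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483648)
}

# xor of two non-negative doubles < 2^32, chunked through 16-bit halves so
# bitwXor's 32-bit signed range is never exceeded
bitwXor64 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# A tiny self-contained 32-bit LCG (Numerical Recipes constants), used where
# a stream must be reproducible independently of R's RNG machinery (fountain
# droplet expansion from a stored 16-bit seed).  State and outputs are
# doubles; all products stay below 2^53.
lcg_new <- function(seed) {
  state <- seed %% 4294967296
  list(
    next_u32 = function() {
      state <<- (1664525 * state + 1013904223) %% 4294967296
      state
    },
    # uniform in [0, 1)
    next_unif = function() {
      state <<- (1664525 * state + 1013904223) %% 4294967296
      state / 4294967296
    },
    # uniform integer in 1..n
    next_int = function(n) {
      state <<- (1664525 * state + 1013904223) %% 4294967296
      1L + as.integer(floor(state / 4294967296 * n))
    }
  )
}
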