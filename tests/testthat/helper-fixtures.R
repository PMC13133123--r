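# Shared fixtures: everything is generated in code, nothing is stored.

random_pool <- function(n = 20L, L = 60L, seed = 1L) {
  seqs <- oligobench:::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))
  reference_pool(seqs)
}

# independent Levenshtein oracle: plain dynamic programming in R
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  prev <- 0:length(y)
  for (i in seq_along(x)) {
    cur <- c(i, integer(length(y)))
    for (j in seq_along(y)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[length(y) + 1]
}

# brute-force carry-less GF(2^8) multiply mod 0x11D, vectorized
bf_gf_mul <- function(a, b) {
  r <- integer(length(a))
  for (i in 0:7) {
    bit <- bitwAnd(b, bitwShiftL(1L, i)) != 0L
    r[bit] <- bitwXor(r[bit], bitwShiftL(a[bit], i))
  }
  for (i in 15:8) {
    bit <- bitwAnd(r, bitwShiftL(1L, i)) != 0L
    r[bit] <- bitwXor(r[bit], bitwShiftL(285L, i - 8L))
  }
  r
}
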