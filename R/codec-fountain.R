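#' The LT fountain reference codec
#'
#' Rateless "droplet" coding: the payload is split into `K` equal
#' segments; each sequence is a droplet — a 2-byte droplet seed, the XOR
#' of a degree-`d` subset of segments (degree drawn from the robust
#' soliton distribution), and a small inner RS parity used purely for
#' DETECTION: any droplet whose parity does not verify is discarded, it
#' is never corrected.  Dropout tolerance comes from the droplet
#' overhead `epsilon` (`ceiling(K * (1 + epsilon))` droplets are
#' generated).
#'
#' Decoding uses belief-propagation peeling with a Gaussian-elimination
#' fallback on the residual system (inactivation decoding), and succeeds
#' only if all `K` segments are resolved and the byte-for-byte payload
#' comparison passes.
#'
#' @param L Design sequence length in nt.
#' @param epsilon Droplet overhead (fractional), `>= 0`.
#' @param K Number of payload segments; `NULL` (default) derives it from
#'   the payload size at encode time so each droplet carries one segment.
#' @param parity_bytes Inner RS detection parity per droplet (default 2).
#' @param c,delta Robust soliton parameters (defaults 0.03 and 0.05).
#' @return A codec object for [codec_encode()] / [codec_decode()].
#' @export
#' @examples
#' cdc <- fountain_codec(L = 40, epsilon = 0.5)
#' enc <- codec_encode(cdc, generate_payload(30, seed = 1))
#' codec_decode(cdc, enc$pool, enc$meta)$status
fountain_codec <- function(L = 150L, epsilon = 0.10, K = NULL,
                           parity_bytes = 2L, c = 0.03, delta = 0.05) {
  if (epsilon < 0) stop("droplet overhead `epsilon` must be >= 0")
  n <- L %/% 4L
  seed_bytes <- 2L
  seg_bytes <- n - seed_bytes - parity_bytes
  stopifnot(seg_bytes >= 1L, parity_bytes >= 1L, c > 0, delta > 0, delta < 1)
  params <- list(L = as.integer(L), n = as.integer(n),
                 seed_bytes = seed_bytes, parity_bytes = as.integer(parity_bytes),
                 seg_bytes = as.integer(seg_bytes), epsilon = epsilon,
                 K = K, c = c, delta = delta)
  new_codec("fountain", params, fountain_encode_, fountain_decode_)
}

# robust soliton degree distribution over 1..K
robust_soliton <- function(K, c, delta) {
  rho <- c(1 / K, 1 / ((2:K) * (1:(K - 1))))
  Rrs <- c * log(K / delta) * sqrt(K)
  tau <- numeric(K)
  if (Rrs > 1) {
    spike <- max(1L, min(K, floor(K / Rrs)))
    upto <- spike - 1L
    if (upto >= 1) tau[1:upto] <- Rrs / ((1:upto) * K)
    tau[spike] <- Rrs * log(Rrs / delta) / K
  }
  p <- rho + pmax(tau, 0)
  p / sum(p)
}

# droplet seed -> (degree, neighbor set), via the self-contained LCG so the
# expansion is reproducible from the stored 16-bit seed alone
droplet_neighbors <- function(droplet_id, K, cdf) {
  rng <- lcg_new((2654435761 * (droplet_id + 1)) %% 4294967296)
  rng$next_u32(); rng$next_u32()        # warm-up
  d <- findInterval(rng$next_unif(), cdf) + 1L
  d <- min(d, K)
  if (d >= K) return(seq_len(K))
  nb <- integer(0)
  while (length(nb) < d) {
    cand <- rng$next_int(K)
    if (!(cand %in% nb)) nb <- c(nb, cand)
  }
  sort(nb)
}

fountain_encode_ <- function(data, params) {
  seg_bytes <- params$seg_bytes
  K <- params$K %||% ceiling(length(data) / seg_bytes)
  stopifnot(K >= 1L)
  # tolerance guards against floating-point overshoot (e.g. 110 + 1e-14)
  count <- as.integer(ceiling(K * (1 + params$epsilon) - 1e-9))
  if (count > 65536) stop("droplet count exceeds the 2-byte seed space")
  padded <- c(as.integer(data), integer(K * seg_bytes - length(data)))
  segs <- matrix(padded, nrow = seg_bytes, ncol = K)
  cdf <- cumsum(robust_soliton(K, params$c, params$delta))
  cdf <- cdf[-length(cdf)]              # findInterval boundaries
  seqs <- vapply(seq_len(count) - 1L, function(id) {
    nb <- droplet_neighbors(id, K, cdf)
    val <- integer(seg_bytes)
    for (j in nb) val <- bitwXor(val, segs[, j])
    msg <- c(int_to_bytes(id, params$seed_bytes), val)
    cw <- rs_encode_block(msg, params$parity_bytes)
    bytes_to_dna(cw, pad_to_nt = params$L)
  }, character(1))
  list(sequences = seqs, meta = list(count = count, K = K))
}

fountain_decode_ <- function(cand, params, meta) {
  K <- meta$K
  seg_bytes <- params$seg_bytes
  cdf <- cumsum(robust_soliton(K, params$c, params$delta))
  cdf <- cdf[-length(cdf)]
  # collect verified droplets (detection only; first occurrence per id)
  ids_seen <- logical(meta$count)
  neighbors <- list()
  values <- list()
  n_discarded <- 0L
  for (s in cand$sequences) {
    if (nchar(s) < 4L * params$n) { n_discarded <- n_discarded + 1L; next }
    bytes <- tryCatch(dna_to_bytes(s, params$n), error = function(e) NULL)
    if (is.null(bytes) || any(rs_syndromes(bytes, params$parity_bytes) != 0L)) {
      n_discarded <- n_discarded + 1L
      next
    }
    id <- bytes_to_int(bytes[seq_len(params$seed_bytes)])
    if (id >= meta$count || ids_seen[id + 1L]) next
    ids_seen[id + 1L] <- TRUE
    neighbors[[length(neighbors) + 1L]] <- droplet_neighbors(id, K, cdf)
    values[[length(values) + 1L]] <-
      bytes[(params$seed_bytes + 1L):(params$seed_bytes + seg_bytes)]
  }
  resolved <- vector("list", K)
  if (length(neighbors)) {
    # belief-propagation peeling
    seg_index <- vector("list", K)  # droplets touching each segment
    for (i in seq_along(neighbors)) {
      for (j in neighbors[[i]]) seg_index[[j]] <- c(seg_index[[j]], i)
    }
    queue <- which(lengths(neighbors) == 1L)
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      if (length(neighbors[[i]]) != 1L) next
      j <- neighbors[[i]]
      if (!is.null(resolved[[j]])) { neighbors[[i]] <- integer(0); next }
      resolved[[j]] <- values[[i]]
      neighbors[[i]] <- integer(0)
      for (ii in seg_index[[j]]) {
        if (j %in% neighbors[[ii]]) {
          values[[ii]] <- bitwXor(values[[ii]], resolved[[j]])
          neighbors[[ii]] <- setdiff(neighbors[[ii]], j)
          if (length(neighbors[[ii]]) == 1L) queue <- c(queue, ii)
        }
      }
    }
    # Gaussian-elimination fallback on the residual system
    todo <- which(vapply(resolved, is.null, logical(1)))
    if (length(todo)) {
      rows <- which(lengths(neighbors) > 0L)
      if (length(rows)) {
        A <- matrix(FALSE, nrow = length(rows), ncol = length(todo))
        for (r in seq_along(rows)) {
          A[r, match(neighbors[[rows[r]]], todo)] <- TRUE
        }
        V <- values[rows]
        piv <- integer(length(todo))
        rr <- 1L
        for (col in seq_along(todo)) {
          hit <- which(A[, col] & seq_len(nrow(A)) >= rr)
          if (!length(hit)) { piv[col] <- NA_integer_; next }
          h <- hit[1L]
          if (h != rr) {
            A[c(h, rr), ] <- A[c(rr, h), ]
            V[c(h, rr)] <- V[c(rr, h)]
          }
          others <- which(A[, col] & seq_len(nrow(A)) != rr)
          for (o in others) {
            A[o, ] <- xor(A[o, ], A[rr, ])
            V[[o]] <- bitwXor(V[[o]], V[[rr]])
          }
          piv[col] <- rr
          rr <- rr + 1L
        }
        if (!anyNA(piv)) {
          for (col in seq_along(todo)) resolved[[todo[col]]] <- V[[piv[col]]]
        }
      }
    }
  }
  if (any(vapply(resolved, is.null, logical(1)))) {
    return(decode_result("failure", diagnostics = list(
      droplets_used = length(neighbors), droplets_discarded = n_discarded,
      unresolved = sum(vapply(resolved, is.null, logical(1))),
      reason = "unresolved segments")))
  }
  payload <- as.raw(unlist(resolved)[seq_len(meta$payload_size)])
  decode_result("success", payload = payload, diagnostics = list(
    droplets_used = length(neighbors), droplets_discarded = n_discarded,
    unresolved = 0L))
}
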