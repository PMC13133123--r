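#' The Reed-Solomon inner/outer reference codec
#'
#' Embodies the inner/outer code-separation strategy: an inner RS code
#' within each sequence corrects symbol errors, and an outer RS code
#' across sequences recovers dropped or uncorrectable sequences as
#' erasures (plus residual errors, `2*errors + erasures <= N - K`).
#'
#' Layout per sequence (at 2 bit/nt): index bytes, body bytes, inner
#' parity bytes.  The pool is organized into outer blocks of `outer_n`
#' sequences (`outer_k` of them data); pools larger than one block are
#' split into round-robin interleaved blocks so clustered dropout spreads
#' across blocks.  Outer parity is computed per byte position across the
#' block ("column-wise").
#'
#' Inner decoding marks uncorrectable sequences as erasures; outer
#' decoding is errors-and-erasures.  Standardized parameter sets for code
#' rates 0.50 / 1.00 / 1.50 bit per nt at L = 150 ship as presets
#' (see `inst/extdata/codec_presets.yaml` and [codec_preset()]).
#'
#' @param L Design sequence length in nt.
#' @param inner_parity Inner RS parity symbols per sequence (corrects
#'   `floor(inner_parity / 2)` byte errors).
#' @param outer_n,outer_k Outer block length and data count in sequences
#'   (`outer_k < outer_n <= 255`).
#' @return A codec object for [codec_encode()] / [codec_decode()].
#' @export
#' @examples
#' cdc <- rs_codec(L = 48, inner_parity = 4, outer_n = 7, outer_k = 4)
#' enc <- codec_encode(cdc, generate_payload(20, seed = 1))
#' codec_decode(cdc, enc$pool, enc$meta)$status
rs_codec <- function(L = 150L, inner_parity = 6L, outer_n = 100L,
                     outer_k = 62L) {
  n <- L %/% 4L
  stopifnot(inner_parity >= 1L, n - inner_parity >= 2L,
            outer_k >= 1L, outer_k < outer_n, outer_n <= 255L)
  params <- list(L = as.integer(L), n = as.integer(n),
                 inner_parity = as.integer(inner_parity),
                 outer_n = as.integer(outer_n),
                 outer_k = as.integer(outer_k))
  new_codec("rs_inner_outer", params, rs_encode_, rs_decode_)
}

rs_layout <- function(size_bytes, params) {
  k <- params$n - params$inner_parity
  idx_width <- 1L
  repeat {
    body <- k - idx_width
    if (body < 1L) stop("no payload capacity at these parameters")
    per_block <- params$outer_k * body
    blocks <- max(1L, ceiling(size_bytes / per_block))
    count <- blocks * params$outer_n
    if (count <= 256^idx_width) break
    idx_width <- idx_width + 1L
  }
  list(k = k, idx_width = idx_width, body = body, blocks = blocks,
       count = count)
}

rs_encode_ <- function(data, params) {
  lay <- rs_layout(length(data), params)
  K <- params$outer_k; N <- params$outer_n
  padded <- c(as.integer(data),
              integer(lay$blocks * K * lay$body - length(data)))
  # data chunk for (block b, position p) is chunk index b*K + p  (0-based)
  seqs <- character(lay$count)
  for (b in seq_len(lay$blocks) - 1L) {
    block <- matrix(padded[(b * K * lay$body + 1L):((b + 1L) * K * lay$body)],
                    nrow = lay$body, ncol = K)
    # outer code: each byte position across the block is a codeword
    parity <- t(apply(block, 1L, function(row) {
      cw <- rs_encode_block(row, N - K)
      cw[(K + 1L):N]
    }))
    if (lay$body == 1L) parity <- matrix(parity, nrow = 1L)
    full <- cbind(block, parity)          # body x N
    for (p in seq_len(N) - 1L) {
      g <- p * lay$blocks + b             # round-robin global index
      msg <- c(int_to_bytes(g, lay$idx_width), full[, p + 1L])
      cw <- rs_encode_block(msg, params$inner_parity)
      seqs[g + 1L] <- bytes_to_dna(cw, pad_to_nt = params$L)
    }
  }
  list(sequences = seqs,
       meta = list(count = lay$count, blocks = lay$blocks,
                   idx_width = lay$idx_width, body = lay$body))
}

rs_decode_ <- function(cand, params, meta) {
  K <- params$outer_k; N <- params$outer_n
  blocks <- meta$blocks
  slots <- vector("list", meta$count)
  inner_corrected <- 0L
  inner_failed <- 0L
  n <- params$n
  usable <- which(nchar(cand$sequences) >= 4L * n)
  inner_failed <- inner_failed + length(cand$sequences) - length(usable)
  if (length(usable)) {
    B <- dna_to_bytes_matrix(substr(cand$sequences[usable], 1L, 4L * n), n)
    S <- batch_syndromes(B, params$inner_parity)
    clean <- colSums(S != 0L) == 0L
    store <- function(msg) {
      g <- bytes_to_int(msg[seq_len(meta$idx_width)]) + 1
      if (g >= 1 && g <= meta$count && is.null(slots[[g]])) {
        slots[[g]] <<- msg[(meta$idx_width + 1L):length(msg)]
        TRUE
      } else FALSE
    }
    # error-free candidates first (heaviest first within each class)
    for (ci in which(clean)) {
      store(B[seq_len(n - params$inner_parity), ci])
    }
    n_empty <- sum(vapply(slots, is.null, logical(1)))
    for (ci in which(!clean)) {
      if (n_empty == 0L) break
      d <- rs_decode_block(B[, ci], params$inner_parity, synd = S[, ci])
      if (!d$ok) { inner_failed <- inner_failed + 1L; next }
      if (store(d$msg)) {
        n_empty <- n_empty - 1L
        if (d$n_corrected > 0L) inner_corrected <- inner_corrected + 1L
      }
    }
  }
  filled <- !vapply(slots, is.null, logical(1))
  erased <- sum(!filled)
  out <- integer(blocks * K * meta$body)
  for (b in seq_len(blocks) - 1L) {
    gs <- (seq_len(N) - 1L) * blocks + b + 1L       # global indices, p=0..N-1
    present <- filled[gs]
    erase_pos <- which(!present)
    if (length(erase_pos) > N - K) {
      return(decode_result("failure", diagnostics = list(
        inner_corrected = inner_corrected, inner_failed = inner_failed,
        erased = erased, outer_recovered = 0L,
        reason = "outer erasures exceed parity")))
    }
    received <- matrix(0L, nrow = meta$body, ncol = N)
    for (p in which(present)) received[, p] <- slots[[gs[p]]]
    for (row in seq_len(meta$body)) {
      d <- rs_decode_block(received[row, ], N - K, erase_pos = erase_pos)
      if (!d$ok) {
        return(decode_result("failure", diagnostics = list(
          inner_corrected = inner_corrected, inner_failed = inner_failed,
          erased = erased, outer_recovered = 0L,
          reason = "outer decode failure")))
      }
      out[(b * K * meta$body) + (seq_len(K) - 1L) * meta$body + row] <-
        d$msg[seq_len(K)]
    }
  }
  payload <- as.raw(out[seq_len(meta$payload_size)])
  decode_result("success", payload = payload, diagnostics = list(
    inner_corrected = inner_corrected, inner_failed = inner_failed,
    erased = erased, outer_recovered = erased))
}
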