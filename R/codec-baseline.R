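#' The no-ECC baseline codec
#'
#' Each sequence is a base-4 index prefix followed by a base-4 payload
#' chunk at 2 bits per nt — no error correction of any kind.  Decoding
#' takes the heaviest candidate per recovered index, concatenates chunks
#' in index order and truncates to the payload length; any missing index
#' or corrupted byte makes the byte-for-byte comparison fail.  Its
#' tolerance therefore comes entirely from the clustering/consensus step
#' (and it cannot compensate for any sequence dropout).
#'
#' @param L Design sequence length in nt (default 150).
#' @return A codec object for [codec_encode()] / [codec_decode()].
#' @export
#' @examples
#' cdc <- baseline_codec(L = 20)
#' enc <- codec_encode(cdc, generate_payload(8, seed = 1))
#' codec_decode(cdc, enc$pool, enc$meta)$status
baseline_codec <- function(L = 150L) {
  stopifnot(L >= 8L, L %/% 4L >= 2L)
  params <- list(L = as.integer(L))
  new_codec("baseline", params, baseline_encode_, baseline_decode_)
}

baseline_encode_ <- function(data, params) {
  n <- params$L %/% 4L
  # index width grows with the sequence count; fixed-point iteration
  idx_width <- 1L
  repeat {
    chunk <- n - idx_width
    if (chunk < 1L) stop("payload too large for the index width at this L")
    count <- ceiling(length(data) / chunk)
    if (count <= 256^idx_width) break
    idx_width <- idx_width + 1L
  }
  padded <- c(as.integer(data), integer(count * chunk - length(data)))
  seqs <- vapply(seq_len(count), function(g) {
    bytes <- c(int_to_bytes(g - 1L, idx_width),
               padded[((g - 1L) * chunk + 1L):(g * chunk)])
    bytes_to_dna(bytes, pad_to_nt = params$L)
  }, character(1))
  list(sequences = seqs,
       meta = list(count = count, idx_width = idx_width, chunk = chunk))
}

baseline_decode_ <- function(cand, params, meta) {
  n <- params$L %/% 4L
  slots <- vector("list", meta$count)
  for (s in cand$sequences) {
    if (nchar(s) < 4L * n) next
    bytes <- tryCatch(dna_to_bytes(s, n), error = function(e) NULL)
    if (is.null(bytes)) next
    g <- bytes_to_int(bytes[seq_len(meta$idx_width)]) + 1
    if (g >= 1 && g <= meta$count && is.null(slots[[g]])) {
      slots[[g]] <- bytes[(meta$idx_width + 1L):n]
    }
  }
  missing <- sum(vapply(slots, is.null, logical(1)))
  if (missing > 0L) {
    return(decode_result("failure", diagnostics = list(
      erased = missing, reason = "missing sequence index")))
  }
  payload <- as.raw(unlist(slots)[seq_len(meta$payload_size)])
  decode_result("success", payload = payload,
                diagnostics = list(erased = 0L))
}
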