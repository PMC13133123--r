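# Common codec machinery: the 2 bit/nt base mapping (A=00, C=01, G=10,
# T=11), sequence indexing, the codec interface, and the decode-result
# contract.  Every decoder's success claim is verified against the
# payload checksum recorded at encode time, so a decoder can never report
# success with a payload differing from the input.

#' Convert bytes to DNA and back
#'
#' Two bits per nucleotide, `A=00, C=01, G=10, T=11`, most significant
#' bits first within each byte.  `dna_to_bytes()` ignores trailing
#' nucleotides beyond `4 * floor(nchar(seq) / 4)` only when asked to read
#' a fixed byte count.
#'
#' @param bytes Integer vector in `[0, 255]`.
#' @param pad_to_nt Optional total sequence length; the tail is padded
#'   with `A`.
#' @param seq A DNA string.
#' @param n_bytes Number of bytes to read from the start of `seq`.
#' @return `bytes_to_dna()` a DNA string; `dna_to_bytes()` an integer
#'   vector.
#' @export
#' @examples
#' bytes_to_dna(c(0, 255))          # "AAAATTTT"
#' dna_to_bytes("AAAATTTT", 2)      # 0 255
bytes_to_dna <- function(bytes, pad_to_nt = NULL) {
  b <- as.integer(bytes)
  stopifnot(all(b >= 0L & b <= 255L))
  m <- rbind(b %/% 64L, (b %/% 16L) %% 4L, (b %/% 4L) %% 4L, b %% 4L)
  s <- paste(DNA_BASES[m + 1L], collapse = "")
  if (!is.null(pad_to_nt)) {
    if (nchar(s) > pad_to_nt) stop("sequence longer than pad_to_nt")
    s <- paste0(s, strrep("A", pad_to_nt - nchar(s)))
  }
  s
}

#' @rdname bytes_to_dna
#' @export
dna_to_bytes <- function(seq, n_bytes = nchar(seq) %/% 4L) {
  if (4L * n_bytes > nchar(seq)) stop("sequence too short for n_bytes")
  codes <- match(strsplit(substr(seq, 1L, 4L * n_bytes), "",
                          fixed = TRUE)[[1L]], DNA_BASES) - 1L
  if (anyNA(codes)) stop("sequence contains non-ACGT characters")
  m <- matrix(codes, nrow = 4L)
  as.integer(m[1L, ] * 64L + m[2L, ] * 16L + m[3L, ] * 4L + m[4L, ])
}

# vectorized byte-matrix conversion for equal-length sequences:
# returns an n_bytes x n_seqs integer matrix
dna_to_bytes_matrix <- function(seqs, n_bytes) {
  codes <- match(unlist(strsplit(seqs, "", fixed = TRUE)), DNA_BASES) - 1L
  if (anyNA(codes)) stop("sequence contains non-ACGT characters")
  m <- matrix(codes, nrow = 4L * n_bytes)
  i <- seq(1L, 4L * n_bytes, by = 4L)
  m[i, , drop = FALSE] * 64L + m[i + 1L, , drop = FALSE] * 16L +
    m[i + 2L, , drop = FALSE] * 4L + m[i + 3L, , drop = FALSE]
}

int_to_bytes <- function(x, width) {
  out <- integer(width)
  for (i in width:1) {
    out[i] <- x %% 256L
    x <- x %/% 256L
  }
  out
}

bytes_to_int <- function(b) {
  x <- 0
  for (v in b) x <- x * 256 + v
  x
}

index_width_for <- function(count) max(1L, ceiling(log2(max(count, 2)) / 8))

#' Decode result
#'
#' @param status `"success"` or `"failure"`.
#' @param payload Recovered payload as a raw vector (success only).
#' @param diagnostics Named list of counters and flags (e.g.
#'   `inner_corrected`, `inner_failed`, `erased`, `outer_recovered`,
#'   `reason`).
#' @return A `decode_result` object.
#' @export
decode_result <- function(status, payload = NULL, diagnostics = list()) {
  stopifnot(status %in% c("success", "failure"))
  structure(list(status = status, payload = payload,
                 diagnostics = diagnostics),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %s%s\n", x$status,
              if (x$status == "success")
                sprintf(" (%d bytes)", length(x$payload))
              else if (!is.null(x$diagnostics$reason))
                paste0(": ", x$diagnostics$reason)
              else ""))
  invisible(x)
}

#' Encode a payload with a codec / decode candidate sequences
#'
#' `codec_encode()` returns the encoded [reference_pool()] together with
#' the metadata the decoder needs (`meta`): codec parameters, payload
#' size and payload CRC-32.  `codec_decode()` accepts a consensus set, a
#' reference pool, a read set or a plain character vector of candidate
#' sequences, and returns a [decode_result()].  Success is only reported
#' when the recovered payload matches the recorded checksum and size
#' byte-for-byte.
#'
#' @param codec A codec object ([baseline_codec()], [rs_codec()],
#'   [fountain_codec()], [external_codec_adapter()]).
#' @param payload A [generate_payload()] object or raw vector.
#' @param x Candidate sequences (consensus set, pool, read set or
#'   character vector).
#' @param meta The metadata list returned by `codec_encode()`.
#' @return `codec_encode()`: list with `pool` and `meta`;
#'   `codec_decode()`: a [decode_result()].
#' @export
codec_encode <- function(codec, payload) {
  stopifnot(inherits(codec, "oligo_codec"))
  if (is.raw(payload)) payload <- new_payload(payload)
  stopifnot(inherits(payload, "payload"))
  enc <- codec$fn_encode(payload$data, codec$params)
  meta <- c(enc$meta,
            list(codec = codec$name, payload_size = payload$size_bytes,
                 crc32 = crc32(payload$data)))
  pool <- reference_pool(enc$sequences, payload_size = payload$size_bytes)
  list(pool = pool, meta = meta)
}

#' @rdname codec_encode
#' @export
codec_decode <- function(codec, x, meta) {
  stopifnot(inherits(codec, "oligo_codec"))
  cand <- as_candidates(x)
  res <- codec$fn_decode(cand, codec$params, meta)
  # central never-wrong-success guard: byte-by-byte equivalent check
  if (res$status == "success") {
    p <- res$payload
    if (is.null(p) || length(p) != meta$payload_size ||
        crc32(p) != meta$crc32) {
      res <- decode_result("failure", diagnostics = c(
        res$diagnostics, list(reason = "payload mismatch")))
    }
  }
  res
}

new_codec <- function(name, params, fn_encode, fn_decode) {
  structure(list(name = name, params = params,
                 fn_encode = fn_encode, fn_decode = fn_decode),
            class = "oligo_codec")
}

#' @export
print.oligo_codec <- function(x, ...) {
  cat(sprintf("<codec:%s>\n", x$name))
  invisible(x)
}

# normalize decoder input to (sequences, weight), heaviest first
as_candidates <- function(x) {
  if (inherits(x, "consensus_set")) {
    out <- list(sequences = x$sequences, weight = x$sizes)
  } else if (inherits(x, "reference_pool")) {
    out <- list(sequences = x$sequences,
                weight = rep(1, length(x$sequences)))
  } else if (inherits(x, "read_set")) {
    out <- list(sequences = x$sequences, weight = x$abundance)
  } else if (is.character(x)) {
    out <- list(sequences = x, weight = rep(1, length(x)))
  } else {
    stop("cannot interpret decoder input of class ",
         paste(class(x), collapse = "/"))
  }
  ord <- order(-out$weight, out$sequences)
  list(sequences = out$sequences[ord], weight = out$weight[ord])
}
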