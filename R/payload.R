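#' Generate a random binary payload
#'
#' Produces a uniformly random byte string of exactly `size_bytes` bytes,
#' reproducible from the seed.  The default benchmark payload is a 19 kB
#' (19456 byte) random-content file.
#'
#' @param size_bytes Positive integer, payload size in bytes.
#' @param seed Integer seed.
#' @param label Free-text label stored with the payload.
#' @return A `payload` object: list with `data` (raw vector), `size_bytes`
#'   and `label`.
#' @export
#' @examples
#' p <- generate_payload(64, seed = 1)
#' p$size_bytes
generate_payload <- function(size_bytes, seed = 1L, label = "random") {
  if (!is.numeric(size_bytes) || length(size_bytes) != 1L ||
      is.na(size_bytes) || size_bytes < 1) {
    stop("`size_bytes` must be a positive integer")
  }
  size_bytes <- as.integer(size_bytes)
  data <- with_seed(derive_seed(seed, "payload"),
                    as.raw(sample.int(256L, size_bytes, replace = TRUE) - 1L))
  new_payload(data, label = label)
}

new_payload <- function(data, label = "payload") {
  stopifnot(is.raw(data))
  structure(list(data = data, size_bytes = length(data), label = label),
            class = "payload")
}

#' @export
print.payload <- function(x, ...) {
  cat(sprintf("<payload> %s: %d bytes, crc32 %.0f\n",
              x$label, x$size_bytes, crc32(x$data)))
  invisible(x)
}

#' Read or write a binary payload file
#'
#' Payload files round-trip bit-exactly.
#'
#' @param path File path.
#' @param payload A `payload` object (or raw vector) to write.
#' @return `read_payload()` returns a `payload`; `write_payload()` returns
#'   `path` invisibly.
#' @export
read_payload <- function(path) {
  if (!file.exists(path)) stop("payload file does not exist: ", path)
  n <- file.info(path)$size
  new_payload(readBin(path, "raw", n = n), label = basename(path))
}

#' @rdname read_payload
#' @export
write_payload <- function(payload, path) {
  if (is.raw(payload)) payload <- new_payload(payload)
  stopifnot(inherits(payload, "payload"))
  writeBin(payload$data, path)
  invisible(path)
}

# -- CRC-32 (IEEE 802.3, poly 0xEDB88320 reflected) --------------------------
# Used internally so decoders can never report success with a corrupted
# payload: every encoder records the payload checksum in its parameters and
# every decoder verifies it before declaring success.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (c %% 2 == 1) bitwXor64(3988292384, c %/% 2) else c %/% 2
        }
        t[i + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

#' CRC-32 checksum of a raw vector
#'
#' @param data Raw vector.
#' @return The checksum as a double in `[0, 2^32)`.
#' @export
#' @examples
#' crc32(charToRaw("123456789"))  # 3421780262 (0xcbf43926)
crc32 <- function(data) {
  stopifnot(is.raw(data))
  tab <- crc32_table()
  crc <- 4294967295
  ints <- as.integer(data)
  for (b in ints) {
    crc <- bitwXor64(crc %/% 256, tab[bitwXor(as.integer(crc %% 256), b) + 1])
  }
  bitwXor64(crc, 4294967295)
}
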