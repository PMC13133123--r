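#' Construct a reference pool
#'
#' The ordered set of encoded DNA sequences that constitutes the ground
#' truth for all downstream evaluation.  All sequences must share the
#' design length `L` and use the strict A/C/G/T alphabet.
#'
#' @param sequences Character vector of DNA sequences over `{A,C,G,T}`.
#' @param ids Optional character vector of unique, stable identifiers
#'   (default `seq_00001` style).
#' @param code_rate Code rate in bit per nt, if known (else computed from
#'   `payload_size` when available).
#' @param payload_size Encoded payload size in bytes, if known.
#' @param alphabet Allowed sequence characters (default strict A/C/G/T;
#'   pass [IUPAC_BASES] to tolerate ambiguity codes).
#' @return A `reference_pool` object.
#' @export
reference_pool <- function(sequences, ids = NULL, code_rate = NA_real_,
                           payload_size = NA_integer_,
                           alphabet = DNA_BASES) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  check_dna(sequences, what = "reference sequence", alphabet = alphabet)
  L <- unique(nchar(sequences))
  if (length(L) != 1L) {
    stop("all reference sequences must share the design length; found lengths ",
         paste(sort(L), collapse = ", "))
  }
  if (is.null(ids)) {
    ids <- sprintf("seq_%05d", seq_along(sequences))
  }
  stopifnot(length(ids) == length(sequences))
  if (anyDuplicated(ids)) stop("reference pool ids must be unique")
  if (is.na(code_rate) && !is.na(payload_size)) {
    code_rate <- 8 * payload_size / (length(sequences) * L)
  }
  structure(list(sequences = unname(sequences), ids = as.character(ids),
                 length = L, code_rate = code_rate,
                 payload_size = payload_size),
            class = "reference_pool")
}

#' @export
print.reference_pool <- function(x, ...) {
  cat(sprintf("<reference_pool> %d sequences x %d nt, code rate %s bit/nt\n",
              length(x$sequences), x$length,
              ifelse(is.na(x$code_rate), "?", format(round(x$code_rate, 4)))))
  invisible(x)
}

#' Achieved code rate of a pool
#'
#' `8 * payload_size / (count * L)` in bit per nt.
#'
#' @param pool A `reference_pool` with known `payload_size`.
#' @return Numeric scalar.
#' @export
pool_code_rate <- function(pool) {
  stopifnot(inherits(pool, "reference_pool"))
  if (is.na(pool$payload_size)) stop("pool has no payload_size metadata")
  8 * pool$payload_size / (length(pool$sequences) * pool$length)
}

#' Construct a read set
#'
#' Simulated sequencing reads.  Each read may carry its ground-truth origin
#' (the index of the reference sequence it derives from) and an abundance
#' (multiplicity); identical reads from the same origin may be collapsed
#' into one record with abundance > 1.
#'
#' @param sequences Character vector of read sequences over `{A,C,G,T}`.
#' @param origins Optional integer vector of 1-based reference indices
#'   (NA when unknown).
#' @param abundance Positive integer multiplicities (default all 1).
#' @param pool_size Size of the originating pool (used for the `depth`
#'   summary); NA if unknown.
#' @param pool_ref Identifier of the originating pool.
#' @return A `read_set` object.
#' @export
read_set <- function(sequences, origins = NULL, abundance = NULL,
                     pool_size = NA_integer_, pool_ref = NA_character_) {
  stopifnot(is.character(sequences))
  if (length(sequences) && any(!nzchar(sequences)))
    stop("reads must be non-empty")
  check_dna(sequences, what = "read")
  n <- length(sequences)
  if (is.null(origins)) origins <- rep(NA_integer_, n)
  if (is.null(abundance)) abundance <- rep(1L, n)
  stopifnot(length(origins) == n, length(abundance) == n,
            all(abundance >= 1L))
  structure(list(sequences = unname(sequences),
                 origins = as.integer(origins),
                 abundance = as.integer(abundance),
                 pool_size = as.integer(pool_size),
                 pool_ref = pool_ref),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  n <- sum(x$abundance)
  depth <- if (is.na(x$pool_size)) NA_real_ else n / x$pool_size
  cat(sprintf("<read_set> %d reads (%d unique records), depth %s\n",
              n, length(x$sequences),
              ifelse(is.na(depth), "?", format(round(depth, 2)))))
  invisible(x)
}

#' Mean sequencing depth of a read set
#'
#' Total read count (with multiplicity) divided by the originating pool size.
#'
#' @param readset A `read_set` with known `pool_size`.
#' @return Numeric scalar.
#' @export
read_depth <- function(readset) {
  stopifnot(inherits(readset, "read_set"))
  if (is.na(readset$pool_size)) stop("read set has no pool_size metadata")
  sum(readset$abundance) / readset$pool_size
}

# expand a read_set so every physical read is one record
expand_reads <- function(readset) {
  if (all(readset$abundance == 1L)) return(readset)
  idx <- rep(seq_along(readset$sequences), readset$abundance)
  read_set(readset$sequences[idx], readset$origins[idx],
           pool_size = readset$pool_size, pool_ref = readset$pool_ref)
}

check_dna <- function(x, what = "sequence", alphabet = DNA_BASES) {
  bad <- grepl(sprintf("[^%s]", paste(alphabet, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("%s %d contains characters outside {%s}",
                 what, which(bad)[1L], paste(alphabet, collapse = ",")))
  }
  invisible(TRUE)
}
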