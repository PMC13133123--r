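# FASTA/FASTQ exchange.  Pools are exchanged with external codecs and tools
# as FASTA; simulated reads are persisted as FASTQ with placeholder
# qualities (the pipeline is quality-blind: reads are merged and clustered,
# and qualities are discarded downstream).  Parsing is delegated to
# Biostrings; this layer adds the strict-alphabet contract and the
# origin-index round-trip.

#' Read and write reference pools as FASTA
#'
#' `write_pool_fasta()` followed by `read_pool_fasta()` is the identity on
#' `(ids, sequences)`; line wrapping is not significant.  In strict mode
#' (the default) any record with characters outside `{A,C,G,T}` is a format
#' error naming the record; with `iupac = TRUE` IUPAC ambiguity codes are
#' tolerated.
#'
#' @param path File path.
#' @param iupac Tolerate IUPAC ambiguity letters (default strict A/C/G/T).
#' @param pool A `reference_pool`.
#' @return `read_pool_fasta()` returns a `reference_pool`;
#'   `write_pool_fasta()` returns `path` invisibly.
#' @export
read_pool_fasta <- function(path, iupac = FALSE) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- as.character(x)
  ids <- sub("\\s.*$", "", names(x))
  if (!iupac) {
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad)) {
      stop(sprintf("record '%s' contains non-ACGT characters (strict mode)",
                   ids[which(bad)[1L]]))
    }
  }
  meta <- parse_header_fields(names(x))
  reference_pool(seqs, ids = ids,
                 code_rate = meta$code_rate %||% NA_real_,
                 payload_size = meta$payload_size %||% NA_integer_,
                 alphabet = if (iupac) IUPAC_BASES else DNA_BASES)
}

#' @rdname read_pool_fasta
#' @export
write_pool_fasta <- function(pool, path) {
  stopifnot(inherits(pool, "reference_pool"))
  if (length(pool$sequences) == 0L) stop("cannot write an empty pool")
  x <- Biostrings::DNAStringSet(pool$sequences)
  hdr <- pool$ids
  extra <- character(0)
  if (!is.na(pool$code_rate)) extra <- c(extra, sprintf("code_rate=%.6g", pool$code_rate))
  if (!is.na(pool$payload_size)) extra <- c(extra, sprintf("payload_size=%d", pool$payload_size))
  if (length(extra)) hdr[1L] <- paste(c(hdr[1L], extra), collapse = " ")
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read and write read sets as FASTQ
#'
#' Reads are written with a constant placeholder quality (`I`) which is
#' ignored on read-back.  The ground-truth origin index travels in the
#' record description (`origin=<i>`) and is recovered on round-trip; reads
#' with abundance k are expanded into k records with distinct suffixes.
#'
#' @param path File path.
#' @param readset A `read_set`.
#' @return `read_reads_fastq()` returns a `read_set`;
#'   `write_reads_fastq()` returns `path` invisibly.
#' @export
read_reads_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file does not exist: ", path)
  check_fastq_format(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(x) == 0L) stop("FASTQ file contains no records: ", path)
  meta <- parse_header_fields(names(x))
  read_set(as.character(x), origins = meta$origins,
           pool_size = meta$pool_size %||% NA_integer_)
}

#' @rdname read_reads_fastq
#' @export
write_reads_fastq <- function(readset, path) {
  stopifnot(inherits(readset, "read_set"))
  ex <- expand_reads(readset)
  if (length(ex$sequences) == 0L) stop("cannot write an empty read set")
  x <- Biostrings::DNAStringSet(ex$sequences)
  hdr <- sprintf("r%06d", seq_along(ex$sequences))
  has_origin <- !is.na(ex$origins)
  hdr[has_origin] <- sprintf("%s origin=%d", hdr[has_origin],
                             ex$origins[has_origin])
  if (!is.na(ex$pool_size)) {
    hdr[1L] <- sprintf("%s pool_size=%d", hdr[1L], ex$pool_size)
  }
  names(x) <- hdr
  qual <- Biostrings::BStringSet(vapply(nchar(ex$sequences), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

# minimal structural validation: record framing and sequence/quality length
# agreement (Biostrings is lenient about the latter)
check_fastq_format <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("FASTQ file contains no records: ", path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in ", path, ": line count not a multiple of 4")
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (any(!startsWith(ids, "@")) || any(!startsWith(plus, "+")))
    stop("malformed FASTQ in ", path, ": bad record framing")
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    stop(sprintf("malformed FASTQ in %s: record '%s' has mismatched sequence/quality lengths",
                 path, sub("^@", "", sub("\\s.*$", "", ids[which(bad)[1L]]))))
  }
  invisible(TRUE)
}

# pull `key=value` annotations out of FASTA/FASTQ headers
parse_header_fields <- function(headers) {
  grab <- function(key) {
    m <- regmatches(headers, regexpr(sprintf("%s=[0-9.eE+-]+", key), headers))
    has <- grepl(sprintf("%s=", key), headers, fixed = TRUE)
    vals <- rep(NA_character_, length(headers))
    vals[has] <- sub(sprintf("^%s=", key), "", m)
    vals
  }
  origins <- suppressWarnings(as.integer(grab("origin")))
  ps <- suppressWarnings(as.integer(grab("pool_size")))
  cr <- suppressWarnings(as.numeric(grab("code_rate")))
  psz <- suppressWarnings(as.integer(grab("payload_size")))
  list(origins = origins,
       pool_size = if (any(!is.na(ps))) ps[!is.na(ps)][1L] else NULL,
       code_rate = if (any(!is.na(cr))) cr[!is.na(cr)][1L] else NULL,
       payload_size = if (any(!is.na(psz))) psz[!is.na(psz)][1L] else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
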