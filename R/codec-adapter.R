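#' Wrap an external encoder/decoder pair as a codec
#'
#' Lets out-of-process codecs be benchmarked through the same interface
#' as the built-in ones.  `encode_cmd` and `decode_cmd` are shell command
#' templates with `{in}` and `{out}` placeholders: encoding reads a
#' binary payload file and writes a FASTA pool; decoding reads a FASTA of
#' candidate sequences and writes the recovered payload file.  A nonzero
#' exit status, a missing output file, or exceeding `timeout_s` converts
#' the result into a decode failure (with a timeout diagnostic), matching
#' the rule that any constraint violation along the pipeline counts as
#' unsuccessful decoding.  Byte mismatches are caught by the central
#' checksum guard in [codec_decode()].
#'
#' @param encode_cmd,decode_cmd Command templates (character scalars)
#'   containing `{in}` and `{out}`.
#' @param timeout_s Wall-time limit per invocation in seconds
#'   (default 3600).
#' @return A codec object for [codec_encode()] / [codec_decode()].
#' @export
external_codec_adapter <- function(encode_cmd, decode_cmd,
                                   timeout_s = 3600) {
  stopifnot(is.character(encode_cmd), is.character(decode_cmd),
            timeout_s > 0)
  params <- list(encode_cmd = encode_cmd, decode_cmd = decode_cmd,
                 timeout_s = timeout_s)
  new_codec("external", params, adapter_encode_, adapter_decode_)
}

run_template <- function(template, infile, outfile, timeout_s) {
  cmd <- gsub("{in}", infile, gsub("{out}", outfile, template,
                                   fixed = TRUE), fixed = TRUE)
  t0 <- Sys.time()
  status <- tryCatch(
    system(cmd, timeout = ceiling(timeout_s), ignore.stdout = TRUE,
           ignore.stderr = TRUE),
    error = function(e) 124L, warning = function(w) 124L)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(status = status, timed_out = status == 124L || elapsed > timeout_s,
       elapsed = elapsed)
}

adapter_encode_ <- function(data, params) {
  fin <- tempfile(fileext = ".bin")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)))
  writeBin(as.raw(data), fin)
  r <- run_template(params$encode_cmd, fin, fout, params$timeout_s)
  if (r$status != 0L || !file.exists(fout)) {
    stop("external encoder failed (exit status ", r$status, ")")
  }
  pool <- read_pool_fasta(fout)
  list(sequences = pool$sequences,
       meta = list(count = length(pool$sequences)))
}

adapter_decode_ <- function(cand, params, meta) {
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".bin")
  on.exit(unlink(c(fin, fout)))
  write_pool_fasta(reference_pool_lenient(cand$sequences), fin)
  r <- run_template(params$decode_cmd, fin, fout, params$timeout_s)
  if (r$timed_out) {
    return(decode_result("failure",
                         diagnostics = list(reason = "timeout",
                                            elapsed_s = r$elapsed)))
  }
  if (r$status != 0L || !file.exists(fout)) {
    return(decode_result("failure",
                         diagnostics = list(reason = "external decoder exit",
                                            exit_status = r$status)))
  }
  payload <- readBin(fout, "raw", n = file.info(fout)$size)
  decode_result("success", payload = payload,
                diagnostics = list(elapsed_s = r$elapsed))
}

# candidate sequences may have heterogeneous lengths; bypass the
# equal-length pool invariant for the exchange file
reference_pool_lenient <- function(sequences) {
  L <- max(nchar(sequences))
  padded <- vapply(sequences, function(s)
    paste0(s, strrep("A", L - nchar(s))), character(1))
  reference_pool(padded)
}
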