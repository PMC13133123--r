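test_that("all codecs round-trip over the noiseless channel", {
  payload <- generate_payload(400, seed = 6)
  for (cdc in list(baseline_codec(60),
                   rs_codec(60, inner_parity = 4, outer_n = 50,
                            outer_k = 30),
                   fountain_codec(60, epsilon = 0.5))) {
    enc <- codec_encode(cdc, payload)
    res <- codec_decode(cdc, enc$pool, enc$meta)
    expect_equal(res$status, "success", info = cdc$name)
    expect_identical(res$payload, payload$data)
  }
})

test_that("standardized presets achieve their target code rates", {
  targets <- c("0.50" = 0.50, "1.00" = 1.00, "1.50" = 1.50)
  # payload sized to fill one outer block per preset
  sizes <- c("0.50" = 936, "1.00" = 1860, "1.50" = 2784)
  for (nm in names(targets)) {
    enc <- codec_encode(codec_preset("rs", nm),
                        generate_payload(sizes[[nm]], seed = 1))
    rho <- pool_code_rate(enc$pool)
    expect_lt(abs(rho - targets[[nm]]) / targets[[nm]], 0.05)
    expect_equal(enc$pool$length, 150L)
    # pool invariant: rho recomputed from the pool fields
    expect_equal(rho, 8 * enc$meta$payload_size /
                   (length(enc$pool$sequences) * 150))
  }
  for (nm in names(targets)) {
    cdc <- codec_preset("fountain", nm)
    enc <- codec_encode(cdc, generate_payload(3300, seed = 1))
    rho <- pool_code_rate(enc$pool)
    expect_lt(abs(rho - targets[[nm]]) / targets[[nm]], 0.05)
  }
})

test_that("the baseline codec has no tolerance at all", {
  payload <- generate_payload(64, seed = 2)
  cdc <- baseline_codec(40)
  enc <- codec_encode(cdc, payload)
  # one missing sequence -> failure
  res <- codec_decode(cdc, enc$pool$sequences[-3], enc$meta)
  expect_equal(res$status, "failure")
  # one substituted nt -> wrong bytes -> failure by byte comparison
  seqs <- enc$pool$sequences
  substr(seqs[2], 12, 12) <- ifelse(substr(seqs[2], 12, 12) == "A", "C", "A")
  expect_equal(codec_decode(cdc, seqs, enc$meta)$status, "failure")
})

test_that("RS codec dropout tolerance equals the outer bound, exhaustively", {
  # small instance: outer (7,4) -> tolerates any 3 of 7 dropped, never 4
  cdc <- rs_codec(L = 48, inner_parity = 4, outer_n = 7, outer_k = 4)
  payload <- generate_payload(20, seed = 4)
  enc <- codec_encode(cdc, payload)
  expect_equal(length(enc$pool$sequences), 7L)
  for (pat in combn(7, 3, simplify = FALSE)) {
    res <- codec_decode(cdc, enc$pool$sequences[-pat], enc$meta)
    expect_equal(res$status, "success")
    expect_identical(res$payload, payload$data)
  }
  for (pat in combn(7, 4, simplify = FALSE)) {
    expect_equal(codec_decode(cdc, enc$pool$sequences[-pat], enc$meta)$status,
                 "failure")
  }
})

test_that("RS inner code corrects within its radius and reports it", {
  cdc <- codec_preset("rs", "1.50")  # inner parity 4 -> radius 2
  payload <- generate_payload(2784, seed = 5)
  enc <- codec_encode(cdc, payload)
  seqs <- enc$pool$sequences
  b <- dna_to_bytes(seqs[10], 37)
  b[c(4, 20)] <- bitwXor(b[c(4, 20)], c(17L, 200L))
  seqs[10] <- bytes_to_dna(b, pad_to_nt = 150)
  res <- codec_decode(cdc, seqs, enc$meta)
  expect_equal(res$status, "success")
  expect_equal(res$diagnostics$inner_corrected, 1L)
  expect_identical(res$payload, payload$data)
})

test_that("decoders never report wrong-success", {
  # corrupt every sequence heavily; whatever happens, a success status
  # must carry the byte-identical payload
  payload <- generate_payload(200, seed = 7)
  for (cdc in list(baseline_codec(60),
                   rs_codec(60, inner_parity = 2, outer_n = 20,
                            outer_k = 15),
                   fountain_codec(60, epsilon = 0.3))) {
    enc <- codec_encode(cdc, payload)
    mangled <- oligobench:::with_seed(1,
      inject_errors(enc$pool$sequences, error_spec(0.2)))
    mangled <- mangled[nchar(mangled) > 0]
    cs <- consensus_set(mangled, L = 60)
    res <- codec_decode(cdc, cs, enc$meta)
    if (res$status == "success") {
      expect_identical(res$payload, payload$data)
    } else {
      expect_true(TRUE)
    }
  }
})

test_that("external adapter reproduces the in-process codec and fails safely", {
  payload <- generate_payload(32, seed = 8)
  cdc <- baseline_codec(40)
  enc <- codec_encode(cdc, payload)
  lib <- .libPaths()[1]
  rscript <- file.path(R.home("bin"), "Rscript")
  dec_cmd <- sprintf(
    paste0("%s -e '.libPaths(\"%s\"); library(oligobench);",
           "pool <- read_pool_fasta(\"{in}\");",
           "res <- codec_decode(baseline_codec(40), pool,",
           " list(codec=\"baseline\", count=%d, idx_width=1L, chunk=9L,",
           " payload_size=%d, crc32=%.0f));",
           "stopifnot(res$status == \"success\");",
           "write_payload(res$payload, \"{out}\")'"),
    rscript, lib, enc$meta$count, enc$meta$payload_size, enc$meta$crc32)
  adapter <- external_codec_adapter("true", dec_cmd, timeout_s = 60)
  res <- codec_decode(adapter, enc$pool, enc$meta)
  expect_equal(res$status, "success")
  expect_identical(res$payload, payload$data)
  # nonzero exit -> failure
  bad <- external_codec_adapter("true", "false", timeout_s = 10)
  expect_equal(codec_decode(bad, enc$pool, enc$meta)$status, "failure")
  # exceeding the time limit -> failure with timeout diagnostic
  slow <- external_codec_adapter("true", "sleep 5", timeout_s = 1)
  res2 <- codec_decode(slow, enc$pool, enc$meta)
  expect_equal(res2$status, "failure")
  expect_match(res2$diagnostics$reason, "timeout|exit")
})
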