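test_that("payload generation is seeded, sized, and uniform-ish", {
  expect_error(generate_payload(0), "positive")
  p <- generate_payload(19456, seed = 1)
  expect_s3_class(p, "payload")
  expect_identical(p$size_bytes, 19456L)
  expect_identical(p$size_bytes, length(p$data))
  # determinism per seed
  expect_identical(generate_payload(1, seed = 7)$data,
                   generate_payload(1, seed = 7)$data)
  # different seeds give nearly disjoint byte strings: per-position
  # collision probability is 1/256, so matches ~ Binomial(1000, 1/256);
  # fewer than 100 differences has probability ~ 1e-300
  a <- generate_payload(1000, seed = 1)$data
  b <- generate_payload(1000, seed = 2)$data
  expect_gt(sum(a != b), 900)
})

test_that("payload files round-trip bit-exactly", {
  p <- generate_payload(513, seed = 3)
  f <- withr::local_tempfile(fileext = ".bin")
  write_payload(p, f)
  expect_identical(read_payload(f)$data, p$data)
})

test_that("crc32 matches the reference test vector", {
  expect_equal(crc32(charToRaw("123456789")), 3421780262)
  expect_equal(crc32(raw(0)), 0)
})

test_that("reference pools enforce their invariants", {
  expect_error(reference_pool(c("ACGT", "ACG")), "design length")
  expect_error(reference_pool(c("ACGT", "ACGN")), "outside")
  expect_error(reference_pool(c("ACGT", "ACGA"), ids = c("a", "a")),
               "unique")
  pool <- reference_pool(c("ACGT", "TTTT"), payload_size = 2L)
  expect_equal(pool_code_rate(pool), 8 * 2 / (2 * 4))
})

test_that("FASTA round-trips pools and rejects malformed input", {
  pool <- random_pool(3, 30, seed = 2)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_pool_fasta(pool, f)
  back <- read_pool_fasta(f)
  expect_identical(back$sequences, pool$sequences)
  expect_identical(back$ids, pool$ids)
  # strict alphabet: N is a format error naming the record
  writeLines(c(">rec1", "ACGTN"), f)
  expect_error(read_pool_fasta(f), "rec1")
  expect_silent(read_pool_fasta(f, iupac = TRUE))
  # an empty file is a format error, not an empty pool
  writeLines(character(0), f)
  expect_error(read_pool_fasta(f), "no records")
})

test_that("FASTQ round-trips reads, origins, and multiplicities", {
  rs <- read_set(c("ACGTACGTAA", "TTGTACGTAA"), origins = c(3L, NA),
                 abundance = c(3L, 1L), pool_size = 5L)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(rs, f)
  # abundance 3 expands into three records with distinct ids
  lines <- readLines(f)
  expect_equal(length(lines), 4 * 4)
  ids <- sub("\\s.*", "", lines[seq(1, 16, 4)])
  expect_equal(anyDuplicated(ids), 0L)
  back <- read_reads_fastq(f)
  expect_equal(sort(back$sequences),
               sort(rep(rs$sequences, rs$abundance)))
  expect_equal(back$origins[back$sequences == "ACGTACGTAA"], rep(3L, 3))
  expect_equal(back$pool_size, 5L)
  # mismatched sequence/quality lengths are a format error
  writeLines(c("@r1", "ACGT", "+", "III"), f)
  expect_error(read_reads_fastq(f), "mismatched")
})

test_that("stage seeds are deterministic and distinct", {
  expect_identical(derive_seed(1, "channel"), derive_seed(1, "channel"))
  expect_false(derive_seed(1, "channel") == derive_seed(1, "cluster"))
  expect_false(derive_seed(1, "channel") == derive_seed(2, "channel"))
  expect_lt(derive_seed(123456, "x"), 2^31)
})
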