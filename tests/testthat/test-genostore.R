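# Sparse/dense record codecs and the .sgen container.

test_that("sparse difflist codec round-trips and enforces its layout", {
  set.seed(11)
  # 5 bytes per entry, deterministic
  r1 <- sparse_record(400000, 7, 1L)
  expect_identical(length(encode_sparse(r1)), 5L)
  expect_identical(encode_sparse(r1), encode_sparse(r1))
  expect_identical(length(encode_sparse(sparse_record(50))), 0L)

  # random round-trips across sizes, with and without missing codes
  for (i in 1:25) {
    n <- sample(c(5, 100, 5000, 3e6), 1)
    k <- sample.int(min(n, 200), 1)
    r <- random_record(n, k, p_missing = 0.2)
    expect_identical(length(encode_sparse(r)), 5L * k)
    r2 <- decode_sparse(encode_sparse(r), n)
    expect_equal(r2$sample_index, r$sample_index)
    expect_identical(r2$value, r$value)
  }

  # hand-packed bytes: (index 0, hom-alt) among 4 samples
  r3 <- decode_sparse(as.raw(c(0, 0, 0, 0, 2)), 4)
  expect_equal(r3$sample_index, 0)
  expect_identical(r3$value, 2L)
  expect_identical(densify(r3), c(2L, 0L, 0L, 0L))

  # 4-byte little-endian index layout, checked against by-hand packing
  r4 <- sparse_record(2^25, 0x01020304, 1L)
  expect_identical(encode_sparse(r4), as.raw(c(0x04, 0x03, 0x02, 0x01, 0x01)))

  # corruption and invariant violations
  expect_error(decode_sparse(as.raw(1:7), 10), "divisible by 5")
  bad_order <- as.raw(c(5, 0, 0, 0, 1, 2, 0, 0, 0, 1)) # indices 5 then 2
  expect_error(decode_sparse(bad_order, 10), "strictly increasing")
  expect_error(decode_sparse(as.raw(c(3, 0, 0, 0, 0)), 10), "zero genotype")
  expect_error(decode_sparse(as.raw(c(9, 0, 0, 0, 1)), 8), "out of range")
  expect_error(sparse_record(10, c(1, 1), c(1L, 2L)), "strictly increasing")
  expect_error(encode_sparse(sparse_record(2^40, 2^33, 1L)), "4-byte")
})

test_that("dense 2-bit codec packs four samples per byte and round-trips", {
  expect_identical(length(encode_dense(rep(0L, 400000))), 100000L)
  expect_identical(length(encode_dense(0L)), 1L)
  set.seed(12)
  for (n in c(1, 3, 4, 5, 37, 1000)) {
    codes <- sample(0:3, n, replace = TRUE)
    bytes <- encode_dense(codes)
    expect_identical(length(bytes), as.integer(ceiling(n / 4)))
    expect_identical(decode_dense(bytes, n), as.integer(codes))
  }
  # sample 0 sits in the lowest-order bit pair of byte 0
  expect_identical(encode_dense(c(3L, 0L, 0L, 0L)), as.raw(0x03))
  expect_identical(encode_dense(c(0L, 0L, 0L, 1L)), as.raw(0x40))
  # NA maps to the missing code
  expect_identical(decode_dense(encode_dense(c(NA, 2L)), 2), c(3L, 2L))
})

test_that("encoding choice takes sparse exactly when strictly smaller", {
  expect_identical(choose_encoding(1, 400000), "SPARSE")
  expect_identical(choose_encoding(1, 20), "DENSE")     # 5 >= 5 tie
  expect_identical(choose_encoding(20000, 400000), "DENSE") # 100000 >= 100000
  expect_identical(choose_encoding(19999, 400000), "SPARSE")
})

test_that("fileset write/read round-trips genotypes and obeys the size law", {
  set.seed(13)
  n <- 123
  m <- 60
  g <- random_geno_matrix(n, m, maf = 0.05, miss = 0.03)
  g[, 1] <- 0L                        # all-reference variant
  g[, 2] <- rbinom(n, 2L, 0.5)        # common variant, stored dense
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_sgen(g, prefix)
  fs <- sgen_open(prefix)
  expect_equal(fs$n_samples, n)
  expect_equal(fs$n_variants, m)
  got <- sgen_genotypes(fs)
  dimnames(got) <- NULL
  expect_identical(got, g)

  # all-reference variant is sparse with k = 0; common variant dense
  expect_equal(fs$directory$type[1], 1L)
  expect_equal(fs$directory$length[1], 0)
  expect_equal(fs$directory$type[2], 0L)

  # size law: file = 18-byte header + 4m directory + sum of body lengths
  ks <- colSums(g != 0L)
  expected_body <- sum(ifelse(5 * ks < ceiling(n / 4), 5 * ks, ceiling(n / 4)))
  expect_equal(file.size(paste0(prefix, ".sgen")),
               18 + 4 * m + expected_body)
  expect_equal(sum(fs$directory$length), expected_body)
  # never larger than all-dense
  expect_lte(expected_body, m * ceiling(n / 4))

  # forced dense storage holds the same genotypes
  write_sgen(g, paste0(prefix, "_fd"), force_dense = TRUE)
  fd <- sgen_open(paste0(prefix, "_fd"))
  expect_identical(unname(sgen_genotypes(fd)), g)
  expect_true(all(fd$directory$type == 0L))
})

test_that("iteration streams sparse records without densification", {
  set.seed(14)
  n <- 1000
  g <- random_geno_matrix(n, 20, maf = 0.003)
  prefix <- file.path(withr::local_tempdir(), "it")
  write_sgen(g, prefix)
  fs <- sgen_open(prefix)

  it <- iter_variants(fs, "as_stored")
  seen <- 0L
  while (it$has_next()) {
    x <- it$next_record()
    seen <- seen + 1L
    expect_identical(x$index, seen)
    if (fs$directory$type[seen] == 1L) {
      expect_s3_class(x$record, "sparse_record")
      expect_identical(densify(x$record), g[, seen])
    }
    expect_identical(sgen_record(fs, seen, "force_dense"), g[, seen])
  }
  expect_identical(seen, 20L)

  # zero-variant fileset yields an empty stream
  prefix0 <- file.path(withr::local_tempdir(), "empty")
  write_sgen(matrix(0L, 8, 0), prefix0)
  fs0 <- sgen_open(prefix0)
  expect_equal(fs0$n_variants, 0)
  expect_false(iter_variants(fs0)$has_next())
})

test_that("corrupt filesets are rejected", {
  set.seed(15)
  prefix <- file.path(withr::local_tempdir(), "bad")
  write_sgen(random_geno_matrix(40, 5), prefix)
  raw_all <- readBin(paste0(prefix, ".sgen"), "raw", file.size(paste0(prefix, ".sgen")))
  writeBin(raw_all[-length(raw_all)], paste0(prefix, ".sgen")) # truncate body
  expect_error(sgen_open(prefix), "directory lengths")
  raw_all[1] <- as.raw(0xff)
  writeBin(raw_all, paste0(prefix, ".sgen"))
  expect_error(sgen_open(prefix), "magic")
})

test_that("BED import reproduces genotypes exactly, including missing", {
  set.seed(16)
  n <- 77
  m <- 40
  g <- random_geno_matrix(n, m, maf = 0.1, miss = 0.05)
  g[, 1] <- 0L
  dir <- withr::local_tempdir()
  write_bed(g, file.path(dir, "plink"))
  fs <- import_bed(file.path(dir, "plink"), file.path(dir, "conv"))
  expect_identical(unname(sgen_genotypes(fs)), g)
  expect_equal(fs$directory$type[1], 1L) # all-reference -> sparse, k=0
  expect_equal(fs$directory$length[1], 0)

  # independent check of the PLINK-1 bit patterns: one variant, 4 samples,
  # codes (hom-A1, missing, het, hom-A2) = internal (2, 3, 1, 0); crumbs
  # 00 01 10 11 little-endian within the byte -> 0xE4.
  con <- file(file.path(dir, "hand.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xE4)), con)
  close(con)
  writeLines(sprintf("F%d\tI%d\t0\t0\t0\t-9", 1:4, 1:4), file.path(dir, "hand.fam"))
  writeLines("1\trs1\t0\t100\tA\tG", file.path(dir, "hand.bim"))
  fs2 <- import_bed(file.path(dir, "hand"), file.path(dir, "hand_conv"))
  expect_identical(as.vector(sgen_genotypes(fs2)), c(2L, 3L, 1L, 0L))

  # format errors
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0xE4)), file.path(dir, "hand.bed"))
  expect_error(import_bed(file.path(dir, "hand"), file.path(dir, "x")), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), file.path(dir, "hand.bed"))
  expect_error(import_bed(file.path(dir, "hand"), file.path(dir, "x")), "BED body")
})
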