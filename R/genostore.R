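# Binary genotype container: sparse difflist + packed 2-bit dense records.
#
# Genotype codes are additive alternate-allele counts for diploid biallelic
# variants: 0, 1, 2, with 3 as the missing sentinel (never conflated with 0).
# A rare variant is stored as an ordered difflist of (sample index, code)
# pairs covering every sample whose code is nonzero (carriers and missing);
# a common variant is stored as a packed array of n 2-bit codes.

#' Missing-genotype sentinel code
#'
#' Genotypes are coded 0/1/2 alternate-allele copies; `GENO_MISSING` (3) marks
#' an unobserved genotype in both the sparse and dense encodings.
#' @export
GENO_MISSING <- 3L

REC_DENSE <- 0L
REC_SPARSE <- 1L
SGEN_MAGIC <- as.raw(c(0x53, 0x47)) # "SG"

#' Construct a sparse variant record
#'
#' A sparse (difflist) record lists every sample whose genotype code is
#' nonzero, as an ordered sequence of (0-based sample index, code) pairs.
#' Codes are 1 (het), 2 (hom-alt) or [GENO_MISSING]; code 0 never appears
#' because absence from the list means homozygous reference.
#'
#' @param n_samples Total number of samples the variant covers.
#' @param sample_index 0-based sample indices, strictly increasing.
#' @param value Genotype codes in `{1, 2, 3}`, one per index.
#' @return An object of class `sparse_record` with fields `n_samples`,
#'   `sample_index`, `value` and carrier count `k = length(sample_index)`.
#' @export
sparse_record <- function(n_samples, sample_index = integer(), value = integer()) {
  if (length(n_samples) != 1L || n_samples < 1) {
    stop("n_samples must be a single positive integer")
  }
  sample_index <- as.numeric(sample_index)
  value <- as.integer(value)
  if (length(sample_index) != length(value)) {
    stop("sample_index and value must have equal length")
  }
  if (length(sample_index)) {
    if (any(diff(sample_index) <= 0)) {
      stop("sparse record indices must be strictly increasing")
    }
    if (sample_index[1L] < 0 || sample_index[length(sample_index)] >= n_samples) {
      stop("sparse record index out of range [0, n_samples)")
    }
    if (any(value < 1L | value > 3L)) {
      stop("sparse record values must be in {1, 2, 3}; zero entries are implicit")
    }
  }
  structure(
    list(
      n_samples = as.numeric(n_samples),
      sample_index = sample_index,
      value = value,
      k = length(sample_index)
    ),
    class = "sparse_record"
  )
}

#' @export
print.sparse_record <- function(x, ...) {
  cat(
    "sparse_record: k =", x$k, "of n =", format(x$n_samples, big.mark = ","),
    "samples;", sum(x$value == GENO_MISSING), "missing\n"
  )
  invisible(x)
}

#' Expand a sparse record to a dense code vector
#'
#' @param record A [sparse_record].
#' @return Integer vector of length `n_samples` with codes in `{0,1,2,3}`.
#' @export
densify <- function(record) {
  stopifnot(inherits(record, "sparse_record"))
  g <- integer(record$n_samples)
  g[record$sample_index + 1L] <- record$value
  g
}

#' Build a sparse record from a dense code vector
#'
#' `NA` entries are treated as missing genotypes (code 3).
#'
#' @param codes Integer codes in `{0,1,2,3}` or `NA`.
#' @return A [sparse_record].
#' @export
sparsify <- function(codes) {
  codes <- as.integer(codes)
  codes[is.na(codes)] <- GENO_MISSING
  if (any(codes < 0L | codes > 3L)) stop("genotype codes must be in {0,1,2,3} or NA")
  nz <- which(codes != 0L)
  sparse_record(length(codes), nz - 1L, codes[nz])
}

#' Convert stored codes to a numeric genotype dosage vector
#'
#' Maps the missing sentinel to `NA`, leaving 0/1/2 allele counts numeric --
#' the form the regression engines consume.
#'
#' @param codes Integer codes in `{0,1,2,3}`.
#' @return Numeric vector with `NA` for missing genotypes.
#' @export
codes_to_numeric <- function(codes) {
  g <- as.numeric(codes)
  g[codes == GENO_MISSING] <- NA_real_
  g
}

# ---- record codecs ----------------------------------------------------------

#' Encode a sparse record as a difflist byte body
#'
#' Each entry costs 5 bytes: a 4-byte little-endian unsigned sample index
#' followed by a 1-byte genotype code, so a singleton carrier among any number
#' of samples occupies 5 body bytes.
#'
#' @param record A [sparse_record].
#' @return A raw vector of exactly `5 * k` bytes.
#' @export
encode_sparse <- function(record) {
  stopifnot(inherits(record, "sparse_record"))
  if (record$k == 0L) return(raw(0))
  i <- record$sample_index
  if (any(i >= 2^32)) stop("sample index >= 2^32 is not representable in a 4-byte field")
  body <- rbind(
    i %% 256,
    (i %/% 256) %% 256,
    (i %/% 65536) %% 256,
    (i %/% 16777216) %% 256,
    record$value
  )
  as.raw(as.vector(body))
}

#' Decode a difflist byte body into a sparse record
#'
#' Inverse of [encode_sparse]. Validates the difflist invariants and raises a
#' corrupt-record error on non-monotone or out-of-range indices or a zero
#' value code.
#'
#' @param bytes Raw vector, length divisible by 5.
#' @param n_samples Number of samples the record covers.
#' @return A [sparse_record].
#' @export
decode_sparse <- function(bytes, n_samples) {
  if (length(bytes) %% 5L != 0L) {
    stop("corrupt sparse record: body length ", length(bytes), " not divisible by 5")
  }
  if (length(bytes) == 0L) return(sparse_record(n_samples))
  m <- matrix(as.integer(bytes), nrow = 5L)
  idx <- m[1L, ] + 256 * m[2L, ] + 65536 * m[3L, ] + 16777216 * as.numeric(m[4L, ])
  val <- m[5L, ]
  if (any(val == 0L)) stop("corrupt sparse record: explicit zero genotype value")
  if (any(val > 3L)) stop("corrupt sparse record: genotype code > 3")
  if (any(diff(idx) <= 0)) stop("corrupt sparse record: indices not strictly increasing")
  if (idx[length(idx)] >= n_samples) stop("corrupt sparse record: index out of range")
  sparse_record(n_samples, idx, val)
}

#' Encode dense genotype codes as a packed 2-bit array
#'
#' Sample 0 occupies the lowest-order bit pair of byte 0 (PLINK-1 bit order);
#' the packed length is `ceiling(n_samples / 4)` bytes. Codes are stored
#' as-is (0/1/2 counts, 3 missing); `NA` input is mapped to 3.
#'
#' @param codes Integer codes in `{0,1,2,3}` or `NA`.
#' @return Raw vector of `ceiling(length(codes)/4)` bytes.
#' @export
encode_dense <- function(codes) {
  codes <- as.integer(codes)
  codes[is.na(codes)] <- GENO_MISSING
  if (length(codes) == 0L) stop("cannot encode a zero-sample record")
  if (any(codes < 0L | codes > 3L)) stop("genotype codes must be in {0,1,2,3} or NA")
  pad <- (-length(codes)) %% 4L
  cm <- matrix(c(codes, integer(pad)), nrow = 4L)
  as.raw(cm[1L, ] + 4L * cm[2L, ] + 16L * cm[3L, ] + 64L * cm[4L, ])
}

#' Decode a packed 2-bit array into genotype codes
#'
#' @param bytes Raw vector as produced by [encode_dense].
#' @param n_samples Number of samples (trailing padding crumbs are dropped).
#' @return Integer vector of codes in `{0,1,2,3}`.
#' @export
decode_dense <- function(bytes, n_samples) {
  if (length(bytes) != ceiling(n_samples / 4)) {
    stop("corrupt dense record: expected ", ceiling(n_samples / 4),
         " bytes, got ", length(bytes))
  }
  b <- as.integer(bytes)
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
  as.integer(codes[seq_len(n_samples)])
}

#' Choose the smaller record encoding for a variant
#'
#' Sparse wins exactly when its body (`5 * k` bytes) is strictly smaller than
#' the packed 2-bit body (`ceiling(n/4)` bytes); ties go dense.
#'
#' @param k Number of nonzero (carrier or missing) entries.
#' @param n_samples Sample count.
#' @return `"SPARSE"` or `"DENSE"`.
#' @export
choose_encoding <- function(k, n_samples) {
  if (5 * k < ceiling(n_samples / 4)) "SPARSE" else "DENSE"
}

# ---- .sgen fileset ----------------------------------------------------------

# Layout of PREFIX.sgen:
#   bytes 0-1    magic "SG"
#   bytes 2-9    n_variants, unsigned 64-bit little-endian
#   bytes 10-17  n_samples,  unsigned 64-bit little-endian
#   directory    n_variants * 4 bytes: 1 record-type byte (0 dense, 1 sparse;
#                higher values reserved) + 3-byte little-endian record length
#   bodies       concatenated record bodies, directory order
# Sample and variant metadata live in sidecar text files PREFIX.ssam (FAM
# dialect) and PREFIX.svar (BIM dialect).

u64_le <- function(x) as.raw(floor(x / 256^(0:7)) %% 256)
u64_from_le <- function(bytes) sum(as.integer(bytes) * 256^(0:7))

dir_entry <- function(type, len) {
  if (len >= 2^24) stop("record body of ", len, " bytes exceeds the 3-byte length field")
  as.raw(c(type, len %% 256, (len %/% 256) %% 256, len %/% 65536))
}

default_variant_meta <- function(m) {
  data.frame(
    chrom = rep("1", m), id = sprintf("var%d", seq_len(m)), cm = rep(0, m),
    pos = seq_len(m), alt = rep("A", m), ref = rep("C", m),
    stringsAsFactors = FALSE
  )
}

default_sample_meta <- function(n) {
  data.frame(
    fid = sprintf("F%06d", seq_len(n)), iid = sprintf("S%06d", seq_len(n)),
    pat = rep("0", n), mat = rep("0", n), sex = rep("0", n),
    pheno = rep("-9", n), stringsAsFactors = FALSE
  )
}

#' Write a sparse genotype fileset
#'
#' Writes `PREFIX.sgen` (binary records), `PREFIX.svar` (variant metadata,
#' BIM dialect: chrom, id, cM, pos, alt, ref) and `PREFIX.ssam` (sample
#' metadata, FAM dialect). Each variant is stored sparse or dense per
#' [choose_encoding] unless `force_dense` is set.
#'
#' @param geno Either an `n x m` integer matrix of codes (`NA` allowed for
#'   missing) or a list of `m` [sparse_record] objects sharing one
#'   `n_samples`.
#' @param prefix Output path prefix.
#' @param variants Optional variant metadata data frame (columns chrom, id,
#'   cm, pos, alt, ref); defaults are generated.
#' @param samples Optional sample metadata data frame (columns fid, iid, pat,
#'   mat, sex, pheno); defaults are generated.
#' @param force_dense Store every record dense regardless of size.
#' @return The prefix, invisibly.
#' @export
write_sgen <- function(geno, prefix, variants = NULL, samples = NULL,
                       force_dense = FALSE) {
  if (is.matrix(geno)) {
    n <- nrow(geno)
    records <- lapply(seq_len(ncol(geno)), function(j) sparsify(geno[, j]))
  } else {
    records <- geno
    if (!length(records) && is.null(samples)) {
      stop("writing a zero-variant fileset requires sample metadata for n")
    }
    n <- if (length(records)) records[[1L]]$n_samples else nrow(samples)
  }
  m <- length(records)
  if (is.null(variants)) variants <- default_variant_meta(m)
  if (is.null(samples)) samples <- default_sample_meta(n)
  stopifnot(nrow(variants) == m, nrow(samples) == n)

  dir_parts <- vector("list", m)
  body_parts <- vector("list", m)
  for (j in seq_len(m)) {
    r <- records[[j]]
    stopifnot(inherits(r, "sparse_record"), r$n_samples == n)
    enc <- if (force_dense) "DENSE" else choose_encoding(r$k, n)
    body <- if (enc == "SPARSE") encode_sparse(r) else encode_dense(densify(r))
    dir_parts[[j]] <- dir_entry(if (enc == "SPARSE") REC_SPARSE else REC_DENSE, length(body))
    body_parts[[j]] <- body
  }

  con <- file(paste0(prefix, ".sgen"), "wb")
  on.exit(close(con))
  writeBin(SGEN_MAGIC, con)
  writeBin(u64_le(m), con)
  writeBin(u64_le(n), con)
  writeBin(as.raw(unlist(dir_parts, use.names = FALSE)), con)
  writeBin(as.raw(unlist(body_parts, use.names = FALSE)), con)

  utils::write.table(variants, paste0(prefix, ".svar"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(samples, paste0(prefix, ".ssam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Open a sparse genotype fileset
#'
#' Parses the header and per-variant directory, validates that directory
#' record lengths exactly tile the body region, and loads the sidecar
#' metadata.
#'
#' @param prefix Path prefix of a fileset written by [write_sgen].
#' @return An object of class `sgen_fileset` with fields `n_samples`,
#'   `n_variants`, `directory` (type, length, offset per variant),
#'   `variants`, `samples`.
#' @export
sgen_open <- function(prefix) {
  path <- paste0(prefix, ".sgen")
  if (!file.exists(path)) stop("no such fileset: ", path)
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) < 18L || !identical(raw_all[1:2], SGEN_MAGIC)) {
    stop("bad magic: not an .sgen file: ", path)
  }
  m <- u64_from_le(raw_all[3:10])
  n <- u64_from_le(raw_all[11:18])
  dir_end <- 18L + 4L * m
  if (length(raw_all) < dir_end) stop("corrupt .sgen: truncated directory")
  if (m > 0L) {
    dirm <- matrix(as.integer(raw_all[18L + seq_len(4L * m)]), nrow = 4L)
    type <- dirm[1L, ]
    len <- dirm[2L, ] + 256 * dirm[3L, ] + 65536 * dirm[4L, ]
  } else {
    type <- integer(0)
    len <- numeric(0)
  }
  if (any(!type %in% c(REC_DENSE, REC_SPARSE))) {
    stop("corrupt .sgen: unknown record type (reserved types are not supported)")
  }
  body <- raw_all[-seq_len(dir_end)]
  if (sum(len) != length(body)) {
    stop("corrupt .sgen: directory lengths sum to ", sum(len),
         " but body region has ", length(body), " bytes")
  }
  offset <- c(0, cumsum(len))[seq_len(max(m, 1L))]
  if (m == 0L) offset <- numeric(0)

  variants <- if (m > 0L) {
    utils::read.table(paste0(prefix, ".svar"), header = FALSE,
                      col.names = c("chrom", "id", "cm", "pos", "alt", "ref"),
                      colClasses = c("character", "character", "numeric",
                                     "integer", "character", "character"))
  } else {
    data.frame(chrom = character(), id = character(), cm = numeric(),
               pos = integer(), alt = character(), ref = character())
  }
  samples <- utils::read.table(paste0(prefix, ".ssam"), header = FALSE,
                               col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                               colClasses = "character")
  if (nrow(samples) != n) stop(".ssam sample count disagrees with .sgen header")
  if (nrow(variants) != m) stop(".svar variant count disagrees with .sgen header")

  structure(
    list(
      prefix = prefix, n_samples = n, n_variants = m,
      directory = data.frame(type = type, length = len, offset = offset),
      body = body, variants = variants, samples = samples
    ),
    class = "sgen_fileset"
  )
}

#' @export
print.sgen_fileset <- function(x, ...) {
  cat("sgen_fileset:", x$n_variants, "variants x", x$n_samples, "samples;",
      sum(x$directory$type == REC_SPARSE), "sparse,",
      sum(x$directory$type == REC_DENSE), "dense\n")
  invisible(x)
}

#' Fetch one variant record from a fileset
#'
#' @param fs An [sgen_open] fileset.
#' @param j 1-based variant index.
#' @param mode `"as_stored"` yields a [sparse_record] for sparse-stored
#'   variants (no densification) and an integer code vector for dense-stored
#'   ones; `"force_dense"` always yields the integer code vector.
#' @return A [sparse_record] or integer code vector.
#' @export
sgen_record <- function(fs, j, mode = c("as_stored", "force_dense")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fs, "sgen_fileset"), j >= 1L, j <= fs$n_variants)
  d <- fs$directory[j, ]
  bytes <- fs$body[seq_len(d$length) + d$offset]
  if (d$type == REC_SPARSE) {
    rec <- decode_sparse(bytes, fs$n_samples)
    if (mode == "force_dense") densify(rec) else rec
  } else {
    decode_dense(bytes, fs$n_samples)
  }
}

#' Iterate over variant records
#'
#' Returns a closure-based iterator streaming records in directory order;
#' sparse-stored variants are yielded without densification in `"as_stored"`
#' mode.
#'
#' @inheritParams sgen_record
#' @return A list with functions `has_next()` and `next_record()`; the latter
#'   returns `list(index, id, record)`.
#' @export
iter_variants <- function(fs, mode = c("as_stored", "force_dense")) {
  mode <- match.arg(mode)
  j <- 0L
  list(
    has_next = function() j < fs$n_variants,
    next_record = function() {
      if (j >= fs$n_variants) stop("iterator exhausted")
      j <<- j + 1L
      list(index = j, id = fs$variants$id[j], record = sgen_record(fs, j, mode))
    }
  )
}

#' Materialize the full genotype code matrix of a fileset
#'
#' Convenience for tests and small cohorts; codes are `{0,1,2,3}`.
#'
#' @param fs An [sgen_open] fileset.
#' @return `n_samples x n_variants` integer matrix.
#' @export
sgen_genotypes <- function(fs) {
  out <- matrix(0L, fs$n_samples, fs$n_variants)
  for (j in seq_len(fs$n_variants)) out[, j] <- sgen_record(fs, j, "force_dense")
  out
}

# ---- PLINK 1 BED import/export ---------------------------------------------

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01)) # SNP-major

# PLINK 1 crumb -> internal code: 00 hom A1 (counted allele) = 2, 01 missing,
# 10 het, 11 hom A2 = 0.
PLINK1_TO_CODE <- c(2L, 3L, 1L, 0L)
CODE_TO_PLINK1 <- c(3L, 2L, 0L, 1L)

read_fam <- function(path) {
  utils::read.table(path, header = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                    colClasses = "character")
}

read_bim <- function(path) {
  utils::read.table(path, header = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "alt", "ref"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
}

#' Import a PLINK 1 binary fileset into the sparse container
#'
#' Reads a SNP-major BED with its BIM/FAM sidecars, translates PLINK's 2-bit
#' patterns (01 = missing) to internal codes, and re-encodes every variant
#' per [choose_encoding]. Genotypes, including missing ones, are preserved
#' exactly; sample order follows the FAM file and variant order the BIM file.
#'
#' @param bed_prefix Path prefix of the `.bed`/`.bim`/`.fam` trio.
#' @param out_prefix Output prefix for the `.sgen` fileset.
#' @param force_dense Store all records dense.
#' @return The opened [sgen_open] fileset.
#' @export
import_bed <- function(bed_prefix, out_prefix, force_dense = FALSE) {
  bed_path <- paste0(bed_prefix, ".bed")
  fam <- read_fam(paste0(bed_prefix, ".fam"))
  bim <- read_bim(paste0(bed_prefix, ".bim"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw_all <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw_all) < 3L || !identical(raw_all[1:3], BED_MAGIC)) {
    stop("bad magic: not a SNP-major PLINK 1 BED file: ", bed_path)
  }
  bpv <- ceiling(n / 4)
  if (length(raw_all) - 3L != bpv * m) {
    stop("BED body has ", length(raw_all) - 3L, " bytes but FAM/BIM imply ",
         bpv * m, " (", n, " samples x ", m, " variants)")
  }
  records <- vector("list", m)
  for (j in seq_len(m)) {
    bytes <- raw_all[3L + (j - 1L) * bpv + seq_len(bpv)]
    plink_codes <- decode_dense(bytes, n) # same crumb order, different code map
    records[[j]] <- sparsify(PLINK1_TO_CODE[plink_codes + 1L])
  }
  write_sgen(records, out_prefix, variants = bim, samples = fam,
             force_dense = force_dense)
  sgen_open(out_prefix)
}

#' Write a PLINK 1 BED/BIM/FAM fileset
#'
#' Counterpart of [import_bed], mainly for generating test inputs and
#' exporting synthetic cohorts to PLINK-consumable form.
#'
#' @param geno `n x m` integer code matrix (`NA` or 3 = missing).
#' @param prefix Output prefix.
#' @param variants,samples Optional metadata as in [write_sgen].
#' @return The prefix, invisibly.
#' @export
write_bed <- function(geno, prefix, variants = NULL, samples = NULL) {
  n <- nrow(geno)
  m <- ncol(geno)
  if (is.null(variants)) variants <- default_variant_meta(m)
  if (is.null(samples)) samples <- default_sample_meta(n)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  for (j in seq_len(m)) {
    codes <- geno[, j]
    codes[is.na(codes)] <- GENO_MISSING
    writeBin(encode_dense(CODE_TO_PLINK1[codes + 1L]), con)
  }
  utils::write.table(variants, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(samples, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
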