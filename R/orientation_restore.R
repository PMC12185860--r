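# Losslessness machinery: reverse complement, order-invariant dataset
# digest, binary restore table, exact input reconstruction, and the
# closed-form overhead arithmetic.

IUPAC_FROM <- "ACGTUMRWSYKVHDBNacgtumrwsykvhdbn"
IUPAC_TO   <- "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn"

#' Reverse complement of DNA sequences
#'
#' Vectorised, case-preserving reverse complement over the full IUPAC
#' alphabet (`U` complements to `A`).  Characters outside the alphabet pass
#' through unchanged (complemented to themselves), with a single warning
#' per session.  `reverse_complement()` is an involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param seqs Character vector of sequences.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement(c("AACG", "acgTN"))
#' @export
reverse_complement <- function(seqs) {
  if (length(seqs) == 0L) return(character(0))
  if (isTRUE(is.null(the$warned_non_iupac)) || !isTRUE(the$warned_non_iupac)) {
    if (any(grepl(paste0("[^", IUPAC_FROM, "]"), seqs))) {
      warn("sequence contains non-IUPAC characters; they pass through reverse_complement unchanged")
      the$warned_non_iupac <- TRUE
    }
  }
  stringi::stri_reverse(chartr(IUPAC_FROM, IUPAC_TO, seqs))
}

#' Canonical (strand-invariant) form of DNA sequences
#'
#' Uppercases each sequence and returns the lexicographically smaller of it
#' and its reverse complement, so that a read and its reverse complement map
#' to the same representative:
#' `canonical_form(s) == canonical_form(reverse_complement(s))`.
#'
#' @param seqs Character vector of sequences.
#' @return Character vector of canonical forms.
#' @export
canonical_form <- function(seqs) {
  u <- toupper(seqs)
  rc <- reverse_complement(u)
  ifelse(u <= rc, u, rc)
}

#' Order-invariant digest of a read set
#'
#' Integrity check for reordering: each record's sequence is hashed with
#' 128-bit MD5 and the per-record hashes are combined by addition modulo
#' 2^128.  Because addition commutes, the digest is invariant under any
#' permutation of the records; with `canonical = TRUE` sequences are first
#' replaced by their [canonical_form()], making the digest also invariant
#' under reverse complementing any record (the right check when strand
#' unification is allowed to change orientations).
#'
#' Headers and quality strings are excluded and sequences are uppercased
#' before hashing, so the digest certifies "same sequences" regardless of
#' softmasking; set `strict = TRUE` to hash the full raw
#' `(id, desc, seq, qual)` tuple instead.
#'
#' @param x Tibble of records (see [read_seqs()]).
#' @param canonical Hash canonical forms instead of raw orientations.
#' @param strict Hash full records byte-for-byte (implies `canonical` is
#'   ignored); detects any field change but is not strand-invariant.
#' @return A `dataset_digest`: list with `digest` (32-char hex string),
#'   `canonical`, `strict`, `n_records`.
#' @export
dataset_digest <- function(x, canonical = FALSE, strict = FALSE) {
  material <- if (strict) {
    paste(x$id, x$desc %||% "", x$seq,
          ifelse(is.na(x$qual %||% NA_character_), "", x$qual),
          sep = "\x1f")
  } else if (canonical) {
    canonical_form(x$seq)
  } else {
    toupper(x$seq)
  }
  digest_hex <- if (length(material) == 0L) {
    strrep("0", 32L)
  } else {
    hashes <- vapply(openssl::md5(material), as.character, character(1))
    sum_mod_2_128(hashes)
  }
  structure(list(digest = digest_hex, canonical = canonical,
                 strict = strict, n_records = nrow(x)),
            class = "dataset_digest")
}

# sum of 128-bit values given as 32-char hex strings, modulo 2^128
sum_mod_2_128 <- function(hex) {
  mat <- vapply(seq(1L, 31L, by = 2L), function(i) {
    strtoi(substr(hex, i, i + 1L), base = 16L)
  }, integer(length(hex)))
  if (length(hex) == 1L) mat <- matrix(mat, nrow = 1L)
  sums <- colSums(mat)  # byte 1 is most significant
  carry <- 0
  out <- integer(16L)
  for (i in 16:1) {
    v <- sums[[i]] + carry
    out[[i]] <- v %% 256
    carry <- v %/% 256
  }
  paste(sprintf("%02x", out), collapse = "")
}

#' @export
print.dataset_digest <- function(x, ...) {
  cat("<dataset_digest> ", x$digest,
      if (x$strict) " (strict)" else if (x$canonical) " (canonical)" else "",
      "  [", x$n_records, " record(s)]\n", sep = "")
  invisible(x)
}

#' @export
format.dataset_digest <- function(x, ...) x$digest

new_restore_table <- function(original_index, flipped, mode) {
  stopifnot(length(original_index) == length(flipped))
  structure(list(n_reads = length(original_index),
                 original_index = as.double(original_index),
                 flipped = as.logical(flipped),
                 mode = mode),
            class = "restore_table")
}

#' @export
print.restore_table <- function(x, ...) {
  cat("<restore_table> ", x$n_reads, " read(s), mode ", x$mode,
      ", ", sum(x$flipped), " flipped\n", sep = "")
  invisible(x)
}

#' Tidy a restore table into one row per output read
#'
#' @param x A `restore_table`.
#' @param ... Unused.
#' @return A tibble with `output_index` (0-based position in the reordered
#'   file), `original_index` (0-based position in the input file) and
#'   `flipped`.
#' @method tidy restore_table
#' @export
tidy.restore_table <- function(x, ...) {
  tibble(output_index = seq_len(x$n_reads) - 1,
         original_index = x$original_index,
         flipped = x$flipped)
}

RESTORE_MAGIC <- charToRaw("RELOREST")
RESTORE_VERSION <- 1L
MODE_LEVELS <- c("unify", "preserve", "ignore")

#' Serialize a restore table to its binary sidecar format
#'
#' Fixed layout: 8 magic bytes, 1 version byte, 1 strand-mode byte, 8-byte
#' little-endian read count, then one little-endian 32-bit original index
#' per output read, then the orientation bits packed LSB-first into
#' `ceiling(n/8)` bytes — i.e. `18 + 4n + ceiling(n/8)` bytes total,
#' matching the per-read cost of one 32-bit integer plus one bit.
#'
#' @param table A `restore_table` (from [apply_plan()] or [run_sort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restore_table <- function(table, path) {
  stopifnot(inherits(table, "restore_table"))
  n <- table$n_reads
  if (n > 0 && max(table$original_index) >= 2^32) {
    abort("restore table indices exceed 32 bits", class = "relo_io_error")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(RESTORE_MAGIC, con)
  writeBin(as.raw(RESTORE_VERSION), con)
  writeBin(as.raw(match(table$mode, MODE_LEVELS)), con)
  writeBin(double_to_le8(n), con)
  if (n > 0) {
    idx <- table$original_index
    idx <- ifelse(idx >= 2^31, idx - 2^32, idx)  # reinterpret as signed
    writeBin(as.integer(idx), con, size = 4L, endian = "little")
    pad <- (8L - n %% 8L) %% 8L
    writeBin(packBits(c(table$flipped, rep(FALSE, pad)), type = "raw"), con)
  }
  invisible(path)
}

double_to_le8 <- function(n) {
  out <- raw(8L)
  for (i in 1:8) {
    out[[i]] <- as.raw(n %% 256)
    n <- n %/% 256
  }
  out
}

le8_to_double <- function(bytes) {
  sum(as.double(as.integer(bytes)) * 256^(0:7))
}

#' Load a restore table, validating layout and permutation
#'
#' Rejects bad magic/version bytes, a read count inconsistent with the file
#' size, and any index block whose values are not exactly the permutation
#' `0..n-1` — so a corrupted file fails loudly instead of silently
#' misordering reads.
#'
#' @param path Path written by [write_restore_table()].
#' @return A `restore_table`.
#' @export
read_restore_table <- function(path) {
  size <- file.size(path)
  if (is.na(size) || size < 18) {
    abort(paste0(path, ": not a restore table (file too short)"),
          class = "relo_restore_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", size)
  if (!identical(raw[1:8], RESTORE_MAGIC)) {
    abort(paste0(path, ": bad magic bytes"), class = "relo_restore_error")
  }
  if (as.integer(raw[[9L]]) != RESTORE_VERSION) {
    abort(paste0(path, ": unsupported restore-table version ",
                 as.integer(raw[[9L]])), class = "relo_restore_error")
  }
  mode_byte <- as.integer(raw[[10L]])
  if (mode_byte < 1L || mode_byte > length(MODE_LEVELS)) {
    abort(paste0(path, ": invalid strand-mode byte ", mode_byte),
          class = "relo_restore_error")
  }
  n <- le8_to_double(raw[11:18])
  expected <- 18 + 4 * n + ceiling(n / 8)
  if (size != expected) {
    abort(paste0(path, ": file size ", size, " does not match the ", n,
                 "-read layout (expected ", expected, " bytes)"),
          class = "relo_restore_error")
  }
  if (n == 0) {
    return(new_restore_table(double(), logical(), MODE_LEVELS[[mode_byte]]))
  }
  idx <- readBin(raw[19:(18 + 4 * n)], "integer", n = n, size = 4L,
                 endian = "little")
  idx <- as.double(idx)
  idx <- ifelse(idx < 0, idx + 2^32, idx)
  if (any(idx >= n) || anyDuplicated(idx)) {
    abort(paste0(path, ": index block is not a permutation of 0..n-1 ",
                 "(corrupt restore table)"),
          class = "relo_restore_error")
  }
  bits <- rawToBits(raw[(19 + 4 * n):length(raw)])
  flipped <- as.logical(bits[seq_len(n)])
  mode <- MODE_LEVELS[[mode_byte]]
  if (mode != "unify" && any(flipped)) {
    abort(paste0(path, ": orientation bits set under mode '", mode,
                 "' (corrupt restore table)"),
          class = "relo_restore_error")
  }
  new_restore_table(idx, flipped, mode)
}

#' Reconstruct the original read file from a reordered one
#'
#' Applies a restore table to a reordered record set: record `i` is sent
#' back to input position `original_index[i]`, reverse-complemented (with
#' its quality string re-reversed) where its orientation bit is set.  The
#' result is field-for-field identical to the pre-sort input.
#'
#' @param x Reordered records (tibble, see [read_seqs()]).
#' @param table Matching `restore_table`.
#' @return Tibble of records in original input order.
#' @export
restore_input <- function(x, table) {
  stopifnot(inherits(table, "restore_table"))
  if (nrow(x) != table$n_reads) {
    abort(paste0("record count (", nrow(x), ") != restore table n_reads (",
                 table$n_reads, ")"), class = "relo_restore_error")
  }
  if (any(table$flipped)) {
    flip <- table$flipped
    x$seq[flip] <- reverse_complement(x$seq[flip])
    if ("qual" %in% names(x)) {
      has_q <- flip & !is.na(x$qual)
      x$qual[has_q] <- stringi::stri_reverse(x$qual[has_q])
    }
  }
  x[order(table$original_index), , drop = FALSE]
}

#' Closed-form size of the order/orientation sidecar
#'
#' Storing the original position of each of `n` reads as a fixed-width
#' integer plus an optional per-read flag costs
#' `n * (bits_per_position + bits_per_flag) / 8` bytes (rounded up to a
#' whole byte).  With 32-bit positions, 10 million reads cost 40 MB
#' (decimal) — small next to the multi-gigabase files they index.
#'
#' @param n_reads Number of reads.
#' @param bits_per_position Bits per stored position (default 32).
#' @param bits_per_flag Bits per orientation flag (default 1; use 0 when
#'   orientation is untouched).
#' @return Size in bytes.
#' @examples
#' position_overhead_bytes(1e7, 32, 0) # 40 MB decimal
#' @export
position_overhead_bytes <- function(n_reads, bits_per_position = 32L,
                                    bits_per_flag = 1L) {
  stopifnot(n_reads >= 0, bits_per_position >= 0, bits_per_flag >= 0)
  ceiling(n_reads * (bits_per_position + bits_per_flag) / 8)
}
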