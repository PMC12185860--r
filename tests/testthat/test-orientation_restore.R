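test_that("reverse complement handles IUPAC codes, case, and palindromes", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AACG"), "CGTT")
  expect_equal(reverse_complement("acgTN"), "NAcgt")
  expect_equal(reverse_complement("RYSWKM"), "KMWSRY")
  expect_equal(reverse_complement(character(0)), character(0))
})

test_that("reverse complement is a length-preserving involution", {
  x <- random_records(300L, seed = 41L)
  rc <- reverse_complement(x$seq)
  expect_equal(nchar(rc), nchar(x$seq))
  expect_identical(reverse_complement(rc), x$seq)
})

test_that("canonical form is strand-invariant and picks the smaller string", {
  expect_equal(canonical_form("TTTT"), "AAAA")
  expect_equal(canonical_form("ACGT"), "ACGT")
  x <- random_records(1000L, seed = 43L)
  expect_identical(canonical_form(x$seq),
                   canonical_form(reverse_complement(x$seq)))
  expect_identical(canonical_form(x$seq), canonical_form(toupper(x$seq)))
})

test_that("the dataset digest is order-invariant and strand-aware as configured", {
  x <- random_records(120L, seed = 47L, fastq = TRUE)
  d0 <- dataset_digest(x)
  expect_match(d0$digest, "^[0-9a-f]{32}$")
  expect_identical(dataset_digest(shuffle_reads(x, 5L))$digest, d0$digest)
  expect_identical(dataset_digest(shuffle_reads(x, 6L))$digest, d0$digest)

  flipped <- x
  flipped$seq <- reverse_complement(flipped$seq)
  expect_identical(dataset_digest(flipped, canonical = TRUE)$digest,
                   dataset_digest(x, canonical = TRUE)$digest)

  # non-canonical: flipping one non-palindromic record changes the digest
  toy <- tibble::tibble(id = c("a", "b", "c"), desc = "",
                        seq = c("AAC", "GGT", "CCA"),
                        qual = NA_character_)
  toy2 <- toy
  toy2$seq[1L] <- reverse_complement(toy2$seq[1L])
  expect_false(identical(dataset_digest(toy2)$digest,
                         dataset_digest(toy)$digest))

  # quality and headers are excluded from the sequence digest
  requal <- x
  requal$qual <- rev(x$qual)
  requal$desc <- "changed"
  expect_identical(dataset_digest(requal)$digest, d0$digest)
  expect_false(identical(dataset_digest(requal, strict = TRUE)$digest,
                         dataset_digest(x, strict = TRUE)$digest))
})

test_that("digest of the empty set is the additive identity", {
  empty <- tibble::tibble(id = character(), desc = character(),
                          seq = character(), qual = character())
  expect_equal(dataset_digest(empty)$digest, strrep("0", 32L))
})

test_that("restore tables round-trip bit-exactly with the documented layout", {
  withr::with_seed(53L, {
    for (n in sample(0:5000, 20L)) {
      idx <- sample(n) - 1
      flips <- runif(n) < 0.3
      tab <- relo:::new_restore_table(idx, flips, "unify")
      path <- withr::local_tempfile()
      write_restore_table(tab, path)
      expect_equal(file.size(path), 18 + 4 * n + ceiling(n / 8))
      back <- read_restore_table(path)
      expect_equal(back$original_index, idx)
      expect_equal(back$flipped, flips)
      expect_equal(back$mode, "unify")
    }
  })
})

test_that("corrupting one byte of the index block is detected at load", {
  n <- 64L
  tab <- relo:::new_restore_table(sample(n) - 1, rep(FALSE, n), "preserve")
  path <- withr::local_tempfile()
  write_restore_table(tab, path)
  withr::with_seed(59L, {
    for (rep in 1:20) {
      raw <- readBin(path, "raw", file.size(path))
      at <- sample(19:(18L + 4L * n), 1L)
      orig <- raw[[at]]
      raw[[at]] <- as.raw(bitwXor(as.integer(orig),
                                  as.integer(sample(1:255, 1L))))
      bad <- withr::local_tempfile()
      writeBin(raw, bad)
      expect_error(read_restore_table(bad), class = "relo_restore_error")
    }
  })
  # header corruption is caught too
  raw <- readBin(path, "raw", file.size(path))
  raw[[1L]] <- as.raw(0L)
  writeBin(raw, path)
  expect_error(read_restore_table(path), "magic",
               class = "relo_restore_error")
})

test_that("truncated or mode-inconsistent tables are rejected", {
  tab <- relo:::new_restore_table(c(1, 0), c(TRUE, FALSE), "unify")
  path <- withr::local_tempfile()
  write_restore_table(tab, path)
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[-length(raw)], path)
  expect_error(read_restore_table(path), "size",
               class = "relo_restore_error")
  # flip bits under a non-unify mode marker are inconsistent
  raw[[10L]] <- as.raw(2L)  # preserve
  writeBin(raw, path)
  expect_error(read_restore_table(path), "orientation",
               class = "relo_restore_error")
})

test_that("restore_input inverts reordering and flips exactly", {
  x <- random_records(50L, seed = 61L, fastq = TRUE)
  perm <- withr::with_seed(62L, sample(50L))
  flips <- withr::with_seed(63L, runif(50L) < 0.5)
  reordered <- x[perm, ]
  reordered$seq[flips] <- reverse_complement(reordered$seq[flips])
  reordered$qual[flips] <- stringi::stri_reverse(reordered$qual[flips])
  tab <- relo:::new_restore_table(perm - 1, flips, "unify")
  expect_equal(restore_input(reordered, tab), x, ignore_attr = TRUE)

  # identity table, no flips
  id_tab <- relo:::new_restore_table(0:49, rep(FALSE, 50L), "ignore")
  expect_equal(restore_input(x, id_tab), x, ignore_attr = TRUE)

  # single flipped read
  one <- tibble::tibble(id = "r", desc = "", seq = "AACG",
                        qual = NA_character_)
  one_tab <- relo:::new_restore_table(0, TRUE, "unify")
  expect_equal(restore_input(one, one_tab)$seq, "CGTT")

  expect_error(restore_input(x[1:10, ], tab), "n_reads",
               class = "relo_restore_error")
})

test_that("position overhead follows the closed form", {
  expect_equal(position_overhead_bytes(1e7, 32, 0), 4e7)  # 40 MB decimal
  expect_equal(position_overhead_bytes(0), 0)
  expect_equal(position_overhead_bytes(1e7, 0, 1), 1250000)
  expect_equal(position_overhead_bytes(3, 32, 1), ceiling(3 * 33 / 8))
})
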