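test_that("simulated genomes are deterministic in the seed and carry repeats", {
  cfg <- sim_config(genome_length = 1000L, n_repeats = 0L, seed = 1L)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nchar(g1), 1000L)
  expect_true(grepl("^[ACGT]+$", g1))

  g3 <- simulate_genome(sim_config(genome_length = 1000L, seed = 2L))
  expect_false(identical(g1, g3))  # different seed, different sequence

  cfg_rep <- sim_config(genome_length = 5000L, n_repeats = 2L,
                        repeat_length = 100L, seed = 3L)
  gr <- simulate_genome(cfg_rep)
  # the planted motif occurs at least twice as an exact substring
  hits <- vapply(seq_len(nchar(gr) - 99L),
                 function(i) substr(gr, i, i + 99L), character(1))
  expect_true(any(table(hits) >= 2L))
})

test_that("read sampling hits the coverage target and respects the error model", {
  cfg <- sim_config(genome_length = 20000L, coverage = 10,
                    mean_read_length = 1000L, seed = 5L)
  genome <- simulate_genome(cfg)
  rs <- sample_reads(genome, cfg)
  total <- sum(nchar(rs$reads$seq))
  expect_gte(total, 10 * 20000)
  expect_lt(total, 10 * 20000 + max(nchar(rs$reads$seq)))
  expect_equal(nrow(rs$reads), nrow(rs$truth))
  expect_equal(rs$truth$true_end - rs$truth$true_start,
               nchar(rs$reads$seq))  # error-free: lengths match truth

  # '+' reads are exact substrings of the genome; '-' reads of its revcomp
  plus <- rs$truth$true_strand == "+"
  expect_true(all(mapply(function(s, a, b) {
    identical(s, substr(genome, a + 1, b))
  }, rs$reads$seq[plus], rs$truth$true_start[plus],
     rs$truth$true_end[plus])))
  minus <- which(!plus)[1:5]
  expect_true(all(mapply(function(s, a, b) {
    identical(reverse_complement(s), substr(genome, a + 1, b))
  }, rs$reads$seq[minus], rs$truth$true_start[minus],
     rs$truth$true_end[minus])))
})

test_that("substitution-only errors diverge at about the configured rate", {
  cfg <- sim_config(genome_length = 50000L, coverage = 2,
                    mean_read_length = 5000L, read_length_sd = 0,
                    sub_rate = 0.05, seed = 7L)
  genome <- simulate_genome(cfg)
  rs <- sample_reads(genome, cfg)
  # no indels, so reads align positionally to their truth interval
  mism <- mapply(function(s, a, b, strand) {
    ref <- substr(genome, a + 1, b)
    obs <- if (strand == "-") reverse_complement(s) else s
    rv <- strsplit(ref, "")[[1L]]
    ov <- strsplit(obs, "")[[1L]]
    mean(rv != ov)
  }, rs$reads$seq, rs$truth$true_start, rs$truth$true_end,
     rs$truth$true_strand)
  expect_gt(mean(mism), 0.04)
  expect_lt(mean(mism), 0.06)
})

test_that("truth intervals tile the genome densely at high coverage", {
  cfg <- sim_config(genome_length = 50000L, coverage = 20, seed = 11L)
  genome <- simulate_genome(cfg)
  rs <- sample_reads(genome, cfg)
  starts <- sort(rs$truth$true_start)
  # generous bound: with ~1000 reads on 50 kb, max gap far below 2 kb
  expect_lt(max(diff(starts)), 2000)
  expect_lt(starts[1L], 2000)
})

test_that("truth assemblies cut the genome into linked overlapping windows", {
  cfg <- sim_config(genome_length = 8000L, seed = 13L)
  genome <- simulate_genome(cfg)

  one <- build_truth_assembly(genome, 1L)
  expect_equal(one$contigs$seq, genome)
  expect_equal(nrow(one$graph$links), 0L)

  ta <- build_truth_assembly(genome, 4L, link_overlap = 100L)
  expect_equal(nrow(ta$graph$segments), 4L)
  expect_equal(nrow(ta$graph$links), 3L)
  expect_true(all(ta$graph$links$from_orient == "+"))
  # windows reconstruct the genome and overlap by the stated amount
  for (i in 1:3) {
    expect_equal(
      substr(ta$contigs$seq[i], nchar(ta$contigs$seq[i]) - 99L,
             nchar(ta$contigs$seq[i])),
      substr(ta$contigs$seq[i + 1], 1L, 100L))
  }
  # DFS over the path graph recovers genomic order
  ord <- dfs_order(ta$graph)
  expect_equal(ord$contig_id, ta$contigs$id)
  expect_equal(ord$orient, rep("+", 4L))
})

test_that("branching truth assembly gives one segment two successors", {
  genome <- simulate_genome(sim_config(genome_length = 3000L, seed = 17L))
  ta <- build_truth_assembly(genome, 3L, branching = TRUE)
  expect_equal(ta$graph$links$from, c("ctg001", "ctg001"))
  ord <- dfs_order(ta$graph)
  expect_equal(ord$contig_id[1L], "ctg001")
  expect_setequal(ord$contig_id, c("ctg001", "ctg002", "ctg003"))
})

test_that("truth PAF maps reads to covering contigs with exact withholding", {
  cfg <- sim_config(genome_length = 30000L, coverage = 5, seed = 19L)
  genome <- simulate_genome(cfg)
  rs <- sample_reads(genome, cfg)
  ta <- build_truth_assembly(genome, 3L)

  paf <- emit_truth_paf(rs$truth, ta$contigs)
  expect_equal(nrow(paf), nrow(rs$truth))        # 0% withheld: all present
  expect_equal(anyDuplicated(paf$read_id), 0L)   # each read exactly once
  off <- ta$contigs$offset[match(paf$contig_id, ta$contigs$id)]
  expect_equal(paf$t_start, rs$truth$true_start - off)
  expect_true(all(paf$t_start >= 0 & paf$t_start < paf$contig_len))

  n <- nrow(rs$truth)
  paf10 <- emit_truth_paf(rs$truth, ta$contigs, withhold_frac = 0.1,
                          seed = 42L)
  expect_equal(nrow(paf10), n - round(0.1 * n))
})

test_that("shuffling preserves the record multiset and is seed-reproducible", {
  x <- random_records(1000L, seed = 23L)
  expect_identical(shuffle_reads(x[1, ], seed = 1L), x[1, ])
  s1 <- shuffle_reads(x, seed = 9L)
  s2 <- shuffle_reads(x, seed = 9L)
  expect_identical(s1, s2)
  expect_setequal(s1$id, x$id)
  # Kendall-tau-positive: the permutation moves things (rank correlation < 1)
  expect_gt(sum(match(s1$id, x$id) != seq_len(1000L)), 900L)
})

test_that("the simulate writer emits a consistent file bundle", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(genome_length = 10000L, coverage = 5, seed = 29L)
  sim <- write_simulation(cfg, dir, n_contigs = 2L, withhold_frac = 0.1)
  expect_true(all(file.exists(unlist(sim$paths))))
  reads <- read_seqs(sim$paths$reads)
  expect_equal(nrow(reads), nrow(sim$truth))
  paf <- parse_paf(sim$paths$paf)
  expect_equal(nrow(paf), nrow(sim$mappings))
  g <- parse_gfa(sim$paths$gfa)
  expect_equal(nrow(g$segments), 2L)
})
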