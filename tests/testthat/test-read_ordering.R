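test_that("mappings sort by contig rank then start position then read id", {
  m <- dplyr::bind_rows(
    toy_mapping("r1", "u2", "+", 50),
    toy_mapping("r2", "u1", "+", 10),
    toy_mapping("r3", "u1", "+", 5)
  )
  s <- sort_mappings(m, toy_order(c("u1", "u2")))
  expect_equal(s$read_id, c("r3", "r2", "r1"))
  expect_equal(sort_mappings(m[0, ], toy_order("u1"))$read_id, character(0))
})

test_that("preserve mode groups the '+' strand block before the '-' block", {
  m <- dplyr::bind_rows(
    toy_mapping("r1", "u1", "-", 5),
    toy_mapping("r2", "u1", "+", 50)
  )
  s <- sort_mappings(m, toy_order("u1"), mode = "preserve")
  expect_equal(s$read_id, c("r2", "r1"))
  # unify mode sorts the same rows purely by position
  expect_equal(sort_mappings(m, toy_order("u1"), mode = "unify")$read_id,
               c("r1", "r2"))
})

test_that("reverse-traversed contigs sort by descending end and flip strands", {
  m <- dplyr::bind_rows(
    toy_mapping("early", "u1", "+", 10, t_end = 110),
    toy_mapping("late", "u1", "-", 700, t_end = 800)
  )
  s <- sort_mappings(m, toy_order("u1", orient = "-"))
  expect_equal(s$read_id, c("late", "early"))   # block read right-to-left
  expect_equal(s$eff_strand, c("+", "-"))       # strands flipped
  s_off <- sort_mappings(m, toy_order("u1", orient = "-"),
                         block_flip = FALSE)
  expect_equal(s_off$read_id, c("early", "late"))
  expect_equal(s_off$eff_strand, c("+", "-"))
})

test_that("mappings to contigs missing from the order are dropped with a warning", {
  m <- dplyr::bind_rows(toy_mapping("r1", "u1", "+", 5),
                        toy_mapping("r2", "phantom", "+", 5))
  expect_warning(s <- sort_mappings(m, toy_order("u1")), "phantom")
  expect_equal(s$read_id, "r1")
  plan <- plan_placement(s, c("r1", "r2"))
  expect_equal(plan$unmapped_ids, "r2")  # dropped mapping -> unmapped tail
})

test_that("each read places once, at its first encounter along the order", {
  m <- dplyr::bind_rows(
    toy_mapping("r1", "u1", "+", 10),
    toy_mapping("r1", "u3", "+", 4),
    toy_mapping("r2", "u3", "+", 0)
  )
  s <- sort_mappings(m, toy_order(c("u1", "u3")))
  plan <- plan_placement(s, c("r1", "r2"))
  expect_equal(plan$placed$read_id, c("r1", "r2"))
  expect_equal(plan$placed$contig_id, c("u1", "u3"))  # first encounter wins
  expect_equal(plan$unmapped_ids, character(0))
})

test_that("best-mapping dedup picks the maximum-match mapping instead", {
  m <- dplyr::bind_rows(
    toy_mapping("r1", "u1", "+", 10, n_match = 50),
    toy_mapping("r1", "u3", "+", 4, n_match = 95),
    toy_mapping("r2", "u1", "+", 20, n_match = 60)
  )
  s <- sort_mappings(m, toy_order(c("u1", "u3")))
  plan <- plan_placement(s, c("r1", "r2"), best_mapping = TRUE)
  expect_equal(plan$placed$read_id, c("r2", "r1"))
  expect_equal(plan$placed$contig_id, c("u1", "u3"))
})

test_that("unmapped reads append in input order; unify flags '-' reads", {
  m <- toy_mapping("r2", "u1", "-", 50)
  s <- sort_mappings(m, toy_order("u1"))
  plan <- plan_placement(s, c("r1", "r2", "r3"), mode = "unify")
  expect_equal(plan$placed$read_id, "r2")
  expect_true(plan$placed$emit_rc)
  expect_equal(plan$unmapped_ids, c("r1", "r3"))

  for (mode in c("preserve", "ignore")) {
    p <- plan_placement(sort_mappings(m, toy_order("u1"), mode = mode),
                        c("r1", "r2", "r3"), mode = mode)
    expect_false(any(p$placed$emit_rc))
  }
})

test_that("mappings naming unknown reads are a PAF/FASTA mismatch error", {
  s <- sort_mappings(toy_mapping("ghost", "u1", "+", 5), toy_order("u1"))
  expect_error(plan_placement(s, c("r1", "r2")), "ghost",
               class = "relo_plan_error")
})

test_that("apply_plan reorders, reverse-complements flagged reads, and logs restore rows", {
  x <- tibble::tibble(id = c("r1", "r2"), desc = "",
                      seq = c("AACG", "TTGG"),
                      qual = c("IIAB", "FFFF"))
  m <- toy_mapping("r1", "u1", "-", 50)
  plan <- plan_placement(sort_mappings(m, toy_order("u1")), x$id,
                         mode = "unify")
  res <- apply_plan(x, plan)
  expect_equal(res$records$id, c("r1", "r2"))
  expect_equal(res$records$seq[1L], "CGTT")   # revcomp of AACG
  expect_equal(res$records$qual[1L], "BAII")  # quality reversed in step
  expect_equal(res$restore$original_index, c(0, 1))
  expect_equal(res$restore$flipped, c(TRUE, FALSE))

  # identity plan leaves the records untouched
  id_plan <- plan_placement(
    sort_mappings(toy_mapping(character(0), character(0), character(0),
                              double(0)), toy_order("u1")), x$id)
  expect_equal(apply_plan(x, id_plan)$records, x)
})

test_that("apply_plan rejects id mismatches in either direction", {
  x <- tibble::tibble(id = "only", desc = "", seq = "AC",
                      qual = NA_character_)
  plan <- plan_placement(
    sort_mappings(toy_mapping("only", "u1", "+", 1), toy_order("u1")),
    c("only", "extra"))
  expect_error(apply_plan(x, plan), "extra", class = "relo_plan_error")
})

test_that("the read-id multiset survives pathological mapping inputs", {
  ids <- sprintf("p%03d", 1:60)
  x <- random_records(60L, seed = 31L)
  x$id <- ids
  # duplicates, unknown contigs, repeated positions
  m <- dplyr::bind_rows(
    toy_mapping(sample(ids, 40, replace = TRUE), "u1", "+",
                sample(0:500, 40, replace = TRUE)),
    toy_mapping(sample(ids, 10), "nowhere", "-", 5)
  )
  for (mode in c("unify", "preserve", "ignore")) {
    s <- suppressWarnings(sort_mappings(m, toy_order("u1"), mode = mode))
    plan <- plan_placement(s, ids, mode = mode)
    expect_setequal(relo:::plan_ids(plan), ids)
    res <- apply_plan(x, plan)
    expect_setequal(res$records$id, ids)
    if (mode != "unify") {
      expect_identical(sort(res$records$seq), sort(x$seq))  # no byte changed
    } else {
      expect_identical(sort(canonical_form(res$records$seq)),
                       sort(canonical_form(x$seq)))
    }
  }
})

test_that("locality score is the mean adjacent true-start distance", {
  truth <- tibble::tibble(read_id = c("a", "b", "c"),
                          true_start = c(0, 100, 200),
                          true_end = c(50, 150, 250),
                          true_strand = "+")
  expect_equal(locality_score(c("a", "b", "c"), truth), 100)
  expect_equal(locality_score(c("b", "a", "c"), truth), 150)
  expect_true(is.na(locality_score("a", truth)))
  # modular distance on circular genomes
  expect_equal(locality_score(c("a", "c"), truth, circular = TRUE,
                              genome_length = 250), 50)
})

test_that("a shuffled order scores strictly worse than the truth order", {
  cfg <- sim_config(genome_length = 30000L, coverage = 17,
                    mean_read_length = 1000L, seed = 37L)
  rs <- sample_reads(simulate_genome(cfg), cfg)
  truth_order <- rs$truth$read_id[order(rs$truth$true_start)]
  shuffled <- withr::with_seed(38L, sample(truth_order))
  expect_gt(locality_score(shuffled, rs$truth),
            locality_score(truth_order, rs$truth))
})
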