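# Programmatic fixtures: random record sets and random contig graphs.

random_records <- function(n, seed, fastq = FALSE, min_len = 5L,
                           max_len = 60L) {
  withr::with_seed(seed, {
    lens <- sample(min_len:max_len, n, replace = TRUE)
    seqs <- vapply(lens, function(l) {
      paste0(sample(c("A", "C", "G", "T", "a", "c", "g", "t", "N"), l,
                    replace = TRUE, prob = c(rep(0.12, 8), 0.04)),
             collapse = "")
    }, character(1))
    quals <- if (fastq) {
      vapply(lens, function(l) {
        paste0(sample(strsplit(rawToChar(as.raw(33:73)), "")[[1L]], l,
                      replace = TRUE), collapse = "")
      }, character(1))
    } else {
      rep(NA_character_, n)
    }
    descs <- ifelse(runif(n) < 0.5,
                    paste("len", lens, "extra info"), "")
    tibble::tibble(id = sprintf("rr%04d", seq_len(n)), desc = descs,
                   seq = seqs, qual = quals)
  })
}

# random bidirected contig graph with up to `max_segments` segments
random_graph <- function(seed, max_segments = 10L) {
  withr::with_seed(seed, {
    n <- sample(0:max_segments, 1L)
    ids <- if (n > 0) sprintf("s%02d", seq_len(n)) else character(0)
    segs <- tibble::tibble(
      id = ids,
      length = if (n > 0) sample(10:100, n, replace = TRUE) else integer(0),
      seq = rep(NA_character_, n)
    )
    m <- if (n > 0) sample(0:(2L * n), 1L) else 0L
    links <- if (m > 0) {
      tibble::tibble(
        from = sample(ids, m, replace = TRUE),
        from_orient = sample(c("+", "-"), m, replace = TRUE),
        to = sample(ids, m, replace = TRUE),
        to_orient = sample(c("+", "-"), m, replace = TRUE),
        overlap_len = sample(0:50, m, replace = TRUE)
      )
    } else {
      tibble::tibble(from = character(), from_orient = character(),
                     to = character(), to_orient = character(),
                     overlap_len = integer())
    }
    relo:::new_contig_graph(segs, links)
  })
}

# tiny worked dataset shared by placement tests
toy_order <- function(ids = c("u1", "u2"), orient = NULL) {
  structure(
    tibble::tibble(rank = seq_along(ids) - 1L, contig_id = ids,
                   orient = orient %||% rep("+", length(ids))),
    class = c("contig_order", "tbl_df", "tbl", "data.frame")
  )
}

toy_mapping <- function(read_id, contig_id, strand, t_start, t_end = NULL,
                        contig_len = 1000, n_match = NULL) {
  tibble::tibble(
    read_id = read_id,
    read_len = 100,
    strand = strand,
    contig_id = contig_id,
    contig_len = contig_len,
    t_start = t_start,
    t_end = t_end %||% (t_start + 100),
    n_match = n_match %||% 90,
    is_primary = TRUE
  )
}

`%||%` <- rlang::`%||%`
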