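# Seeded simulator: genome with planted repeats, strand-aware error-bearing
# reads, and matching truth contigs/GFA/PAF, so the whole reordering
# pipeline is testable with no external assembler or mapper.
#
# Seed discipline: every operation is a pure function of (inputs, seed).
# simulate_genome draws from cfg$seed, sample_reads from cfg$seed + 1, and
# withholding in emit_truth_paf from its own seed argument, all through
# withr::with_seed so the caller's RNG state is untouched.

DNA <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Bundles and validates the knobs of the read simulator.  Defaults emulate
#' a small HiFi-like experiment: a 100 kb genome read at 20x with ~1 kb
#' reads and no sequencing error; raise `sub_rate`/`ins_rate`/`del_rate`
#' towards 0.05–0.10 for an ONT-like error regime.
#'
#' @param genome_length Genome size in bases.
#' @param n_repeats Number of planted copies of a repeat motif.
#' @param repeat_length Length of the repeat motif (bases).
#' @param coverage Target coverage (x): reads are drawn until their total
#'   bases reach `coverage * genome_length`.
#' @param mean_read_length Median read length in bases (the lognormal's
#'   scale parameter).
#' @param read_length_sd Log-space standard deviation of the lognormal
#'   read-length distribution; lengths are clipped to
#'   `[min(200, genome_length), genome_length]`.
#' @param sub_rate,ins_rate,del_rate Per-base substitution / insertion /
#'   deletion probabilities, each in `[0, 0.2]`.
#' @param circular Treat the genome as circular (reads may wrap).
#' @param seed Integer seed; every downstream draw derives from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 100000L, n_repeats = 0L,
                       repeat_length = 500L, coverage = 20,
                       mean_read_length = 1000L, read_length_sd = 0.25,
                       sub_rate = 0, ins_rate = 0, del_rate = 0,
                       circular = FALSE, seed = 1L) {
  stopifnot(genome_length >= 1, n_repeats >= 0, repeat_length >= 1,
            coverage > 0, mean_read_length >= 1, read_length_sd >= 0,
            sub_rate >= 0, sub_rate <= 0.2,
            ins_rate >= 0, ins_rate <= 0.2,
            del_rate >= 0, del_rate <= 0.2,
            is.logical(circular), length(seed) == 1L)
  if (n_repeats * repeat_length >= genome_length / 2) {
    abort("repeat content must occupy less than half the genome",
          class = "relo_sim_error")
  }
  structure(list(genome_length = as.integer(genome_length),
                 n_repeats = as.integer(n_repeats),
                 repeat_length = as.integer(repeat_length),
                 coverage = coverage,
                 mean_read_length = as.integer(mean_read_length),
                 read_length_sd = read_length_sd,
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, circular = circular,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random genome with planted repeats
#'
#' Draws a uniform-random ACGT string and plants `n_repeats` exact copies
#' of one random motif at non-overlapping seeded-random positions
#' (repeats are what fragment real assemblies into multiple contigs).
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A single character string of length `cfg$genome_length`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    bases <- sample(DNA, cfg$genome_length, replace = TRUE)
    if (cfg$n_repeats > 0) {
      motif <- sample(DNA, cfg$repeat_length, replace = TRUE)
      starts <- place_nonoverlapping(cfg$n_repeats, cfg$repeat_length,
                                     cfg$genome_length)
      for (s in starts) {
        bases[s:(s + cfg$repeat_length - 1L)] <- motif
      }
    }
    paste0(bases, collapse = "")
  })
}

place_nonoverlapping <- function(n, width, total, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    starts <- sort(sample.int(total - width + 1L, n))
    if (n == 1L || all(diff(starts) >= width)) return(starts)
  }
  abort(paste0("could not place ", n, " non-overlapping ", width,
               "-base repeats in ", total, " bases after ", max_tries,
               " tries"), class = "relo_sim_error")
}

#' Sample error-bearing reads from a genome
#'
#' Draws reads until total bases reach `coverage * genome_length`.  Lengths
#' are lognormal (clipped), start positions uniform over positions where
#' the read fits (anywhere, with wraparound, for circular genomes), and
#' strand is Bernoulli(0.5).  Minus-strand reads are stored
#' reverse-complemented — the sequence a sequencer would emit.  Errors are
#' injected per base in a single pass (substitution, then insertion after
#' the base, then deletion) at the configured rates.  Truth coordinates are
#' always the error-free genome interval.
#'
#' Reads are emitted in passes of roughly 1x coverage, each pass sorted by
#' start position — the layout position-sorted simulators produce, stacked
#' across passes the way multi-run archives concatenate files.  The raw
#' file therefore carries *partial* locality: much worse than a
#' position-perfect ordering, much better than a shuffle, which is the
#' regime where reordering is measurable.  Use [shuffle_reads()] for a
#' locality-free baseline.
#'
#' @param genome Genome string from [simulate_genome()].
#' @param cfg The same [sim_config()].
#' @return A list with `reads` (record tibble, see [read_seqs()]) and
#'   `truth` (tibble `read_id`, `true_start`, `true_end` 0-based half-open,
#'   `true_strand`).
#' @export
sample_reads <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  glen <- nchar(genome)
  target <- cfg$coverage * glen
  min_len <- min(200L, glen)
  withr::with_seed(cfg$seed + 1L, {
    starts <- integer(0); lens <- integer(0); strands <- character(0)
    total <- 0
    while (total < target) {
      # one ~1x pass, emitted sorted by start position
      pass_target <- min(glen, target - total)
      p_starts <- integer(0); p_lens <- integer(0)
      p_strands <- character(0); p_total <- 0
      while (p_total < pass_target) {
        k <- max(16L, ceiling((pass_target - p_total) / cfg$mean_read_length))
        len <- as.integer(round(rlnorm(k, log(cfg$mean_read_length),
                                       cfg$read_length_sd)))
        len <- pmin(pmax(len, min_len), glen)
        start <- if (cfg$circular) {
          sample.int(glen, k, replace = TRUE)
        } else {
          # uniform over placements where the read fits
          1L + as.integer(floor(runif(k) * (glen - len + 1L)))
        }
        strand <- ifelse(runif(k) < 0.5, "+", "-")
        # keep reads while the running total is still below target, so the
        # read crossing the threshold is included and sampling stops there
        keep <- which((cumsum(len) - len) < (pass_target - p_total))
        p_starts <- c(p_starts, start[keep]); p_lens <- c(p_lens, len[keep])
        p_strands <- c(p_strands, strand[keep])
        p_total <- p_total + sum(len[keep])
      }
      ord <- order(p_starts, p_lens)
      starts <- c(starts, p_starts[ord]); lens <- c(lens, p_lens[ord])
      strands <- c(strands, p_strands[ord])
      total <- total + p_total
    }
    n <- length(starts)
    raw <- extract_interval(genome, starts, lens, cfg$circular)
    emitted <- ifelse(strands == "-", reverse_complement(raw), raw)
    if (cfg$sub_rate > 0 || cfg$ins_rate > 0 || cfg$del_rate > 0) {
      emitted <- vapply(emitted, inject_errors, character(1),
                        sub_rate = cfg$sub_rate, ins_rate = cfg$ins_rate,
                        del_rate = cfg$del_rate, USE.NAMES = FALSE)
    }
    ids <- sprintf("read%06d", seq_len(n))
    list(
      reads = tibble(id = ids, desc = "", seq = emitted,
                     qual = NA_character_),
      truth = tibble(read_id = ids,
                     true_start = as.double(starts - 1L),
                     true_end = as.double(starts - 1L + lens),
                     true_strand = strands)
    )
  })
}

extract_interval <- function(genome, starts, lens, circular) {
  glen <- nchar(genome)
  ends <- starts + lens - 1L
  if (!circular) return(substring(genome, starts, ends))
  wrap <- ends > glen
  out <- character(length(starts))
  out[!wrap] <- substring(genome, starts[!wrap], ends[!wrap])
  if (any(wrap)) {
    out[wrap] <- paste0(substring(genome, starts[wrap], glen),
                        substring(genome, 1L, ends[wrap] - glen))
  }
  out
}

# single pass over the read: substitute, then insert after the base, then
# delete the (possibly substituted) base
inject_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(v)
  sub_at <- runif(n) < sub_rate
  if (any(sub_at)) {
    v[sub_at] <- vapply(v[sub_at],
                        function(b) sample(setdiff(DNA, toupper(b)), 1L),
                        character(1), USE.NAMES = FALSE)
  }
  ins_at <- runif(n) < ins_rate
  del_at <- runif(n) < del_rate
  kept <- ifelse(del_at, "", v)
  inserted <- ifelse(ins_at, sample(DNA, n, replace = TRUE), "")
  paste0(paste0(kept, inserted), collapse = "")
}

#' Cut a genome into an overlapping-window truth assembly
#'
#' Splits the genome into `n_contigs` consecutive windows overlapping by
#' `link_overlap` bases and links them head-to-tail with `+/+` GFA links —
#' a stand-in for the draft contigs an assembler would produce, with known
#' genomic offsets.  `branching = TRUE` (requires `n_contigs == 3`) instead
#' links the first window to both others (A→B, A→C), the shape used to
#' exercise DFS backtracking.
#'
#' @param genome Genome string.
#' @param n_contigs Number of windows (>= 1).
#' @param link_overlap Overlap between consecutive windows (bases).
#' @param circular Add a closing link from the last window to the first.
#' @param branching Emit the 3-segment branching variant instead of a path.
#' @return List with `contigs` (tibble `id`, `seq`, `offset` — 0-based
#'   genomic start of each window) and `graph` (a `contig_graph`).
#' @export
build_truth_assembly <- function(genome, n_contigs, link_overlap = 0L,
                                 circular = FALSE, branching = FALSE) {
  glen <- nchar(genome)
  stopifnot(n_contigs >= 1, link_overlap >= 0)
  if (branching && n_contigs != 3L) {
    abort("branching truth assembly requires exactly 3 contigs",
          class = "relo_sim_error")
  }
  width <- ceiling((glen + (n_contigs - 1) * link_overlap) / n_contigs)
  if (width <= link_overlap) {
    abort(paste0("cannot cut ", glen, " bases into ", n_contigs,
                 " windows overlapping by ", link_overlap),
          class = "relo_sim_error")
  }
  offsets <- (seq_len(n_contigs) - 1L) * (width - link_overlap)
  starts <- offsets + 1L
  ends <- pmin(starts + width - 1L, glen)
  ids <- sprintf("ctg%03d", seq_len(n_contigs))
  contigs <- tibble(id = ids,
                    seq = substring(genome, starts, ends),
                    offset = as.double(offsets))
  segs <- tibble(id = ids, length = nchar(contigs$seq), seq = contigs$seq)
  links <- if (branching) {
    tibble(from = ids[c(1L, 1L)], from_orient = "+",
           to = ids[c(2L, 3L)], to_orient = "+",
           overlap_len = as.integer(link_overlap))
  } else if (n_contigs > 1L) {
    tibble(from = ids[-n_contigs], from_orient = "+",
           to = ids[-1L], to_orient = "+",
           overlap_len = as.integer(link_overlap))
  } else {
    tibble(from = character(), from_orient = character(),
           to = character(), to_orient = character(),
           overlap_len = integer())
  }
  if (circular && n_contigs > 1L && !branching) {
    links <- bind_rows(links,
                       tibble(from = ids[n_contigs], from_orient = "+",
                              to = ids[1L], to_orient = "+",
                              overlap_len = 0L))
  }
  list(contigs = contigs, graph = new_contig_graph(segs, links))
}

#' Emit truth mappings for simulated reads
#'
#' Maps each read onto the truth contig whose window covers its true start:
#' `t_start = true_start - offset`, strand equal to the true strand, and
#' `n_match` equal to the error-free read span.  A configurable fraction of
#' reads is withheld (seeded) to exercise the unmapped-read path.
#'
#' @param truth Truth tibble from [sample_reads()].
#' @param contigs Contig tibble from [build_truth_assembly()].
#' @param withhold_frac Fraction of reads to leave out of the PAF
#'   (`round(withhold_frac * n)` reads exactly).
#' @param seed Seed for the withheld subset.
#' @return A mapping tibble in [parse_paf()] layout.
#' @export
emit_truth_paf <- function(truth, contigs, withhold_frac = 0, seed = 1L) {
  stopifnot(withhold_frac >= 0, withhold_frac < 1)
  clen <- nchar(contigs$seq)
  ctg_idx <- findInterval(truth$true_start, contigs$offset)
  stopifnot(all(ctg_idx >= 1L))
  offset <- contigs$offset[ctg_idx]
  span <- truth$true_end - truth$true_start
  t_start <- truth$true_start - offset
  t_end <- pmin(t_start + span, clen[ctg_idx])
  out <- tibble(
    read_id = truth$read_id,
    read_len = span,
    strand = truth$true_strand,
    contig_id = contigs$id[ctg_idx],
    contig_len = as.double(clen[ctg_idx]),
    t_start = t_start,
    t_end = t_end,
    n_match = span,
    is_primary = TRUE
  )
  n_out <- round(withhold_frac * nrow(out))
  if (n_out > 0) {
    drop <- withr::with_seed(seed, sample.int(nrow(out), n_out))
    out <- out[-drop, , drop = FALSE]
  }
  out
}

#' Uniformly shuffle records
#'
#' Seeded uniform permutation of the record rows — the worst-case baseline
#' order for compression comparisons.  The multiset of records is
#' unchanged.
#'
#' @param x Record tibble.
#' @param seed Integer seed.
#' @return The permuted tibble.
#' @export
shuffle_reads <- function(x, seed) {
  if (nrow(x) < 2L) return(x)
  withr::with_seed(as.integer(seed), x[sample.int(nrow(x)), , drop = FALSE])
}

#' Run the simulator and write all its artefacts
#'
#' Convenience wrapper for the `simulate` command: writes `reads.fasta`,
#' `truth.paf`, `truth.gfa`, `truth.tsv` (read id + true interval/strand)
#' and `config.json` into `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param n_contigs,link_overlap Truth-assembly shape
#'   (see [build_truth_assembly()]).
#' @param withhold_frac Fraction of reads withheld from the truth PAF.
#' @param shuffle Shuffle the reads before writing (so the file order
#'   carries no locality, as a downloaded archive might).
#' @return Invisibly, a list of the generated objects and file paths.
#' @export
write_simulation <- function(cfg, dir, n_contigs = 4L, link_overlap = 0L,
                             withhold_frac = 0, shuffle = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(cfg)
  rs <- sample_reads(genome, cfg)
  ta <- build_truth_assembly(genome, n_contigs, link_overlap,
                             circular = cfg$circular)
  paf <- emit_truth_paf(rs$truth, ta$contigs, withhold_frac,
                        seed = cfg$seed + 2L)
  reads <- if (shuffle) shuffle_reads(rs$reads, cfg$seed + 3L) else rs$reads
  paths <- list(
    reads = file.path(dir, "reads.fasta"),
    paf = file.path(dir, "truth.paf"),
    gfa = file.path(dir, "truth.gfa"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.json")
  )
  write_seqs(reads, paths$reads, format = "fasta")
  write_paf(paf, paths$paf)
  write_gfa(ta$graph, paths$gfa)
  utils::write.table(rs$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE)
  invisible(list(paths = paths, genome = genome, reads = reads,
                 truth = rs$truth, contigs = ta$contigs, graph = ta$graph,
                 mappings = paf))
}
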