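---
title: "Reordering long reads along a draft assembly: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reordering long reads along a draft assembly: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relo)
```

## The problem

A long-read sequencing file at coverage $c$ contains each genomic position
in roughly $c$ reads, so the information content per base is far below two
bits — yet gzip and friends rarely do better than four-fold on FASTA.  Two
things defeat them.  First, overlapping reads are scattered: a generic
compressor's match window (32 kB for DEFLATE, a few hundred MB for zstd
at high levels) rarely spans the distance between two reads from the same
locus.  Second, roughly half of all read pairs covering a locus are on
opposite strands; a reverse complement shares no literal substrings with
its mate, so even adjacent placement does not help until orientations are
unified.

`relo` is a *pre-compressor*: it permutes (and optionally
reverse-complements) the reads so that a downstream generic compressor
sees the redundancy, and it guarantees the permutation is invertible.  It
deliberately does not compress anything itself.

## Pipeline

The placement signal comes from a draft assembly: a contig graph (GFA1)
plus read-to-contig mappings (PAF).  Both can be supplied from files,
produced by external tools (`run_external_assembly()` wraps the
conventional minimap2 → miniasm → minimap2 chain as configurable shell
templates), or generated as ground truth by the built-in simulator.  The
assembly only needs to co-locate overlapping reads — consensus accuracy is
irrelevant, which is why a fast layout-only assembler is the intended
producer.

### Contig linearization

GFA links are bidirected: a link $a\,o_a \to b\,o_b$ also supports the
mirrored traversal $b\,\bar o_b \to a\,\bar o_a$, and `build_adjacency()`
materialises both directions on oriented nodes.  `dfs_order()` then
linearizes the graph depth-first, following each path to its end before
backtracking, which keeps chains of linked contigs — and therefore the
reads on them — contiguous in the output.  Choices the graph format does
not dictate, fixed here for determinism:

* **Roots.**  Traversal starts at oriented nodes $(s, +)$ with no incoming
  traversal edge — path ends — processed in descending segment length,
  then ascending id.  If unvisited segments remain (isolated contigs,
  components only reachable in reverse, cycles), the longest unvisited
  segment is re-rooted in `+` orientation until all are emitted.  Starting
  at path ends prevents a linear component from being entered in the
  middle and split in two.
* **Successor order.**  Descending link overlap, then descending successor
  length, then ascending id.  A larger overlap means more shared sequence
  across the junction, so the junction that compresses best is kept
  adjacent.
* **Orientation and cycles.**  A segment is emitted once, at first visit
  (the visited set is on segment ids, so cycles terminate and a segment
  later reached in the opposite orientation is not re-emitted), with the
  orientation in which it was first reached.
* **Iteration.**  The DFS uses an explicit stack; recursion depth never
  bounds graph size.  A brute-force recursive implementation with the same
  tie-breaks (`order_equivalence_oracle()`) exists purely as a test
  oracle, and the suite checks agreement on hundreds of random graphs.

### Read placement

`sort_mappings()` orders mappings by (contig rank, start position, read
id).  For a contig the DFS reached in `-` orientation, its block is read
right-to-left (descending end position) and mapping strands are flipped,
so the block stays collinear with the traversal; `block_flip = FALSE`
disables this.  `plan_placement()` scans the sorted list and emits each
read at its **first encounter** — the literal rule, even if a later
mapping has more matching bases; `best_mapping = TRUE` switches to each
read's maximum-`n_match` mapping for users who prefer that.  Reads absent
from the PAF (or whose mappings point at contigs missing from the order,
which are dropped with a warning rather than erroring) are appended at the
end in input order: unmapped reads are few in practice and ordering them
by content costs more than it saves.

Strand modes: `unify` reverse-complements reads whose effective strand is
`-` (maximum redundancy); `preserve` keeps orientations and instead groups
the `+` block before the `-` block, each position-sorted — the `+`-first
convention is arbitrary but fixed; `ignore` sorts by position only.
FASTQ quality strings are reversed (not complemented) alongside a reverse
complement.

### Losslessness

Two mechanisms make the transformation safe:

* **Restore table** (`write_restore_table()`): per output read, the
  original 0-based input index as a little-endian 32-bit integer plus one
  orientation bit, after an 18-byte header — `18 + 4n + \lceil n/8
  \rceil` bytes total.  For 10 million reads that is 40 MB of positions
  plus 1.25 MB of bits (`position_overhead_bytes()`), the $N \log N$-bit
  cost of remembering a permutation, trivial next to a 100-gigabase file.
  The 32-bit width caps input at $2^{32}$ reads; the version byte reserves
  room for a 64-bit variant.  On load, the magic, version, mode byte and
  exact file size are validated and the index block must be a permutation
  of $0..n{-}1$ — a corrupted table fails loudly, never silently
  misorders.  Entropy coding of the table is left to the user's `gzip`.
* **Dataset digest** (`dataset_digest()`): each read's sequence
  (uppercased; headers and qualities excluded) is hashed with 128-bit MD5
  and the hashes are summed modulo $2^{128}$.  Addition commutes, so the
  digest is order-invariant by construction; with `canonical = TRUE` each
  sequence is first replaced by the lexicographic minimum of itself and
  its reverse complement, making the digest strand-invariant too.
  `run_sort()` compares input and output digests (canonical exactly when
  the mode may flip reads) and deletes the output on mismatch.  Uppercasing
  keeps the check independent of softmasking; `strict = TRUE` offers a
  byte-exact digest over full records instead.  An additive combiner is
  weaker against adversarial collisions than a keyed construction, but the
  threat model is corruption, not attack.

## The simulator

The generator exists so every pipeline property is testable hermetically.
`simulate_genome()` draws a uniform ACGT genome and plants exact copies of
a repeat motif at non-overlapping positions (repeats are what fragment
real assemblies).  `sample_reads()` draws reads to a coverage target with
lognormal lengths (default: median 1 kb, log-sd 0.25, clipped below at
200 bases — a generic long-read regime), uniform starts, Bernoulli(0.5)
strand; minus-strand reads are stored reverse-complemented, as a sequencer
emits them — this is precisely what makes the strand-mode comparison
meaningful.  Errors are injected per base in one pass (substitution, then
insertion, then deletion); only the rates matter to any test, not the
error process's fine structure.  Defaults are error-free (HiFi-like);
~5–10% total error emulates noisier chemistry.

Reads are emitted in ~1× passes, each pass sorted by start position — the
layout position-sorted simulators produce, concatenated the way multi-run
archives are.  The raw file therefore has *partial* locality (mean
adjacent true-start distance around the per-pass gap), sitting strictly
between a position-perfect ordering and a shuffle.  That intermediate
regime is deliberate: it is the one in which improving on the input order
is both possible and measurable, and the test suite asserts the strict
chain reordered < input < shuffled on it.  A uniformly random emission
order would be statistically indistinguishable from the shuffled baseline
and the comparison would carry no information.

`build_truth_assembly()` cuts the genome into overlapping windows linked
head-to-tail (optionally branching, for DFS tests), and `emit_truth_paf()`
maps each read to the window covering its true start, withholding a
configurable fraction to exercise the unmapped path.  What the simulator
does *not* emulate: realistic error profiles (homopolymer bias), quality
strings, chimeric reads, adapters.  Tests passing on it demonstrate the
ordering, orientation and restore machinery — not error-robustness of any
particular mapper.

## Numerical and interface choices

* Everything tabular is a tibble; records are `(id, desc, seq, qual)`
  rows, mappings are PAF rows with 0-based half-open coordinates kept
  exactly as the format defines them.
* All operations are in-memory; at the multi-gigabase scale the original
  tool targets one would stream, but R's idiom (and the package's test and
  demonstration scale — thousands to tens of thousands of reads) is
  whole-object.  Problem sizes used by the test suite: 20× coverage of
  100 kb genomes for round-trip and locality properties (about 2 000
  reads), 50× of 50 kb for the compression-direction property, 200 random
  graphs of at most 10 segments for the DFS oracle.
* Duplicate read ids are rejected by default (placement and restore assume
  unique ids); `dup_ids = "make_unique"` suffixes them reversibly.
* Case and non-ACGT characters pass through unchanged; reverse complement
  uses the full IUPAC table, case-preserving, and unknown characters pass
  through with a one-time warning.
* Ties everywhere break deterministically (documented sort keys), so
  identical inputs give byte-identical outputs; every random draw in the
  simulator is a pure function of the seed.
* The external-tool chain is three plain shell templates with named
  placeholders, validated before execution; a missing binary or failing
  stage is an actionable error and never affects the file-driven core.

## Limitations

The quality of the ordering is bounded by the draft assembly: a
fragmented assembly yields many short runs, and reads the mapper misses
fall back to input order.  Compression gains on FASTQ are structurally
smaller because quality strings dominate and are near-incompressible;
separating and re-ordering quality streams is out of scope.  The bench
(`run_bench()`) asserts only directions on synthetic data — absolute
ratios depend on the compressor, its level, and the dataset.
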