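# relo — reference-free reordering of long reads for better compression

Long-read FASTA/FASTQ files are highly redundant — at 30× coverage every
genomic position is covered by dozens of overlapping reads — yet generic
compressors (gzip, zstd, xz) rarely beat a four-fold reduction on them.
The reason is locality: reads that share sequence are scattered across the
file, far outside any compressor's context window, and a read and its
reverse complement look like unrelated strings even when they cover the
same locus.

`relo` fixes the order, not the compressor.  Given a draft-assembly contig
graph (GFA1, e.g. from miniasm) and read-to-contig mappings (PAF, e.g. from
minimap2), it rewrites the read file so overlapping reads sit next to each
other in a consistent orientation, then lets any generic compressor exploit
the redundancy.  The transformation is lossless: a small sidecar table
restores the original file byte-for-byte, and an order-invariant digest
verifies integrity on every run.

## Method

1. **Contig linearization.**  The GFA segments and oriented links form a
   bidirected graph (each link is traversable forwards and as its mirrored
   reverse).  An iterative depth-first search follows each path to its end
   before backtracking, starting from segments with no incoming link
   (longest first) so runs of linked contigs stay unbroken; every segment
   is emitted exactly once, in the orientation first reached.  Successors
   are tried in order of descending overlap length.
2. **Read placement.**  PAF mappings are sorted by contig rank along the
   linearization, then by start position.  Scanning that sorted list, each
   read is emitted at its *first encounter*; reads with no (usable) mapping
   are appended at the end in input order.  Every input read appears
   exactly once.
3. **Strand handling** (three modes):
   * `unify` (default) — reads mapping to the reverse strand are
     reverse-complemented so neighbours share orientation; best
     compression.
   * `preserve` — orientations untouched; the file is grouped into a `+`
     block and a `-` block, each position-sorted (for strand-aware
     analyses).
   * `ignore` — position sort only, strand plays no role (baseline).
4. **Losslessness.**  Each output read's 0-based original index (32 bits)
   and orientation bit go into a restore table — `18 + 4n + ⌈n/8⌉` bytes
   for `n` reads, i.e. ~40 MB for 10 million reads, negligible next to the
   data.  An order-invariant digest (per-read 128-bit MD5 combined by
   addition mod 2^128; canonical, strand-invariant form when orientations
   may change) is checked before any output is accepted.

A seeded simulator (`sim_config()`, `simulate_genome()`, `sample_reads()`,
`build_truth_assembly()`, `emit_truth_paf()`) generates genomes,
error-bearing strand-aware reads, and matching truth GFA/PAF, so the whole
pipeline runs and is testable without any external tools.

## Worked example

```r
library(relo)

# a 50 kb genome at 20x, truth assembly of 4 contigs, 5% of reads unmapped,
# input file shuffled (an archival worst case)
cfg    <- sim_config(genome_length = 50000, coverage = 20, seed = 7)
genome <- simulate_genome(cfg)
rs     <- sample_reads(genome, cfg)
ta     <- build_truth_assembly(genome, n_contigs = 4, link_overlap = 200)
paf    <- emit_truth_paf(rs$truth, ta$contigs, withhold_frac = 0.05, seed = 8)
reads  <- shuffle_reads(rs$reads, seed = 9)

report <- run_sort(reads, ta$graph, paf, mode = "unify",
                   out = "sorted.fasta", restore_out = "restore.bin")
report
#> <relo_report> mode unify
#>   reads:    964 (916 placed, 48 unmapped, 456 reverse-complemented)
#>   contigs:  4 segment(s), 3 link(s)
#>   digest:   1dd2dca6857d7beb2d96134a994ec0af (canonical) == output digest [OK]
```

916 of the 964 reads were placed by their mappings (the 48 withheld from
the PAF were appended unmapped), 456 were reverse-complemented onto their
contig's strand, and the canonical digest certifies the output holds
exactly the same sequences.  The compression effect:

```r
write_seqs(reads, "input.fasta")
run_bench(c(input = "input.fasta", reordered = "sorted.fasta"))
#>        file compressor original_bytes compressed_bytes     ratio failed
#> 1     input    deflate        1012683           274817  3.684936  FALSE
#> 2 reordered    deflate        1012683            45201 22.403995  FALSE
```

Same bytes, same compressor: the shuffled input compresses 3.7-fold, the
reordered file 22.4-fold, because consecutive reads now overlap.  Mean
adjacent true-start distance drops from ~17 kb (shuffled) to ~53 bases
(reordered).  And the round trip is exact:

```r
back <- restore_input(read_seqs("sorted.fasta"),
                      read_restore_table("restore.bin"))
identical(as.data.frame(back), as.data.frame(reads))
#> [1] TRUE
```

`tidy(report)` gives one row per output read (origin, placement, flip);
`glance(report)` the one-row summary; `autoplot(report, truth = rs$truth)`
the position-vs-rank layout plot.

A command-line front end wrapping these functions ships at
`inst/cli/relo.R` with `sort`, `restore`, `digest`, `simulate` and `bench`
subcommands (exit codes: 0 success, 2 usage, 3 integrity, 4 external
tool).

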