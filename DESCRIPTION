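Package: relo
Title: Reference-Free Reordering of Long Reads for Better Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rewrites long-read FASTA/FASTQ files so that reads with
    overlapping sequences sit next to each other and share a consistent
    orientation, which lets generic compressors (gzip, zstd, xz) exploit
    the redundancy their bounded context windows would otherwise miss.
    Read placement is driven by a draft-assembly contig graph (GFA1) and
    read-to-contig mappings (PAF): the contig graph is linearised by
    depth-first search, mappings are sorted by contig rank and position,
    and each read is emitted at its first encounter with unmapped reads
    appended.  Reordering is lossless: a compact restore table (32 bits
    plus one orientation bit per read) reconstructs the original file
    exactly, and an order-invariant sequence digest verifies integrity.
    A seeded simulator generates genomes, error-bearing strand-aware
    reads and matching truth GFA/PAF so the whole pipeline can be
    exercised without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    magrittr,
    openssl,
    purrr,
    rlang,
    stringi,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
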