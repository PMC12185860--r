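# Streaming-style readers/writers for FASTA/FASTQ, GFA1 and PAF.
# All readers accept plain or gzip-compressed files (gzfile() sniffs the
# magic bytes itself), return tibbles, and keep coordinates exactly as the
# source format defines them (PAF: 0-based half-open).

#' Read sequences from a FASTA or FASTQ file
#'
#' Parses a (possibly gzip-compressed) FASTA or FASTQ file into a tibble with
#' one row per record, preserving ids, free-text descriptions, sequence case
#' and quality strings byte-for-byte so that [write_seqs()] can round-trip
#' the file exactly.  Row order is input order, so `dplyr::row_number() - 1`
#' is the 0-based original index of each read.
#'
#' @param path Path to a FASTA/FASTQ file, optionally gzip-compressed.
#' @param format `"auto"` (sniff from the first non-empty character: `>` for
#'   FASTA, `@` for FASTQ), `"fasta"` or `"fastq"`.
#' @param dup_ids What to do with duplicate read ids: `"error"` (default;
#'   downstream placement and restore logic assume unique ids) or
#'   `"make_unique"`, which suffixes later duplicates with `"_dupK"` and
#'   records the original id in a `.orig_id` column that [write_seqs()]
#'   emits in place of the internal id.
#'
#' @return A tibble with columns `id` (token before the first whitespace of
#'   the header), `desc` (the rest of the header, `""` if absent), `seq`,
#'   and `qual` (`NA` for FASTA records).
#'
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1 sample", "ACGT", ">r2", "GG", "TT"), fa)
#' read_seqs(fa)
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq"),
                      dup_ids = c("error", "make_unique")) {
  format <- match.arg(format)
  dup_ids <- match.arg(dup_ids)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "relo_io_error")
  }
  lines <- readLines(gzfile(path), warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    return(tibble(id = character(), desc = character(),
                  seq = character(), qual = character()))
  }
  if (format == "auto") {
    first <- substr(lines[nonempty[1L]], 1L, 1L)
    format <- switch(first, ">" = "fasta", "@" = "fastq",
      abort(paste0("cannot sniff format of ", path,
                   ": first record starts with '", first, "'"),
            class = "relo_parse_error"))
  }
  recs <- if (format == "fasta") parse_fasta_lines(lines, path)
          else parse_fastq_lines(lines, path)
  dup <- duplicated(recs$id)
  if (any(dup)) {
    if (dup_ids == "error") {
      abort(paste0("duplicate read id(s) in ", path, ": ",
                   paste(head(unique(recs$id[dup]), 5L), collapse = ", "),
                   " (use dup_ids = \"make_unique\" to keep them)"),
            class = "relo_dup_id_error")
    }
    recs$.orig_id <- recs$id
    recs$id <- make_unique_ids(recs$id)
  }
  recs
}

parse_fasta_lines <- function(lines, path) {
  hdr <- startsWith(lines, ">")
  if (!hdr[which(nzchar(trimws(lines)))[1L]]) {
    abort(paste0(path, ": line ", which(nzchar(trimws(lines)))[1L],
                 ": sequence data before the first '>' header"),
          class = "relo_parse_error")
  }
  grp <- cumsum(hdr)
  keep <- nzchar(lines) | hdr
  headers <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[keep & !hdr], grp[keep & !hdr]),
                 paste0, character(1), collapse = "")
  # groups with no sequence line at all must still appear (empty sequence)
  full <- character(sum(hdr))
  names(full) <- as.character(seq_len(sum(hdr)))
  full[names(seqs)] <- seqs
  tibble(
    id = sub("\\s.*$", "", headers),
    desc = ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), ""),
    seq = unname(full),
    qual = NA_character_
  )
}

parse_fastq_lines <- function(lines, path) {
  # trailing blank lines are tolerated; blank lines inside a record are not
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    abort(paste0(path, ": truncated FASTQ record at line ",
                 4L * (length(lines) %/% 4L) + 1L,
                 " (file has ", length(lines), " lines, not a multiple of 4)"),
          class = "relo_parse_error")
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    abort(paste0(path, ": line ", idx[bad_hdr[1L]],
                 ": FASTQ header does not start with '@'"),
          class = "relo_parse_error")
  }
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    abort(paste0(path, ": line ", idx[bad_plus[1L]] + 2L,
                 ": expected '+' separator line"),
          class = "relo_parse_error")
  }
  quals <- lines[idx + 3L]
  bad_len <- which(nchar(quals) != nchar(seqs))
  if (length(bad_len)) {
    abort(paste0(path, ": line ", idx[bad_len[1L]] + 3L,
                 ": quality length (", nchar(quals[bad_len[1L]]),
                 ") != sequence length (", nchar(seqs[bad_len[1L]]), ")"),
          class = "relo_parse_error")
  }
  headers <- sub("^@", "", hdr)
  tibble(
    id = sub("\\s.*$", "", headers),
    desc = ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), ""),
    seq = seqs,
    qual = quals
  )
}

make_unique_ids <- function(ids) {
  out <- ids
  counts <- new.env(parent = emptyenv())
  for (i in seq_along(ids)) {
    k <- ids[[i]]
    prev <- get0(k, envir = counts, ifnotfound = 0L)
    if (prev > 0L) out[[i]] <- paste0(k, "_dup", prev + 1L)
    assign(k, prev + 1L, envir = counts)
  }
  out
}

#' Write sequences to a FASTA or FASTQ file
#'
#' Inverse of [read_seqs()]: `read_seqs(write_seqs(x, path))` reproduces
#' `x`'s `(id, desc, seq, qual)` tuples exactly (line wrapping is
#' presentation only).  Output is gzip-compressed when `path` ends in
#' `.gz`.
#'
#' @param x Tibble with columns `id`, `desc`, `seq` and optionally `qual`
#'   (as produced by [read_seqs()]).  If a `.orig_id` column is present
#'   (duplicate-id handling) it is written in place of `id`.
#' @param path Output path.
#' @param format `"auto"` (FASTQ when every record has a quality string,
#'   FASTA otherwise), `"fasta"` or `"fastq"`.
#' @param line_width Wrap FASTA sequence lines at this many characters;
#'   `NULL` (default) writes each sequence on one line.  Ignored for FASTQ.
#'
#' @return The number of records written, invisibly.
#' @export
write_seqs <- function(x, path, format = c("auto", "fasta", "fastq"),
                       line_width = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  desc <- if ("desc" %in% names(x)) x$desc else rep("", nrow(x))
  qual <- if ("qual" %in% names(x)) x$qual else rep(NA_character_, nrow(x))
  ids <- if (".orig_id" %in% names(x)) {
    ifelse(is.na(x$.orig_id), x$id, x$.orig_id)
  } else {
    x$id
  }
  if (format == "auto") {
    format <- if (nrow(x) > 0L && !anyNA(qual)) "fastq" else "fasta"
  }
  hdr <- ifelse(nzchar(desc), paste(ids, desc), ids)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(x) == 0L) return(invisible(0L))  # valid empty file
  if (format == "fastq") {
    missing_q <- which(is.na(qual))
    if (length(missing_q)) {
      abort(paste0("fastq output requested but record(s) lack quality: ",
                   paste(head(ids[missing_q], 5L), collapse = ", ")),
            class = "relo_io_error")
    }
    out <- rbind(paste0("@", hdr), x$seq, "+", qual)
    writeLines(as.vector(out), con)
  } else {
    if (is.null(line_width)) {
      out <- rbind(paste0(">", hdr), x$seq)
      writeLines(as.vector(out), con)
    } else {
      stopifnot(line_width >= 1L)
      for (i in seq_len(nrow(x))) {
        writeLines(paste0(">", hdr[[i]]), con)
        s <- x$seq[[i]]
        if (nchar(s) == 0L) next
        starts <- seq(1L, nchar(s), by = line_width)
        writeLines(substring(s, starts,
                             pmin(starts + line_width - 1L, nchar(s))), con)
      }
    }
  }
  invisible(nrow(x))
}

#' Parse a GFA1 assembly graph
#'
#' Reads `S` (segment) and `L` (oriented link) lines of a GFA1 file into a
#' contig graph.  Other record types (`H`, `A`, `C`, `P`) are ignored;
#' miniasm's `a` read-hint lines in particular are parsed over silently.
#' Segment length comes from the sequence, or from an `LN:i` tag when the
#' sequence is `*`.  Link overlap length is the sum of `M` operations in
#' the CIGAR (0 for `*`).
#'
#' @param path Path to a GFA1 file, optionally gzip-compressed.
#' @param strict If `TRUE` (default) a link that references an undeclared
#'   segment is an error; if `FALSE` a length-0 placeholder segment is
#'   synthesised with a warning.
#'
#' @return A `contig_graph` object: a list with tibbles `segments`
#'   (`id`, `length`, `seq`) and `links` (`from`, `from_orient`, `to`,
#'   `to_orient`, `overlap_len`), plus an `adjacency` slot filled in by
#'   [build_adjacency()].
#' @export
parse_gfa <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "relo_io_error")
  }
  lines <- readLines(gzfile(path), warn = FALSE)
  lines <- lines[nzchar(lines)]
  rectype <- substr(lines, 1L, 1L)
  s_lines <- lines[rectype == "S"]
  l_lines <- lines[rectype == "L"]

  segs <- if (length(s_lines)) {
    fields <- strsplit(s_lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short)) {
      abort(paste0(path, ": S line with fewer than 3 fields (line ",
                   which(rectype == "S")[short[1L]], ")"),
            class = "relo_parse_error")
    }
    ids <- vapply(fields, `[[`, character(1), 2L)
    seqs <- vapply(fields, `[[`, character(1), 3L)
    lens <- integer(length(ids))
    for (i in seq_along(ids)) {
      if (seqs[[i]] == "*") {
        tags <- fields[[i]][-(1:3)]
        ln <- grep("^LN:i:", tags, value = TRUE)
        if (length(ln) == 0L) {
          abort(paste0(path, ": segment '", ids[[i]],
                       "' has '*' sequence and no LN:i tag"),
                class = "relo_parse_error")
        }
        lens[[i]] <- as.integer(sub("^LN:i:", "", ln[[1L]]))
        seqs[[i]] <- NA_character_
      } else {
        lens[[i]] <- nchar(seqs[[i]])
      }
    }
    tibble(id = ids, length = lens, seq = seqs)
  } else {
    tibble(id = character(), length = integer(), seq = character())
  }

  links <- if (length(l_lines)) {
    fields <- strsplit(l_lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 6L)
    if (length(short)) {
      abort(paste0(path, ": L line with fewer than 6 fields (line ",
                   which(rectype == "L")[short[1L]], ")"),
            class = "relo_parse_error")
    }
    f <- function(k) vapply(fields, `[[`, character(1), k)
    orient <- c(f(3L), f(5L))
    if (!all(orient %in% c("+", "-"))) {
      abort(paste0(path, ": L line orientation must be '+' or '-'"),
            class = "relo_parse_error")
    }
    tibble(
      from = f(2L), from_orient = f(3L),
      to = f(4L), to_orient = f(5L),
      overlap_len = vapply(f(6L), cigar_match_len, integer(1),
                           USE.NAMES = FALSE)
    )
  } else {
    tibble(from = character(), from_orient = character(),
           to = character(), to_orient = character(),
           overlap_len = integer())
  }

  undeclared <- setdiff(unique(c(links$from, links$to)), segs$id)
  if (length(undeclared)) {
    if (strict) {
      abort(paste0(path, ": link references undeclared segment(s): ",
                   paste(head(undeclared, 5L), collapse = ", ")),
            class = "relo_parse_error")
    }
    warn(paste0(path, ": synthesising length-0 segment(s) for ",
                paste(head(undeclared, 5L), collapse = ", ")))
    segs <- bind_rows(segs, tibble(id = undeclared, length = 0L,
                                   seq = NA_character_))
  }
  new_contig_graph(segs, links)
}

# sum of M operation lengths in a CIGAR; '*' -> 0
cigar_match_len <- function(cigar) {
  if (cigar == "*") return(0L)
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) {
    abort(paste0("malformed CIGAR in GFA link: '", cigar, "'"),
          class = "relo_parse_error")
  }
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  m <- ops[substr(ops, nchar(ops), nchar(ops)) == "M"]
  if (length(m) == 0L) return(0L)
  sum(as.integer(substr(m, 1L, nchar(m) - 1L)))
}

new_contig_graph <- function(segments, links, adjacency = NULL) {
  structure(list(segments = segments, links = links, adjacency = adjacency),
            class = "contig_graph")
}

#' @export
print.contig_graph <- function(x, ...) {
  cat("<contig_graph> ", nrow(x$segments), " segment(s), ",
      nrow(x$links), " link(s)",
      if (!is.null(x$adjacency)) ", adjacency built" else "", "\n", sep = "")
  invisible(x)
}

#' Parse a PAF mapping file
#'
#' Reads a minimap2-style PAF file (12 mandatory tab-separated columns plus
#' optional SAM-style typed tags) into a tibble of read-to-contig mappings.
#' Coordinates stay 0-based half-open on the target's forward strand, as
#' PAF defines them; they are never shifted to 1-based.
#'
#' @param path Path to a PAF file, optionally gzip-compressed.
#' @param keep `"primary"` (default) drops rows tagged `tp:A:S` (secondary)
#'   or `tp:A:I` (inversion); rows without a `tp` tag are kept.  `"all"`
#'   keeps every row and records primariness in `is_primary`.
#'
#' @return A tibble with one row per kept mapping: `read_id`, `read_len`,
#'   `strand`, `contig_id`, `contig_len`, `t_start`, `t_end`, `n_match`,
#'   `is_primary`.
#' @export
parse_paf <- function(path, keep = c("primary", "all")) {
  keep <- match.arg(keep)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "relo_io_error")
  }
  lines <- readLines(gzfile(path), warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(read_id = character(), read_len = double(),
                  strand = character(), contig_id = character(),
                  contig_len = double(), t_start = double(),
                  t_end = double(), n_match = double(),
                  is_primary = logical()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 12L)
  if (length(short)) {
    abort(paste0(path, ": line ", short[1L], ": PAF requires >= 12 columns, found ",
                 lengths(fields)[short[1L]]),
          class = "relo_parse_error")
  }
  fcol <- function(k) vapply(fields, `[[`, character(1), k)
  icol <- function(k, what) {
    v <- suppressWarnings(as.double(fcol(k)))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(paste0(path, ": line ", bad[1L], ": non-integer ", what,
                   " '", fcol(k)[bad[1L]], "'"),
            class = "relo_parse_error")
    }
    v
  }
  strand <- fcol(5L)
  if (!all(strand %in% c("+", "-"))) {
    abort(paste0(path, ": line ", which(!strand %in% c("+", "-"))[1L],
                 ": strand column must be '+' or '-'"),
          class = "relo_parse_error")
  }
  tp <- vapply(fields, function(f) {
    tags <- f[-(1:12)]
    hit <- grep("^tp:A:", tags, value = TRUE)
    if (length(hit)) substr(hit[[1L]], 6L, 6L) else NA_character_
  }, character(1))
  out <- tibble(
    read_id = fcol(1L),
    read_len = icol(2L, "read length"),
    strand = strand,
    contig_id = fcol(6L),
    contig_len = icol(7L, "target length"),
    t_start = icol(8L, "target start"),
    t_end = icol(9L, "target end"),
    n_match = icol(10L, "match count"),
    is_primary = is.na(tp) | tp == "P"
  )
  bad <- which(!(out$t_start >= 0 & out$t_start < out$t_end &
                   out$t_end <= out$contig_len))
  if (length(bad)) {
    abort(paste0(path, ": line ", bad[1L],
                 ": target coordinates violate 0 <= start < end <= length"),
          class = "relo_parse_error")
  }
  if (keep == "primary") out <- out[out$is_primary, ]
  out
}

#' Write mappings to a PAF file
#'
#' Companion to [parse_paf()]; used by the simulator to emit truth
#' mappings.  Secondary rows (`is_primary == FALSE`) get a `tp:A:S` tag,
#' primary rows `tp:A:P`.
#'
#' @param x Tibble of mappings as returned by [parse_paf()] or
#'   [emit_truth_paf()].
#' @param path Output path (gzip when ending in `.gz`).
#' @return `path`, invisibly.
#' @export
write_paf <- function(x, path) {
  is_primary <- if ("is_primary" %in% names(x)) x$is_primary else TRUE
  # query coordinates are not tracked; write the full-read placeholder
  lines <- paste(x$read_id, fmt_int(x$read_len), 0L, fmt_int(x$read_len),
                 x$strand, x$contig_id, fmt_int(x$contig_len),
                 fmt_int(x$t_start), fmt_int(x$t_end), fmt_int(x$n_match),
                 fmt_int(pmax(x$t_end - x$t_start, x$n_match)), 60L,
                 ifelse(is_primary, "tp:A:P", "tp:A:S"),
                 sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a contig graph to a GFA1 file
#'
#' @param graph A `contig_graph` (see [parse_gfa()]).  Segments without a
#'   stored sequence are written as `*` with an `LN:i` tag.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  segs <- graph$segments
  s <- ifelse(is.na(segs$seq),
              paste("S", segs$id, "*", paste0("LN:i:", segs$length),
                    sep = "\t"),
              paste("S", segs$id, segs$seq, sep = "\t"))
  l <- character(0)
  if (nrow(graph$links)) {
    lk <- graph$links
    l <- paste("L", lk$from, lk$from_orient, lk$to, lk$to_orient,
               ifelse(lk$overlap_len > 0, paste0(lk$overlap_len, "M"), "*"),
               sep = "\t")
  }
  writeLines(c(s, l), path)
  invisible(path)
}

fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)
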