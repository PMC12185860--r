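# End-to-end orchestration: parse -> linearize -> sort -> place -> emit,
# with the digest safety net; assembly-input subsampling; the external
# assembler/mapper subprocess contract; and the desk-scale compression
# bench.

#' Reorder a read file end to end
#'
#' Runs the whole pipeline: read the reads, parse GFA and PAF, linearize
#' the contig graph by DFS, sort the mappings along it, place each read at
#' its first encounter with unmapped reads appended, apply the plan
#' (reverse-complementing under `mode = "unify"`), and verify that the
#' order-invariant dataset digest of the output equals that of the input
#' (canonical digest under `unify`, raw otherwise).  A digest mismatch
#' deletes the output file and aborts — the pipeline never leaves a
#' corrupt reordering behind.
#'
#' @param reads Path to FASTA/FASTQ (optionally gzipped), or a record
#'   tibble.
#' @param gfa Path to a GFA1 file, or a `contig_graph`.
#' @param paf Path to a PAF file, or a mapping tibble.
#' @param mode Strand mode: `"unify"`, `"preserve"` or `"ignore"`
#'   (see [plan_placement()]).
#' @param out Optional path for the reordered reads.
#' @param restore_out Optional path for the binary restore table.
#' @param order_out Optional path for the contig-order TSV.
#' @param keep Which PAF rows to use (see [parse_paf()]).
#' @param best_mapping,block_flip Passed to [plan_placement()] /
#'   [sort_mappings()].
#' @return A `relo_report`: counts, digests, the `placement_plan`, the
#'   `restore_table`, the reordered records and the contig order.
#' @export
run_sort <- function(reads, gfa, paf,
                     mode = c("unify", "preserve", "ignore"),
                     out = NULL, restore_out = NULL, order_out = NULL,
                     keep = c("primary", "all"),
                     best_mapping = FALSE, block_flip = TRUE) {
  mode <- match.arg(mode)
  keep <- match.arg(keep)
  recs <- if (is.character(reads)) read_seqs(reads) else as_tibble(reads)
  graph <- if (is.character(gfa)) parse_gfa(gfa) else gfa
  mappings <- if (is.character(paf)) parse_paf(paf, keep = keep)
              else as_tibble(paf)
  graph <- build_adjacency(graph)
  order <- dfs_order(graph)
  sorted <- sort_mappings(mappings, order, mode = mode,
                          block_flip = block_flip)
  plan <- plan_placement(sorted, recs$id, mode = mode,
                         best_mapping = best_mapping)
  res <- apply_plan(recs, plan)

  canonical <- mode == "unify"
  dg_in <- dataset_digest(recs, canonical = canonical)
  dg_out <- dataset_digest(res$records, canonical = canonical)
  match_ok <- identical(dg_in$digest, dg_out$digest)

  if (!is.null(out)) write_seqs(res$records, out)
  if (!match_ok && !is.null(out)) unlink(out)
  if (!match_ok) {
    abort(paste0("dataset digest mismatch after reordering (mode ", mode,
                 "); output removed"), class = "relo_integrity_error")
  }
  if (!is.null(restore_out)) write_restore_table(res$restore, restore_out)
  if (!is.null(order_out)) write_contig_order(order, order_out)

  structure(list(
    n_reads = nrow(recs),
    n_mappings = nrow(mappings),
    n_placed = nrow(plan$placed),
    n_unmapped = length(plan$unmapped_ids),
    n_flipped = sum(plan$placed$emit_rc),
    n_contigs = nrow(graph$segments),
    n_links = nrow(graph$links),
    mode = mode,
    digest_in = dg_in$digest,
    digest_out = dg_out$digest,
    digest_match = match_ok,
    canonical_digest = canonical,
    plan = plan,
    restore = res$restore,
    records = res$records,
    contig_order = order,
    paths = list(out = out, restore_out = restore_out,
                 order_out = order_out)
  ), class = "relo_report")
}

#' @export
print.relo_report <- function(x, ...) {
  cat("<relo_report> mode ", x$mode, "\n",
      "  reads:    ", x$n_reads, " (", x$n_placed, " placed, ",
      x$n_unmapped, " unmapped, ", x$n_flipped, " reverse-complemented)\n",
      "  contigs:  ", x$n_contigs, " segment(s), ", x$n_links, " link(s)\n",
      "  digest:   ", x$digest_in,
      if (x$canonical_digest) " (canonical)" else "",
      if (x$digest_match) " == output digest [OK]\n"
      else " != output digest [MISMATCH]\n", sep = "")
  invisible(x)
}

#' Glance at a reordering report
#'
#' @param x A `relo_report` from [run_sort()].
#' @param ... Unused.
#' @return One-row tibble of the report's summary quantities.
#' @method glance relo_report
#' @export
glance.relo_report <- function(x, ...) {
  tibble(n_reads = x$n_reads, n_mappings = x$n_mappings,
         n_placed = x$n_placed, n_unmapped = x$n_unmapped,
         n_flipped = x$n_flipped, n_contigs = x$n_contigs,
         n_links = x$n_links, mode = x$mode,
         digest_match = x$digest_match)
}

#' Tidy a reordering report into one row per output read
#'
#' @param x A `relo_report` from [run_sort()].
#' @param ... Unused.
#' @return Tibble with `output_index`, `read_id`, `original_index`,
#'   `flipped`, `placed` and, for placed reads, the placing `contig_id`,
#'   `t_start` and effective `strand`.
#' @method tidy relo_report
#' @export
tidy.relo_report <- function(x, ...) {
  plan <- x$plan
  n_placed <- nrow(plan$placed)
  tibble(
    output_index = seq_len(x$n_reads) - 1,
    read_id = c(plan$placed$read_id, plan$unmapped_ids),
    original_index = x$restore$original_index,
    flipped = x$restore$flipped,
    placed = rep(c(TRUE, FALSE), c(n_placed, length(plan$unmapped_ids))),
    contig_id = c(plan$placed$contig_id,
                  rep(NA_character_, length(plan$unmapped_ids))),
    t_start = c(plan$placed$t_start,
                rep(NA_real_, length(plan$unmapped_ids))),
    strand = c(plan$placed$strand,
               rep(NA_character_, length(plan$unmapped_ids)))
  )
}

#' Export a machine-readable report
#'
#' @param x A `relo_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(glance(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Subsample the longest reads for assembly input
#'
#' Takes reads in descending length order (ties broken by ascending id)
#' until their cumulative bases reach `target_coverage *
#' genome_size_estimate`.  Draft assembly stays contiguous on a moderate
#' coverage of the longest reads, so assembling a subset cuts the dominant
#' all-vs-all alignment cost; the subset feeds *only* the assembler — the
#' reordering itself always covers every read.
#'
#' @param x Record tibble.
#' @param genome_size_estimate Estimated genome size in bases.
#' @param target_coverage Target coverage (x) of the subset, e.g. 30–60.
#' @return The selected records (a prefix of the length-sorted tibble).
#'   If total bases fall short of the target, all records are returned
#'   with a warning.
#' @export
subsample_longest <- function(x, genome_size_estimate, target_coverage) {
  stopifnot(genome_size_estimate > 0, target_coverage > 0)
  lens <- nchar(x$seq)
  ord <- order(-lens, x$id)
  target <- target_coverage * genome_size_estimate
  csum <- cumsum(lens[ord])
  if (csum[length(csum)] < target) {
    warn(paste0("total read bases (", csum[length(csum)],
                ") below target (", fmt_int(target), "); returning all reads"))
    return(x[ord, , drop = FALSE])
  }
  k <- which(csum >= target)[1L]
  x[ord[seq_len(k)], , drop = FALSE]
}

#' Run an external assembler/mapper chain
#'
#' Thin subprocess contract around the conventional draft-assembly chain:
#' all-vs-all overlaps (minimap2 `ava-ont`/`ava-pb`), unitig layout
#' (miniasm), then mapping of *all* reads onto the unitigs (minimap2).
#' The three stages are plain shell templates with `{...}` placeholders,
#' so any tool with compatible outputs can be substituted; nothing in the
#' core pipeline depends on these binaries.
#'
#' Placeholders: `{reads}` (assembly input, possibly subsampled),
#' `{all_reads}` (every read), `{ava_paf}`, `{gfa}`, `{contigs}` (FASTA
#' extracted from the GFA S lines by this function), `{paf}`.
#'
#' @param reads Path to the full read file.
#' @param templates Named character vector/list with entries `ava`, `asm`,
#'   `map`.
#' @param workdir Directory for intermediates (created; kept for
#'   inspection).
#' @param subsample Optional record tibble (e.g. from
#'   [subsample_longest()]) written to `{reads}` instead of the full set.
#' @return List with `gfa` and `paf` paths consumable by [run_sort()].
#' @export
run_external_assembly <- function(reads,
                                  templates = c(
    ava = "minimap2 -x ava-ont {reads} {reads} > {ava_paf}",
    asm = "miniasm -f {reads} {ava_paf} > {gfa}",
    map = "minimap2 {contigs} {all_reads} > {paf}"),
                                  workdir = tempfile("relo_asm_"),
                                  subsample = NULL) {
  stopifnot(all(c("ava", "asm", "map") %in% names(templates)))
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  slots <- list(
    all_reads = reads,
    reads = reads,
    ava_paf = file.path(workdir, "ava.paf"),
    gfa = file.path(workdir, "assembly.gfa"),
    contigs = file.path(workdir, "contigs.fasta"),
    paf = file.path(workdir, "mapped.paf")
  )
  if (!is.null(subsample)) {
    slots$reads <- file.path(workdir, "subsampled.fasta")
    write_seqs(subsample, slots$reads)
  }
  cmds <- vapply(templates[c("ava", "asm", "map")], fill_template,
                 character(1), slots = slots)
  run_stage <- function(cmd, stage) {
    exe <- sub("\\s.*$", "", cmd)
    if (Sys.which(exe) == "") {
      abort(paste0("external tool '", exe, "' not found on PATH; ",
                   "adjust the '", stage, "' template or supply --gfa/--paf ",
                   "directly"), class = "relo_external_error")
    }
    status <- system2("sh", c("-c", shQuote(cmd)),
                      stdout = NULL,
                      stderr = file.path(workdir, paste0(stage, ".stderr")))
    if (status != 0L) {
      err <- readLines(file.path(workdir, paste0(stage, ".stderr")),
                       warn = FALSE)
      abort(paste0("external ", stage, " command failed (exit ", status,
                   "): ", cmd, "\n", paste(tail(err, 10L), collapse = "\n")),
            class = "relo_external_error")
    }
  }
  run_stage(cmds[["ava"]], "ava")
  run_stage(cmds[["asm"]], "asm")
  graph <- parse_gfa(slots$gfa)
  if (nrow(graph$segments) == 0L) {
    abort(paste0("assembly produced no contigs (no S lines in ", slots$gfa,
                 "); try higher coverage or different assembler parameters"),
          class = "relo_external_error")
  }
  if (anyNA(graph$segments$seq)) {
    abort("assembly GFA lacks segment sequences; cannot extract contigs",
          class = "relo_external_error")
  }
  write_seqs(tibble(id = graph$segments$id, desc = "",
                    seq = graph$segments$seq, qual = NA_character_),
             slots$contigs)
  run_stage(cmds[["map"]], "map")
  list(gfa = slots$gfa, paf = slots$paf, workdir = workdir)
}

fill_template <- function(template, slots) {
  found <- regmatches(template, gregexpr("\\{[^{}]*\\}", template))[[1L]]
  keys <- gsub("[{}]", "", found)
  unknown <- setdiff(keys, names(slots))
  if (length(unknown)) {
    abort(paste0("unknown placeholder(s) in command template: ",
                 paste0("{", unknown, "}", collapse = ", ")),
          class = "relo_config_error")
  }
  for (k in unique(keys)) {
    template <- gsub(paste0("{", k, "}"), slots[[k]], template, fixed = TRUE)
  }
  template
}

#' Desk-scale compression bench
#'
#' Compresses the given files with the built-in DEFLATE backend
#' (`memCompress`, zero external dependencies) and any external
#' compressor templates supplied (`{in}`/`{out}` placeholders), reporting
#' bytes and ratio per (file, compressor).  A failing external compressor
#' marks its row `failed` and the run continues.  The bench compares
#' orderings of the same data; it makes no claim about absolute ratios.
#'
#' @param files Named character vector of file paths (names label the
#'   rows, e.g. `c(original = ..., reordered = ...)`).
#' @param compressors Optional named character vector of shell templates,
#'   e.g. `c(gzip9 = "gzip -9 -c {in} > {out}")`.
#' @return A `relo_bench` tibble: `file`, `compressor`, `original_bytes`,
#'   `compressed_bytes`, `ratio`, `failed`.
#' @export
run_bench <- function(files, compressors = character()) {
  if (is.null(names(files)) || any(!nzchar(names(files)))) {
    names(files) <- basename(unlist(files))
  }
  rows <- list()
  for (label in names(files)) {
    path <- files[[label]]
    raw <- readBin(path, "raw", file.size(path))
    rows[[length(rows) + 1L]] <- tibble(
      file = label, compressor = "deflate",
      original_bytes = length(raw),
      compressed_bytes = length(memCompress(raw, type = "gzip")),
      ratio = length(raw) / length(memCompress(raw, type = "gzip")),
      failed = FALSE
    )
    for (cname in names(compressors)) {
      outp <- tempfile("relo_bench_")
      cmd <- fill_template(compressors[[cname]],
                           list(`in` = path, out = outp))
      status <- tryCatch(system2("sh", c("-c", shQuote(cmd)), stdout = NULL,
                                 stderr = NULL),
                         error = function(e) 1L)
      ok <- identical(status, 0L) && file.exists(outp)
      rows[[length(rows) + 1L]] <- tibble(
        file = label, compressor = cname,
        original_bytes = length(raw),
        compressed_bytes = if (ok) file.size(outp) else NA_real_,
        ratio = if (ok) length(raw) / file.size(outp) else NA_real_,
        failed = !ok
      )
      unlink(outp)
    }
  }
  structure(bind_rows(rows),
            class = c("relo_bench", "tbl_df", "tbl", "data.frame"))
}

#' Write a bench table as TSV and JSON
#'
#' @param x A `relo_bench` tibble.
#' @param path Base path; writes `<path>.tsv` and `<path>.json`.
#' @return Invisibly, the two paths.
#' @export
write_bench <- function(x, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(x, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x, json, digits = NA)
  invisible(list(tsv = tsv, json = json))
}
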