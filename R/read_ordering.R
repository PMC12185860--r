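# From (mappings, contig order, strand mode) to the final read permutation:
# sort mappings along the linearized contigs, place each read at its first
# encounter, append unmapped reads, and (in unify mode) flag minus-strand
# reads for reverse complementation.

#' Sort mappings along a contig order
#'
#' Orders PAF mappings by the contig ranks of a [dfs_order()]
#' linearization and, within each contig, by mapping start position.
#' Under `mode = "preserve"` the mappings are first separated by alignment
#' strand (`+` block before `-` block) and only then sorted by contig and
#' position, so reads keep their original orientation but same-strand
#' reads group together.
#'
#' For a contig the DFS reached in `-` orientation (and `block_flip` is
#' on), its mappings sort by descending end position and each mapping's
#' effective strand is flipped, so the contig's read block reads
#' collinearly with the traversal.
#'
#' Mappings to contigs absent from `order` are dropped with a warning
#' (their reads fall through to the unmapped tail), never an error.
#'
#' @param mappings Mapping tibble from [parse_paf()] or
#'   [emit_truth_paf()].
#' @param order A `contig_order` from [dfs_order()].
#' @param mode `"unify"` (default), `"preserve"` or `"ignore"` — see
#'   [plan_placement()].
#' @param block_flip Reverse the within-contig order (and flip effective
#'   strands) for contigs traversed in `-` orientation.
#' @return The sorted mapping tibble with extra columns `rank`,
#'   `eff_strand` and `pos_key`.
#' @export
sort_mappings <- function(mappings, order,
                          mode = c("unify", "preserve", "ignore"),
                          block_flip = TRUE) {
  mode <- match.arg(mode)
  m <- as_tibble(mappings)
  hit <- match(m$contig_id, order$contig_id)
  if (anyNA(hit)) {
    lost <- unique(m$contig_id[is.na(hit)])
    warn(paste0("dropping mappings to ", length(lost),
                " contig(s) absent from the contig order: ",
                paste(head(lost, 5L), collapse = ", ")))
    m <- m[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  m$rank <- order$rank[hit]
  flip <- block_flip & order$orient[hit] == "-"
  m$eff_strand <- ifelse(flip, flip_orient(m$strand), m$strand)
  m$pos_key <- ifelse(flip, m$contig_len - m$t_end, m$t_start)
  if (mode == "preserve") {
    m$strand_group <- match(m$eff_strand, c("+", "-"))
    m <- arrange(m, .data$strand_group, .data$rank, .data$pos_key,
                 .data$read_id)
    m$strand_group <- NULL
  } else {
    m <- arrange(m, .data$rank, .data$pos_key, .data$read_id)
  }
  m
}

#' Plan the output placement of every read
#'
#' Scans the sorted mappings and emits each read at its first encounter,
#' skipping any later mapping of the same read; reads never encountered
#' are appended at the end in input order.  Every input read appears
#' exactly once across placed + unmapped.
#'
#' The strand mode decides orientation handling:
#' * `"unify"` — a read whose effective alignment strand is `-` is flagged
#'   for reverse complementation, so all reads share their contig's
#'   orientation (best compression).
#' * `"preserve"` — reads keep their orientation; same-strand reads are
#'   grouped by [sort_mappings()] (for strand-aware analyses).
#' * `"ignore"` — reads keep their orientation and strand plays no role in
#'   the sort (baseline; typically compresses worst of the three).
#'
#' @param sorted Sorted mapping tibble from [sort_mappings()].
#' @param read_ids All input read ids, in input order.
#' @param mode Strand mode used when sorting.
#' @param best_mapping Instead of first-encounter dedup, pre-filter to each
#'   read's maximum-`n_match` mapping (ties: earliest sort position).
#' @return A `placement_plan`: list with `placed` (tibble `read_id`,
#'   `emit_rc`, and provenance `contig_id`, `t_start`, `strand`),
#'   `unmapped_ids`, and `mode`.
#' @export
plan_placement <- function(sorted, read_ids,
                           mode = c("unify", "preserve", "ignore"),
                           best_mapping = FALSE) {
  mode <- match.arg(mode)
  stranger <- setdiff(unique(sorted$read_id), read_ids)
  if (length(stranger)) {
    abort(paste0("mappings reference read id(s) absent from the input (",
                 "PAF/FASTA mismatch): ",
                 paste(head(stranger, 10L), collapse = ", ")),
          class = "relo_plan_error")
  }
  m <- sorted
  if (best_mapping && nrow(m)) {
    m$.sort_pos <- seq_len(nrow(m))
    m <- m %>%
      group_by(.data$read_id) %>%
      filter(.data$n_match == max(.data$n_match)) %>%
      slice(1L) %>%  # tie: earliest sort position (rows are in sort order)
      ungroup() %>%
      arrange(.data$.sort_pos)
    m$.sort_pos <- NULL
  }
  first <- m[!duplicated(m$read_id), , drop = FALSE]
  placed <- tibble(
    read_id = first$read_id,
    emit_rc = if (mode == "unify") first$eff_strand == "-"
              else rep(FALSE, nrow(first)),
    contig_id = first$contig_id,
    t_start = first$t_start,
    strand = first$eff_strand
  )
  unmapped <- read_ids[!read_ids %in% placed$read_id]
  structure(list(placed = placed, unmapped_ids = unmapped, mode = mode),
            class = "placement_plan")
}

#' @export
print.placement_plan <- function(x, ...) {
  cat("<placement_plan> mode ", x$mode, ": ", nrow(x$placed),
      " placed (", sum(x$placed$emit_rc), " to reverse-complement), ",
      length(x$unmapped_ids), " unmapped appended\n", sep = "")
  invisible(x)
}

plan_ids <- function(plan) c(plan$placed$read_id, plan$unmapped_ids)

#' Apply a placement plan to the records
#'
#' Reorders the records according to the plan, reverse-complements the
#' flagged reads (reversing their quality strings in step), and builds the
#' restore table that maps every output position back to its 0-based input
#' index with an orientation bit — everything [restore_input()] needs for
#' exact reconstruction.
#'
#' @param x Record tibble (input order; see [read_seqs()]).
#' @param plan A `placement_plan` from [plan_placement()].
#' @return List with `records` (reordered tibble) and `restore`
#'   (a `restore_table`).
#' @export
apply_plan <- function(x, plan) {
  stopifnot(inherits(plan, "placement_plan"))
  ids <- plan_ids(plan)
  missing_in_plan <- setdiff(x$id, ids)
  missing_in_input <- setdiff(ids, x$id)
  if (length(missing_in_plan) || length(missing_in_input)) {
    abort(paste0(
      "plan and input disagree on read ids",
      if (length(missing_in_plan))
        paste0("; not in plan: ",
               paste(head(missing_in_plan, 10L), collapse = ", ")),
      if (length(missing_in_input))
        paste0("; not in input: ",
               paste(head(missing_in_input, 10L), collapse = ", "))),
      class = "relo_plan_error")
  }
  pos <- match(ids, x$id)
  out <- x[pos, , drop = FALSE]
  flipped <- c(plan$placed$emit_rc, rep(FALSE, length(plan$unmapped_ids)))
  if (any(flipped)) {
    out$seq[flipped] <- reverse_complement(out$seq[flipped])
    if ("qual" %in% names(out)) {
      has_q <- flipped & !is.na(out$qual)
      out$qual[has_q] <- stringi::stri_reverse(out$qual[has_q])
    }
  }
  list(records = out,
       restore = new_restore_table(pos - 1L, flipped, plan$mode))
}

#' Mean adjacent true-start distance of a read order
#'
#' Quantifies how well an order approximates the reads' genomic
#' arrangement: the mean, over consecutive placed pairs, of the absolute
#' difference of their true start coordinates (modular distance on
#' circular genomes).  Lower is better; a perfectly position-sorted order
#' scores the mean inter-start gap, a shuffled order about a third of the
#' genome length.
#'
#' @param plan A `placement_plan`, or a character vector of read ids in
#'   the order to score.
#' @param truth Truth tibble from [sample_reads()] covering all scored
#'   reads.
#' @param circular Use modular distance.
#' @param genome_length Genome length (required when `circular`).
#' @return Mean distance in bases, or `NA_real_` for fewer than 2 placed
#'   reads.
#' @export
locality_score <- function(plan, truth, circular = FALSE,
                           genome_length = NULL) {
  ids <- if (inherits(plan, "placement_plan")) plan$placed$read_id else plan
  if (length(ids) < 2L) return(NA_real_)
  hit <- match(ids, truth$read_id)
  if (anyNA(hit)) {
    abort("truth does not cover all placed reads",
          class = "relo_plan_error")
  }
  s <- truth$true_start[hit]
  d <- abs(diff(s))
  if (circular) {
    stopifnot(!is.null(genome_length))
    d <- pmin(d, genome_length - d)
  }
  mean(d)
}
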