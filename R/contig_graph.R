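# Bidirected contig-graph adjacency and depth-first linearization.
#
# A GFA link "a oa -> b ob" can be traversed two ways: forward as written,
# and mirrored as "b flip(ob) -> a flip(oa)".  Adjacency therefore lives on
# oriented nodes (segment, orientation).  The DFS walks oriented nodes but
# marks segments visited, so each contig appears exactly once in the
# linearization, in the orientation it was first reached.

flip_orient <- function(o) ifelse(o == "+", "-", "+")

onode <- function(id, orient) paste0(id, orient)

#' Build oriented adjacency lists for a contig graph
#'
#' Inserts, for every link, its forward traversal and the mirrored reverse
#' traversal, then sorts each successor list by descending overlap length,
#' then descending successor segment length, then ascending segment id —
#' so the traversal prefers the junction sharing the most sequence and is
#' deterministic.
#'
#' @param graph A `contig_graph` from [parse_gfa()] or
#'   [build_truth_assembly()].
#' @return The graph with its `adjacency` slot populated: a named list
#'   keyed by oriented node (`"<id><orient>"`), each element a tibble of
#'   successors (`id`, `orient`, `overlap_len`).
#' @export
build_adjacency <- function(graph) {
  stopifnot(inherits(graph, "contig_graph"))
  segs <- graph$segments
  lk <- graph$links
  unknown <- setdiff(unique(c(lk$from, lk$to)), segs$id)
  if (length(unknown)) {
    abort(paste0("link references unknown segment(s): ",
                 paste(head(unknown, 5L), collapse = ", ")),
          class = "relo_graph_error")
  }
  edges <- tibble(
    src = c(onode(lk$from, lk$from_orient),
            onode(lk$to, flip_orient(lk$to_orient))),
    id = c(lk$to, lk$from),
    orient = c(lk$to_orient, flip_orient(lk$from_orient)),
    overlap_len = c(lk$overlap_len, lk$overlap_len)
  )
  edges$succ_len <- segs$length[match(edges$id, segs$id)]
  edges <- distinct(edges)
  edges <- arrange(edges, .data$src, desc(.data$overlap_len),
                   desc(.data$succ_len), .data$id)
  graph$adjacency <- split(
    select(edges, "id", "orient", "overlap_len"),
    factor(edges$src, levels = unique(edges$src))
  )
  graph
}

# segments whose '+' oriented node has no incoming traversal edge,
# in root order (descending length, ascending id)
root_candidates <- function(graph) {
  if (nrow(graph$segments) == 0L) return(character(0))
  all_succ <- unique(unlist(lapply(graph$adjacency,
                                   function(s) onode(s$id, s$orient))))
  segs <- arrange(graph$segments, desc(.data$length), .data$id)
  segs$id[!onode(segs$id, "+") %in% all_succ]
}

#' Linearize a contig graph by depth-first search
#'
#' Orders every segment of the graph by iterative DFS over oriented nodes,
#' following each path to its end before backtracking, so runs of linked
#' contigs stay contiguous in the output.  A segment is emitted once, at
#' first visit, with the orientation in which it was reached; segments left
#' untouched after all roots (isolated segments, unreached components,
#' pure cycles) are re-rooted until every segment appears.
#'
#' Roots are oriented nodes `(s, +)` with no incoming traversal edge,
#' processed in descending segment length then ascending id; when none
#' remain unvisited, the longest unvisited segment is taken in `+`
#' orientation.  Starting at path ends keeps runs unbroken; both policies
#' are deterministic, so identical GFA input gives an identical order.
#'
#' @param graph A `contig_graph`; adjacency is built on the fly if absent.
#' @return A `contig_order` tibble with columns `rank` (0-based), `contig_id`
#'   and `orient` (traversal orientation), one row per segment.
#' @export
dfs_order <- function(graph) {
  stopifnot(inherits(graph, "contig_graph"))
  if (is.null(graph$adjacency)) graph <- build_adjacency(graph)
  segs <- graph$segments
  n <- nrow(segs)
  visited <- new.env(parent = emptyenv())
  out_id <- character(n)
  out_orient <- character(n)
  k <- 0L

  emit_from <- function(root_id, root_orient) {
    # explicit stack; recursion depth must not bound graph size
    stack_id <- root_id
    stack_or <- root_orient
    while (length(stack_id)) {
      i <- length(stack_id)
      id <- stack_id[[i]]; or <- stack_or[[i]]
      stack_id <- stack_id[-i]; stack_or <- stack_or[-i]
      if (!is.null(get0(id, envir = visited))) next
      assign(id, TRUE, envir = visited)
      k <<- k + 1L
      out_id[[k]] <<- id
      out_orient[[k]] <<- or
      succ <- graph$adjacency[[onode(id, or)]]
      if (!is.null(succ) && nrow(succ)) {
        # push in reverse so the best-ranked successor is explored first
        keep <- rev(seq_len(nrow(succ)))
        stack_id <- c(stack_id, succ$id[keep])
        stack_or <- c(stack_or, succ$orient[keep])
      }
    }
  }

  for (root in root_candidates(graph)) {
    if (is.null(get0(root, envir = visited))) emit_from(root, "+")
  }
  if (k < n) {
    rest <- arrange(segs, desc(.data$length), .data$id)$id
    for (id in rest) {
      if (is.null(get0(id, envir = visited))) emit_from(id, "+")
    }
  }
  structure(
    tibble(rank = seq_len(n) - 1L, contig_id = out_id, orient = out_orient),
    class = c("contig_order", "tbl_df", "tbl", "data.frame")
  )
}

#' Brute-force DFS oracle for small graphs
#'
#' Recomputes the linearization with a plain recursive DFS using the same
#' root and successor tie-break policy as [dfs_order()] and compares the
#' two orders exactly.  Exponential-safe only on small graphs, so it
#' refuses anything above `max_segments`.
#'
#' @param graph A `contig_graph`.
#' @param order A `contig_order` to check, e.g. from [dfs_order()].
#' @param max_segments Refuse graphs larger than this (default 12).
#' @return `TRUE` when the recursive reference order equals `order`.
#' @export
order_equivalence_oracle <- function(graph, order, max_segments = 12L) {
  stopifnot(inherits(graph, "contig_graph"))
  if (nrow(graph$segments) > max_segments) {
    abort(paste0("oracle refuses graphs with more than ", max_segments,
                 " segments"), class = "relo_graph_error")
  }
  if (is.null(graph$adjacency)) graph <- build_adjacency(graph)
  visited <- character(0)
  ref_id <- character(0)
  ref_orient <- character(0)
  recurse <- function(id, or) {
    if (id %in% visited) return(invisible())
    visited <<- c(visited, id)
    ref_id <<- c(ref_id, id)
    ref_orient <<- c(ref_orient, or)
    succ <- graph$adjacency[[onode(id, or)]]
    if (!is.null(succ)) {
      for (j in seq_len(nrow(succ))) recurse(succ$id[[j]], succ$orient[[j]])
    }
  }
  for (root in root_candidates(graph)) {
    if (!root %in% visited) recurse(root, "+")
  }
  rest <- arrange(graph$segments, desc(.data$length), .data$id)$id
  for (id in rest) {
    if (!id %in% visited) recurse(id, "+")
  }
  identical(ref_id, order$contig_id) &&
    identical(ref_orient, order$orient)
}

#' Write a contig order as TSV
#'
#' @param order A `contig_order` from [dfs_order()].
#' @param path Output path; columns `rank`, `contig_id`, `orient`.
#' @return `path`, invisibly.
#' @export
write_contig_order <- function(order, path) {
  utils::write.table(order, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
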