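# ggplot2 views of reordering results.

#' Plot read layout against the truth
#'
#' Scatter of output position versus true genomic start for each placed
#' read.  A good reordering shows long monotone runs (one per traversed
#' contig); a shuffled file shows an unstructured cloud.
#'
#' @param plan A `placement_plan` (or a `relo_report`, whose plan is used).
#' @param truth Truth tibble from [sample_reads()].
#' @return A ggplot object.
#' @export
plot_read_layout <- function(plan, truth) {
  if (inherits(plan, "relo_report")) plan <- plan$plan
  stopifnot(inherits(plan, "placement_plan"))
  df <- tibble(
    output_rank = seq_len(nrow(plan$placed)),
    true_start = truth$true_start[match(plan$placed$read_id,
                                        truth$read_id)],
    strand = plan$placed$strand
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$output_rank, .data$true_start,
                                   colour = .data$strand)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::labs(x = "position in reordered file",
                  y = "true genomic start (bases)",
                  colour = "effective\nstrand") +
    ggplot2::theme_minimal()
}

#' @rdname plot_read_layout
#' @param object A `relo_report`.
#' @param ... Must include `truth =` (see [plot_read_layout()]).
#' @method autoplot relo_report
#' @export
autoplot.relo_report <- function(object, ...) {
  dots <- list(...)
  if (is.null(dots$truth)) {
    abort("autoplot.relo_report needs a `truth =` tibble",
          class = "relo_plot_error")
  }
  plot_read_layout(object, dots$truth)
}

#' Plot a compression bench
#'
#' Bar chart of compressed size per (file, compressor) pair, so the effect
#' of reordering on each backend is read off directly.
#'
#' @param object A `relo_bench` tibble from [run_bench()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot relo_bench
#' @export
autoplot.relo_bench <- function(object, ...) {
  df <- object[!object$failed, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$compressor,
                                   .data$compressed_bytes,
                                   fill = .data$file)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "compressed bytes", fill = NULL) +
    ggplot2::theme_minimal()
}
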