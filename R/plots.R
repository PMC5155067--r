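# ggplot2 views of the standard report tables.

#' Stacked bar chart of transcription by phylum (or any grouping)
#'
#' @param expr Output of [aggregate_expression()].
#' @param include_only Drop excluded groups first (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_group_expression <- function(expr, include_only = TRUE) {
  if (include_only) expr <- dplyr::filter(expr, .data$included)
  long <- tidyr::pivot_longer(expr, -c("group", "included"),
                              names_to = "sample", values_to = "rpkm")
  long$sample <- factor(long$sample, unique(long$sample))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$rpkm,
                                     fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "summed RPKM", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of a bin's most transcribed genes
#'
#' @param top Output of [top_genes_in_bin()].
#' @return A ggplot object.
#' @export
plot_top_genes <- function(top) {
  top$gene_id <- factor(top$gene_id, rev(top$gene_id))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$pct_of_bin, y = .data$gene_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "% of bin transcription", y = NULL) +
    ggplot2::theme_minimal()
}

#' Diversity metrics along the sample gradient
#'
#' @param div Output of [diversity_metrics()].
#' @return A ggplot object with one facet per metric.
#' @export
plot_diversity <- function(div) {
  long <- tidyr::pivot_longer(div, -"sample", names_to = "metric")
  long$sample <- factor(long$sample, unique(div$sample))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value,
                                     group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' CO2 evolution rate and its running integral
#'
#' @param trace Trace with `cer` (from [compute_cer()]); a `ccer` column is
#'   added if absent.
#' @return A ggplot object.
#' @export
plot_cer <- function(trace) {
  if (is.null(trace[["ccer"]])) {
    trace$ccer <- integrate_ccer(trace$time, trace$cer, cumulative = TRUE)
  }
  long <- tidyr::pivot_longer(trace[, c("time", "cer", "ccer")], -"time")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(c(
                          cer = "CER (mg CO2 g-1 h-1)",
                          ccer = "cCER (mg CO2 g-1)"))) +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}
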