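# RPKM normalization and aggregation of transcription to genome bins,
# phyla and enzyme classes; top-transcriber share statistics.

#' Compute RPKM from raw counts and gene lengths
#'
#' RPKM = 1e9 x count / (gene length in bp x library size). By default the
#' library size of a sample is the column sum of gene-assigned counts, which
#' reproduces the normalization downstream of a counting step without
#' needing the alignment files; externally measured totals can be supplied
#' instead.
#'
#' @param counts Count tibble (`gene_id` + one integer column per sample).
#' @param genes Gene tibble with `gene_id` and `length` (bp), e.g. from
#'   [read_gff()]. Every counted gene must be present.
#' @param lib_sizes Optional named numeric vector of per-sample library
#'   sizes; default is the per-sample column sum.
#' @return Tibble shaped like `counts` with RPKM values.
#' @export
compute_rpkm <- function(counts, genes, lib_sizes = NULL) {
  samples <- setdiff(names(counts), "gene_id")
  missing <- setdiff(counts$gene_id, genes$gene_id)
  if (length(missing) > 0L) {
    stop("genes present in counts but missing from gene models: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
         call. = FALSE)
  }
  len <- genes$length[match(counts$gene_id, genes$gene_id)]
  if (is.null(lib_sizes)) {
    lib_sizes <- vapply(counts[samples], sum, numeric(1))
  } else {
    if (!all(samples %in% names(lib_sizes))) {
      stop("lib_sizes must name every sample column", call. = FALSE)
    }
    lib_sizes <- lib_sizes[samples]
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive", call. = FALSE)
  out <- counts
  for (s in samples) {
    out[[s]] <- 1e9 * counts[[s]] / (len * lib_sizes[[s]])
  }
  out
}

#' Sum RPKM over groups (bins, phyla, enzyme classes)
#'
#' Genes not covered by the grouping go to the sentinel group
#' `"(ungrouped)"`. Groups can be flagged excluded (eukaryote bins,
#' scaffolds labelled eukaryotes / cellular organisms / unassigned); they
#' are retained in the output but omitted from prokaryotic totals by
#' downstream consumers via the `included` flag.
#'
#' @param rpkm RPKM tibble from [compute_rpkm()].
#' @param grouping Tibble with columns `gene_id`, `group` and optionally a
#'   logical `included` (default `TRUE`).
#' @return Tibble with `group`, `included`, and one summed-RPKM column per
#'   sample.
#' @export
aggregate_expression <- function(rpkm, grouping) {
  stopifnot(all(c("gene_id", "group") %in% names(grouping)))
  grouping <- dplyr::distinct(grouping, .data$gene_id, .keep_all = TRUE)
  if (!"included" %in% names(grouping)) grouping$included <- TRUE
  samples <- setdiff(names(rpkm), "gene_id")
  joined <- rpkm |>
    dplyr::left_join(grouping[, c("gene_id", "group", "included")],
                     by = "gene_id") |>
    dplyr::mutate(group = dplyr::coalesce(.data$group, "(ungrouped)"),
                  included = dplyr::coalesce(.data$included, TRUE))
  joined |>
    dplyr::group_by(.data$group, .data$included) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(samples), sum),
                     .groups = "drop") |>
    dplyr::arrange(.data$group)
}

#' Share of transcription captured by the top k genome bins
#'
#' For each sample, 100 x (sum of the k largest genome-bin RPKM totals) /
#' (total prokaryotic RPKM). The numerator always ranks genome bins; the
#' denominator is configurable because unbinned prokaryotic transcription
#' ("unclassified bacteria" and phylum-labelled unbinned scaffolds) may or
#' may not be counted in the community total:
#'
#' * `"included"` (default): all included groups, binned and unbinned;
#' * `"binned"`: genome bins only.
#'
#' Ties at rank k are broken by group id for determinism. Samples with zero
#' total are reported `NA`.
#'
#' @param bin_expr Output of [aggregate_expression()] with bins as groups.
#' @param k Number of top bins.
#' @param denominator `"included"` or `"binned"`.
#' @param bins Character vector naming the groups that are genome bins;
#'   default: every group not matching `"unbinned:"` and not the sentinel.
#' @return Tibble with columns `sample`, `share_pct`.
#' @export
top_k_share <- function(bin_expr, k = 5, denominator = c("included", "binned"),
                        bins = NULL) {
  stopifnot(k >= 1)
  denominator <- match.arg(denominator)
  if (is.null(bins)) {
    bins <- bin_expr$group[!startsWith(bin_expr$group, "unbinned:") &
                             bin_expr$group != "(ungrouped)"]
  }
  samples <- setdiff(names(bin_expr), c("group", "included"))
  incl <- bin_expr |> dplyr::filter(.data$included)
  purrr::map_dfr(samples, function(s) {
    bin_vals <- incl |>
      dplyr::filter(.data$group %in% bins) |>
      dplyr::arrange(dplyr::desc(.data[[s]]), .data$group)
    denom_vals <- if (denominator == "binned") bin_vals[[s]] else incl[[s]]
    total <- sum(denom_vals)
    share <- if (total > 0) {
      100 * sum(utils::head(bin_vals[[s]], k)) / total
    } else NA_real_
    tibble::tibble(sample = s, share_pct = share)
  })
}

#' Most transcribed genes within one bin
#'
#' Ranks a bin's genes by RPKM in one sample and reports each gene's percent
#' of the bin's total transcription in that sample.
#'
#' @param rpkm RPKM tibble from [compute_rpkm()].
#' @param grouping Tibble with `gene_id`, `group` (bin membership).
#' @param bin Bin (group) id.
#' @param sample Sample column name.
#' @param n Number of genes to report.
#' @return Tibble `gene_id`, `rpkm`, `pct_of_bin`, ranked descending; empty
#'   when the bin has zero total in the sample.
#' @export
top_genes_in_bin <- function(rpkm, grouping, bin, sample, n = 5) {
  members <- grouping$gene_id[grouping$group == bin]
  sub <- rpkm |>
    dplyr::filter(.data$gene_id %in% members) |>
    dplyr::select(gene_id = "gene_id", rpkm = dplyr::all_of(sample))
  total <- sum(sub$rpkm)
  if (total <= 0) {
    return(tibble::tibble(gene_id = character(0), rpkm = numeric(0),
                          pct_of_bin = numeric(0)))
  }
  sub |>
    dplyr::mutate(pct_of_bin = 100 * .data$rpkm / total) |>
    dplyr::arrange(dplyr::desc(.data$rpkm), .data$gene_id) |>
    utils::head(n)
}
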