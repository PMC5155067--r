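# Taxonomy assignment: best-hit voting for genome bins, and a simplified
# lowest-common-ancestor rule for unbinned scaffolds. Lineages are
# semicolon-joined strings over the ranks in lineage_ranks().

#' Assign taxonomy to genome bins by best-hit voting
#'
#' Each gene casts one vote: the full lineage of its closest reference hit
#' (lowest E-value, see [best_hits()]). The bin's taxonomy is the modal
#' lineage; its amino-acid identity (AAI) is the arithmetic mean of percent
#' identity over the genes that voted for the winner. Genes without hits do
#' not vote and are excluded from the vote-fraction denominator. Voting ties
#' are broken by higher mean identity, then lexicographic lineage, so the
#' result is deterministic and permutation-invariant.
#'
#' @param hits Hit tibble (see [read_hits()]); reduced internally to one
#'   closest hit per gene.
#' @param gene_bins Tibble with columns `gene_id`, `bin_id` mapping genes to
#'   bins. Bins whose genes have no hits are reported with label
#'   `"unassigned"` and `NA` statistics.
#' @return Tibble with one row per bin: `bin_id`, `lineage`, `vote_fraction`,
#'   `mean_aai`, `n_genes` (genes that voted), `is_eukaryote`.
#' @export
vote_bin_taxonomy <- function(hits, gene_bins) {
  stopifnot(all(c("gene_id", "bin_id") %in% names(gene_bins)))
  bh <- best_hits(hits) |>
    dplyr::inner_join(dplyr::distinct(gene_bins, .data$gene_id, .data$bin_id),
                      by = "gene_id")
  voted <- bh |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::group_modify(~ vote_one_bin(.x)) |>
    dplyr::ungroup()
  no_hit_bins <- setdiff(unique(gene_bins$bin_id), voted$bin_id)
  if (length(no_hit_bins) > 0L) {
    voted <- dplyr::bind_rows(voted, tibble::tibble(
      bin_id = no_hit_bins, lineage = "unassigned",
      vote_fraction = NA_real_, mean_aai = NA_real_,
      n_genes = 0L, is_eukaryote = FALSE))
  }
  dplyr::arrange(voted, .data$bin_id)
}

vote_one_bin <- function(bh) {
  tally <- bh |>
    dplyr::group_by(.data$lineage) |>
    dplyr::summarise(votes = dplyr::n(), mean_aai = mean(.data$pct_identity),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$votes), dplyr::desc(.data$mean_aai),
                   .data$lineage)
  winner <- tally[1, ]
  tibble::tibble(
    lineage = winner$lineage,
    vote_fraction = winner$votes / nrow(bh),
    mean_aai = winner$mean_aai,
    n_genes = nrow(bh),
    is_eukaryote = identical(lineage_at_rank(winner$lineage, "domain"),
                             "Eukaryota"))
}

#' Label unbinned scaffolds by lowest common ancestor of their hits
#'
#' All hits of a scaffold's genes are pooled; hits scoring within
#' `top_percent` of the scaffold's best hit (score proxy: -log10 E-value)
#' are retained, and the deepest taxonomic rank shared by all retained hits
#' is the scaffold's label. The label vocabulary and inclusion semantics
#' follow genome-resolved metatranscriptome practice:
#'
#' * no hits at all: `"unassigned"`, excluded downstream;
#' * hits agree on no domain: `"cellular organisms"`, excluded;
#' * LCA falls in domain Eukaryota: `"eukaryotes"`, excluded;
#' * LCA is domain Bacteria with no phylum resolved: `"unclassified
#'   bacteria"`, included;
#' * otherwise: the LCA lineage itself, included.
#'
#' @param hits Hit tibble covering the scaffolds' genes (all hits, not just
#'   the best per gene).
#' @param genes Gene tibble with columns `gene_id`, `scaffold_id`; scaffolds
#'   listed here but without hits are reported `"unassigned"`.
#' @param top_percent Width of the score window, percent of the best score.
#' @return Tibble with columns `scaffold_id`, `label`, `lineage`, `include`.
#' @export
lca_assign <- function(hits, genes, top_percent = 10) {
  stopifnot(top_percent > 0, top_percent <= 100)
  pooled <- hits |>
    dplyr::inner_join(dplyr::distinct(genes, .data$gene_id, .data$scaffold_id),
                      by = "gene_id")
  labelled <- if (nrow(pooled) == 0L) {
    tibble::tibble(scaffold_id = character(0), label = character(0),
                   lineage = character(0), include = logical(0))
  } else {
    pooled |>
      dplyr::group_by(.data$scaffold_id) |>
      dplyr::group_modify(~ lca_one_scaffold(.x, top_percent)) |>
      dplyr::ungroup()
  }
  missing <- setdiff(unique(genes$scaffold_id), labelled$scaffold_id)
  if (length(missing) > 0L) {
    labelled <- dplyr::bind_rows(labelled, tibble::tibble(
      scaffold_id = missing, label = "unassigned", lineage = "",
      include = FALSE))
  }
  dplyr::arrange(labelled, .data$scaffold_id)
}

lca_one_scaffold <- function(h, top_percent) {
  if (nrow(h) == 0L) {
    return(tibble::tibble(label = character(0), lineage = character(0),
                          include = logical(0)))
  }
  score <- -log10(pmax(h$evalue, 1e-300))
  keep <- score >= max(score) * (1 - top_percent / 100)
  lca <- lineage_lca(h$lineage[keep])
  lca_label(lca)
}

lca_label <- function(lca) {
  parts <- lineage_split(lca)[[1]]
  depth <- length(parts)
  if (depth == 0L) {
    return(tibble::tibble(label = "cellular organisms", lineage = "",
                          include = FALSE))
  }
  domain <- parts[[1]]
  if (identical(domain, "Eukaryota")) {
    return(tibble::tibble(label = "eukaryotes", lineage = lca, include = FALSE))
  }
  has_phylum <- depth >= match("phylum", lineage_ranks())
  if (identical(domain, "Bacteria") && !has_phylum) {
    return(tibble::tibble(label = "unclassified bacteria", lineage = lca,
                          include = TRUE))
  }
  tibble::tibble(label = lca, lineage = lca, include = TRUE)
}
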