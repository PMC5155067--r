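# Community ecology metrics on OTU or bin-abundance tables: singleton
# removal, richness, Shannon diversity, Pielou's evenness, and the
# Bray-Curtis/UPGMA abundance tree.

#' Remove singleton taxa from an abundance table
#'
#' A singleton is a taxon whose total count across all samples is at most
#' one; such rows inflate variance in diversity estimates and are dropped
#' before analysis. The operation is idempotent and never increases
#' richness.
#'
#' @param table Abundance tibble: id column (first by default) + integer
#'   count columns per sample.
#' @param id Name of the id column.
#' @return The table without singleton rows.
#' @export
remove_singletons <- function(table, id = NULL) {
  if (nrow(table) == 0L) return(table)
  if (is.null(id)) id <- names(table)[1]
  samples <- setdiff(names(table), id)
  counts <- as.matrix(table[samples])
  if (any(counts != floor(counts))) {
    stop("singleton removal requires integer counts", call. = FALSE)
  }
  table[rowSums(counts) > 1, , drop = FALSE]
}

#' Shannon diversity of one sample
#'
#' H = -sum p_i ln p_i over taxa with positive abundance (natural log).
#'
#' @param x Non-negative abundance vector with at least one positive entry.
#' @return Shannon index H.
#' @export
shannon_index <- function(x) {
  stopifnot(all(x >= 0), any(x > 0))
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' Richness (number of observed taxa) of one sample
#'
#' @inheritParams shannon_index
#' @return Count of taxa with positive abundance.
#' @export
richness <- function(x) {
  stopifnot(all(x >= 0))
  as.integer(vegan::specnumber(x))
}

#' Pielou's evenness from Shannon diversity and richness
#'
#' J = H / ln S; 1 means a perfectly even community. Undefined (NA) for
#' S = 1, where ln S = 0.
#'
#' @param H Shannon diversity (natural log).
#' @param S Richness (positive integer count).
#' @return Evenness J in `[0, 1]`, or `NA` when S < 2.
#' @export
pielou <- function(H, S) {
  stopifnot(length(H) == length(S), all(S >= 1))
  ifelse(S >= 2, H / log(S), NA_real_)
}

#' Per-sample diversity report
#'
#' Computes richness, Shannon diversity and Pielou's evenness for every
#' sample column of an abundance table. Apply [remove_singletons()] first
#' when working from raw OTU counts.
#'
#' @inheritParams remove_singletons
#' @return Tibble with columns `sample`, `richness`, `shannon`, `pielou`.
#' @export
diversity_metrics <- function(table, id = NULL) {
  if (is.null(id)) id <- names(table)[1]
  samples <- setdiff(names(table), id)
  purrr::map_dfr(samples, function(s) {
    x <- table[[s]]
    S <- richness(x)
    H <- if (S > 0) shannon_index(x) else NA_real_
    tibble::tibble(sample = s, richness = S, shannon = H,
                   pielou = if (S >= 2) pielou(H, S) else NA_real_)
  })
}

#' Abundance distance tree of samples
#'
#' Samples are placed on a dendrogram by their community composition:
#' per-sample relative abundances, pairwise Bray-Curtis distances, and
#' UPGMA (average-linkage) agglomeration. Identical samples sit at zero
#' distance; `hclust` breaks ties by input order, so the result is
#' deterministic.
#'
#' @inheritParams remove_singletons
#' @param method Distance measure, passed to [vegan::vegdist()].
#' @param linkage Agglomeration method, passed to [stats::hclust()]
#'   (`"average"` = UPGMA).
#' @param relative Divide each sample by its total before computing
#'   distances (default `TRUE`).
#' @return An [ape::phylo] tree with samples as tips and branch lengths
#'   from the merge heights.
#' @export
distance_tree <- function(table, id = NULL, method = "bray",
                          linkage = "average", relative = TRUE) {
  if (is.null(id)) id <- names(table)[1]
  samples <- setdiff(names(table), id)
  if (length(samples) < 2L) stop("need at least two samples", call. = FALSE)
  m <- t(as.matrix(table[samples]))
  rownames(m) <- samples
  if (relative) {
    totals <- rowSums(m)
    if (any(totals <= 0)) stop("every sample needs a positive total", call. = FALSE)
    m <- m / totals
  }
  d <- vegan::vegdist(m, method = method)
  ape::as.phylo(stats::hclust(d, method = linkage))
}
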