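# Functional annotation reconciliation: EC transfer by identity/coverage
# thresholds, dual KO+EC enzyme classification with the cellobiosidase
# EC-only exception, the KO/EC agreement ratio, and ionic-liquid tolerance
# flagging. KO and EC columns hold comma-separated id sets ("" = empty).

#' Built-in enzyme class definitions
#'
#' The five lignocellulose-degradation / acetate-metabolism enzyme classes
#' tracked by the pipeline, each defined by a KEGG Orthology (KO) id set and
#' an Enzyme Commission (EC) number. `requires_both` is `FALSE` only for
#' cellulose 1,4-beta-cellobiosidase, whose KO annotations agree poorly with
#' EC assignments, so membership there rests on the EC number alone.
#'
#' @return Tibble with columns `class`, `ko` (list), `ec` (list),
#'   `requires_both`.
#' @export
enzyme_classes <- function() {
  tibble::tibble(
    class = c("endoglucanase", "cellulose 1,4-beta-cellobiosidase",
              "beta-glucosidase", "xylanase", "acetate kinase"),
    ko = list(c("K01179", "K19356", "K19357", "K20542"),
              c("K01225", "K19668"),
              c("K01188", "K05349", "K05350"),
              c("K01181", "K13465"),
              "K00925"),
    ec = list("3.2.1.4", "3.2.1.91", "3.2.1.21", "3.2.1.8", "2.7.2.1"),
    requires_both = c(TRUE, FALSE, TRUE, TRUE, TRUE))
}

#' Reference ionic-liquid tolerance genes
#'
#' Efflux pump and small-multidrug-resistance genes with demonstrated
#' tolerance of imidazolium ionic liquids.
#'
#' @return Character vector of gene names used as reference subject ids.
#' @export
il_tolerance_genes <- function() {
  c("eilA", "sugE", "emrE", "smvA", "ykkC", "ykkD")
}

split_ids <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    stringr::str_trim(stringr::str_split_1(s, ","))
  })
}

#' Transfer EC numbers from a reference annotation by homology
#'
#' A gene receives the EC number of its closest reference hit when the hit
#' has at least `min_identity` percent identity and at least `min_coverage`
#' percent query coverage (both thresholds inclusive). Hits to reference
#' genes lacking an EC are ignored before closest-hit selection.
#'
#' @param ref_hits Hit tibble of query genes against the reference gene set
#'   (`subject_id` = reference gene id).
#' @param reference_ec Tibble with columns `ref_id`, `ec` mapping reference
#'   genes to EC numbers.
#' @param min_identity,min_coverage Inclusive thresholds in percent.
#' @return Tibble with columns `gene_id`, `ec` for genes that received an EC.
#' @export
transfer_ec <- function(ref_hits, reference_ec, min_identity = 95,
                        min_coverage = 40) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 100)
  usable <- ref_hits |>
    dplyr::inner_join(dplyr::distinct(reference_ec, .data$ref_id, .data$ec),
                      by = c(subject_id = "ref_id"))
  best_hits(usable) |>
    dplyr::filter(.data$pct_identity >= min_identity,
                  .data$query_coverage >= min_coverage) |>
    dplyr::select("gene_id", "ec")
}

#' Classify genes into enzyme classes from KO and EC annotations
#'
#' For classes with `requires_both = TRUE`, a gene belongs to the class only
#' when both a class KO and a class EC are present. For EC-only classes
#' (cellobiosidase), a class EC suffices, provided the gene's KO does not
#' point at a different class: a gene carrying the KO of one class and the
#' EC of another is inconsistent and left unclassified.
#'
#' @param annotations Tibble with columns `gene_id`, `ko`, `ec`; `ko`/`ec`
#'   are comma-separated id sets, `""` or `NA` meaning none.
#' @param classes Class definition tibble, see [enzyme_classes()].
#' @return The input with an `enzyme_class` column (`NA` = unclassified).
#' @export
classify_enzymes <- function(annotations, classes = enzyme_classes()) {
  stopifnot(all(c("gene_id", "ko", "ec") %in% names(annotations)))
  ko_sets <- split_ids(annotations$ko)
  ec_sets <- split_ids(annotations$ec)
  cls <- vapply(seq_len(nrow(annotations)), function(i) {
    classify_one(ko_sets[[i]], ec_sets[[i]], classes)
  }, character(1))
  annotations$enzyme_class <- dplyr::na_if(cls, "")
  annotations
}

classify_one <- function(ko, ec, classes) {
  ko_cls <- classes$class[vapply(classes$ko, function(s) any(ko %in% s), logical(1))]
  ec_cls <- classes$class[vapply(classes$ec, function(s) any(ec %in% s), logical(1))]
  if (length(ko_cls) > 1L || length(ec_cls) > 1L) {
    warning("gene matches several enzyme classes; left unclassified",
            call. = FALSE)
    return("")
  }
  if (length(ko_cls) == 1L && length(ec_cls) == 1L) {
    return(if (identical(ko_cls, ec_cls)) ko_cls else "")
  }
  if (length(ko_cls) == 0L && length(ec_cls) == 1L) {
    ec_only <- !classes$requires_both[match(ec_cls, classes$class)]
    return(if (ec_only) ec_cls else "")
  }
  ""
}

#' KO/EC agreement ratio per enzyme class
#'
#' For each class: 100 x (genes carrying both a class KO and a class EC) /
#' (genes carrying a class KO). Classes with no KO-annotated genes are
#' reported as `NA` rather than zero.
#'
#' @inheritParams classify_enzymes
#' @return Tibble with columns `class`, `n_ko`, `n_match`, `agreement_pct`.
#' @export
ko_ec_agreement <- function(annotations, classes = enzyme_classes()) {
  ko_sets <- split_ids(annotations$ko)
  ec_sets <- split_ids(annotations$ec)
  purrr::pmap_dfr(classes, function(class, ko, ec, requires_both) {
    has_ko <- vapply(ko_sets, function(s) any(s %in% ko), logical(1))
    has_ec <- vapply(ec_sets, function(s) any(s %in% ec), logical(1))
    n_ko <- sum(has_ko)
    n_match <- sum(has_ko & has_ec)
    tibble::tibble(class = class, n_ko = n_ko, n_match = n_match,
                   agreement_pct = if (n_ko > 0) 100 * n_match / n_ko else NA_real_)
  })
}

#' Flag genes homologous to ionic-liquid tolerance genes
#'
#' A gene is flagged when any of its hits against the reference tolerance
#' gene set has an E-value at or below the cutoff (inclusive).
#'
#' @param hits Hit tibble of genes against the tolerance gene references.
#' @param evalue_cutoff Inclusive E-value threshold.
#' @param reference_ids Subject ids counted as tolerance genes.
#' @return Tibble with columns `gene_id`, `il_tolerance` covering every gene
#'   present in `hits`.
#' @export
flag_il_tolerance <- function(hits, evalue_cutoff = 1e-5,
                              reference_ids = il_tolerance_genes()) {
  hits |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      il_tolerance = any(.data$subject_id %in% reference_ids &
                           .data$evalue <= evalue_cutoff),
      .groups = "drop")
}
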