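# Orchestration: a configurable end-to-end run over the module functions,
# writing one report file per stage plus a resolved-config dump and an
# output manifest. The exported functions are the interface; a thin Rscript
# wrapper lives in inst/scripts/bintrans-pipeline.R.

#' Pipeline configuration
#'
#' Collects every tunable threshold with the field-standard defaults: EC
#' transfer at >= 95% identity and >= 40% coverage, ionic-liquid tolerance
#' flagging at E <= 1e-5, an LCA score window of 10%, and top-5 transcriber
#' shares.
#'
#' @param input_dir Directory holding the input tables (as written by
#'   [write_community()]).
#' @param out_dir Directory for report files.
#' @param min_identity,min_coverage EC transfer thresholds (percent,
#'   inclusive).
#' @param evalue_cutoff Ionic-liquid tolerance E-value cutoff (inclusive).
#' @param top_percent LCA score window, percent of the best hit score.
#' @param k Number of top bins for the transcription share.
#' @param denominator `"included"` or `"binned"`, see [top_k_share()].
#' @param distance_method,linkage Distance-tree settings, see
#'   [distance_tree()].
#' @param molar_volume Gas molar volume for respirometry, L mol^-1.
#' @param seed Seed for the simulate stage.
#' @param sim A [sim_config()] used by the simulate stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir = file.path(input_dir, "reports"),
                            min_identity = 95, min_coverage = 40,
                            evalue_cutoff = 1e-5, top_percent = 10, k = 5,
                            denominator = "included",
                            distance_method = "bray", linkage = "average",
                            molar_volume = 24, seed = 1,
                            sim = sim_config(seed = seed)) {
  structure(list(
    input_dir = input_dir, out_dir = out_dir,
    min_identity = min_identity, min_coverage = min_coverage,
    evalue_cutoff = evalue_cutoff, top_percent = top_percent, k = k,
    denominator = denominator, distance_method = distance_method,
    linkage = linkage, molar_volume = molar_volume, seed = seed, sim = sim),
    class = "pipeline_config")
}

input_path <- function(config, file) {
  path <- file.path(config$input_dir, file)
  if (!file.exists(path)) {
    rlang::abort(paste0("missing input file: ", path),
                 class = "bintrans_missing_input")
  }
  path
}

#' Map every gene to its transcription group with inclusion flags
#'
#' Genes on binned scaffolds group by bin (`included` = not a eukaryote
#' bin); genes on unbinned scaffolds group by their LCA label as
#' `"unbinned:<label>"` with the label's inclusion flag (eukaryotes,
#' cellular organisms and unassigned scaffolds are excluded from
#' prokaryotic totals).
#'
#' @param genes Gene tibble with `gene_id`, `scaffold_id`.
#' @param bin_map Scaffold membership tibble (`scaffold_id`, `bin_id`).
#' @param bin_tax Output of [vote_bin_taxonomy()].
#' @param scaffold_labels Output of [lca_assign()] for unbinned scaffolds.
#' @return Tibble `gene_id`, `group`, `included`.
#' @export
transcription_grouping <- function(genes, bin_map, bin_tax, scaffold_labels) {
  genes[, c("gene_id", "scaffold_id")] |>
    dplyr::left_join(bin_map, by = "scaffold_id") |>
    dplyr::left_join(bin_tax[, c("bin_id", "is_eukaryote")], by = "bin_id") |>
    dplyr::left_join(scaffold_labels[, c("scaffold_id", "label", "include")],
                     by = "scaffold_id") |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      group = dplyr::if_else(!is.na(.data$bin_id), .data$bin_id,
                             paste0("unbinned:",
                                    dplyr::coalesce(.data$label, "unassigned"))),
      included = dplyr::if_else(!is.na(.data$bin_id),
                                !dplyr::coalesce(.data$is_eukaryote, FALSE),
                                dplyr::coalesce(.data$include, FALSE)))
}

#' Map every gene to a phylum-level group
#'
#' Binned genes take the phylum of their bin's voted lineage; unbinned
#' genes take the phylum of the scaffold's LCA lineage, falling back on the
#' LCA label ("unclassified bacteria" etc.) when no phylum is resolved.
#'
#' @inheritParams transcription_grouping
#' @return Tibble `gene_id`, `group`, `included`.
#' @export
phylum_grouping <- function(genes, bin_map, bin_tax, scaffold_labels) {
  bt <- bin_tax |>
    dplyr::mutate(bin_phylum = dplyr::coalesce(
      lineage_at_rank(.data$lineage, "phylum"), .data$lineage))
  sl <- scaffold_labels |>
    dplyr::mutate(scf_phylum = dplyr::coalesce(
      lineage_at_rank(.data$lineage, "phylum"), .data$label))
  genes[, c("gene_id", "scaffold_id")] |>
    dplyr::left_join(bin_map, by = "scaffold_id") |>
    dplyr::left_join(bt[, c("bin_id", "bin_phylum", "is_eukaryote")],
                     by = "bin_id") |>
    dplyr::left_join(sl[, c("scaffold_id", "scf_phylum", "include")],
                     by = "scaffold_id") |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      group = dplyr::if_else(!is.na(.data$bin_id), .data$bin_phylum,
                             dplyr::coalesce(.data$scf_phylum, "unassigned")),
      included = dplyr::if_else(!is.na(.data$bin_id),
                                !dplyr::coalesce(.data$is_eukaryote, FALSE),
                                dplyr::coalesce(.data$include, FALSE)))
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (generate a synthetic community and respirometry
#' trace into `input_dir`), `taxonomy` (bin voting + LCA labels),
#' `annotate` (EC transfer, enzyme classification, KO/EC agreement, IL
#' tolerance), `quantify` (RPKM, bin/phylum/class expression, top-k
#' shares), `ecology` (diversity report, distance tree), `respire`
#' (CER/cCER), or `all` for the full chain. Each stage writes its report
#' files under `out_dir`; the resolved configuration and an MD5 manifest of
#' outputs are written alongside.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stage names, or `"all"`.
#' @return Named list of written report paths, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "taxonomy", "annotate", "quantify", "ecology",
                  "respire")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  written <- character(0)

  if ("simulate" %in% stages) {
    sim <- simulate_community(config$sim)
    files <- write_community(sim, config$input_dir)
    trace <- simulate_respirometry()
    write_resp_trace(trace, file.path(config$input_dir, "resp.tsv"))
    written <- c(written, files, resp = file.path(config$input_dir, "resp.tsv"))
  }

  needs_tax <- any(c("taxonomy", "quantify") %in% stages)
  if (needs_tax) {
    genes <- read_gff(input_path(config, "genes.gff"))
    bin_map <- read_bin_map(input_path(config, "bin_map.tsv"))
    hits <- read_hits(input_path(config, "hits.tsv"))
    gene_scf <- genes |>
      dplyr::left_join(bin_map, by = "scaffold_id")
    gene_bins <- gene_scf |>
      dplyr::filter(!is.na(.data$bin_id)) |>
      dplyr::select("gene_id", "bin_id")
    bin_tax <- vote_bin_taxonomy(hits, gene_bins)
    unbinned_genes <- gene_scf |>
      dplyr::filter(is.na(.data$bin_id)) |>
      dplyr::select("gene_id", "scaffold_id")
    scaffold_labels <- lca_assign(hits, unbinned_genes,
                                  top_percent = config$top_percent)
    if ("taxonomy" %in% stages) {
      readr::write_tsv(bin_tax, out("bin_taxonomy.tsv"), progress = FALSE)
      readr::write_tsv(scaffold_labels, out("scaffold_labels.tsv"),
                       progress = FALSE)
      written <- c(written, out("bin_taxonomy.tsv"), out("scaffold_labels.tsv"))
    }
  }

  if (any(c("annotate", "quantify") %in% stages)) {
    ko <- read_tsv_quiet(input_path(config, "ko.tsv"))
    ref_ec <- read_tsv_quiet(input_path(config, "reference_ec.tsv"))
    ref_hits <- read_hits(input_path(config, "ref_hits.tsv"))
    il_hits <- read_hits(input_path(config, "il_hits.tsv"))
    ec <- transfer_ec(ref_hits, ref_ec, config$min_identity,
                      config$min_coverage)
    ann <- dplyr::full_join(
      ko |> dplyr::group_by(.data$gene_id) |>
        dplyr::summarise(ko = paste(.data$ko, collapse = ","), .groups = "drop"),
      ec |> dplyr::group_by(.data$gene_id) |>
        dplyr::summarise(ec = paste(.data$ec, collapse = ","), .groups = "drop"),
      by = "gene_id") |>
      dplyr::mutate(ko = dplyr::coalesce(.data$ko, ""),
                    ec = dplyr::coalesce(.data$ec, ""))
    ann <- classify_enzymes(ann)
    il <- flag_il_tolerance(il_hits, config$evalue_cutoff)
    ann <- ann |>
      dplyr::left_join(il, by = "gene_id") |>
      dplyr::mutate(il_tolerance = dplyr::coalesce(.data$il_tolerance, FALSE))
    if ("annotate" %in% stages) {
      readr::write_tsv(ann, out("annotation.tsv"), progress = FALSE)
      readr::write_tsv(ko_ec_agreement(ann), out("ko_ec_agreement.tsv"),
                       progress = FALSE)
      written <- c(written, out("annotation.tsv"), out("ko_ec_agreement.tsv"))
    }
  }

  if ("quantify" %in% stages) {
    counts <- read_counts(input_path(config, "counts.tsv"))
    rpkm <- compute_rpkm(counts, genes)
    grouping <- transcription_grouping(genes, bin_map, bin_tax, scaffold_labels)
    bin_expr <- aggregate_expression(rpkm, grouping)
    ph_expr <- aggregate_expression(
      rpkm, phylum_grouping(genes, bin_map, bin_tax, scaffold_labels))
    class_expr <- aggregate_expression(
      rpkm, ann |>
        dplyr::filter(!is.na(.data$enzyme_class)) |>
        dplyr::select(gene_id = "gene_id", group = "enzyme_class"))
    shares <- dplyr::bind_rows(
      top_k_share(bin_expr, k = config$k, denominator = "included") |>
        dplyr::mutate(denominator = "included"),
      top_k_share(bin_expr, k = config$k, denominator = "binned") |>
        dplyr::mutate(denominator = "binned"))
    readr::write_tsv(rpkm, out("rpkm.tsv"), progress = FALSE)
    readr::write_tsv(bin_expr, out("bin_expression.tsv"), progress = FALSE)
    readr::write_tsv(ph_expr, out("phylum_expression.tsv"), progress = FALSE)
    readr::write_tsv(class_expr, out("class_expression.tsv"), progress = FALSE)
    readr::write_tsv(shares, out("top_share.tsv"), progress = FALSE)
    written <- c(written, out("rpkm.tsv"), out("bin_expression.tsv"),
                 out("phylum_expression.tsv"), out("class_expression.tsv"),
                 out("top_share.tsv"))
  }

  if ("ecology" %in% stages) {
    otu <- read_abundance(input_path(config, "otu.tsv"))
    div <- diversity_metrics(remove_singletons(otu))
    coverage <- read_abundance(input_path(config, "coverage.tsv"))
    tree <- distance_tree(coverage, method = config$distance_method,
                          linkage = config$linkage)
    readr::write_tsv(div, out("diversity.tsv"), progress = FALSE)
    write_newick(tree, out("abundance_tree.nwk"))
    written <- c(written, out("diversity.tsv"), out("abundance_tree.nwk"))
  }

  if ("respire" %in% stages) {
    trace <- read_resp_trace(input_path(config, "resp.tsv"))
    trace <- compute_cer(trace, molar_volume = config$molar_volume)
    trace$ccer <- integrate_ccer(trace$time, trace$cer, cumulative = TRUE)
    readr::write_tsv(trace, out("respirometry.tsv"), progress = FALSE)
    written <- c(written, out("respirometry.tsv"))
  }

  cfg_flat <- config[setdiff(names(config), "sim")]
  readr::write_tsv(tibble::tibble(
    key = names(cfg_flat),
    value = vapply(cfg_flat, function(v) paste(format(v), collapse = ","),
                   character(1))),
    out("config.tsv"), progress = FALSE)
  manifest <- tibble::tibble(file = basename(written),
                             md5 = unname(tools::md5sum(written)))
  readr::write_tsv(manifest, out("run_manifest.tsv"), progress = FALSE)
  invisible(as.list(written))
}
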