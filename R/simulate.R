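# Synthetic community generator with planted ground truth. Emulates the
# study design the pipeline targets: a multi-phylum genome-bin set whose
# relative abundance shifts along an ionic-liquid treatment gradient,
# genes with log-normal length variation, best-hit records with noisy
# lineages, KO/EC annotations with a controlled consistency rate,
# negative-binomial transcript counts with planted per-bin expression
# profiles, and OTU tables with planted evenness. No sequence-level
# simulation: the files start where assembly/binning/alignment end.

phylum_pool <- c("Proteobacteria", "Firmicutes", "Actinobacteria",
                 "Bacteroidetes", "Chloroflexi", "Planctomycetes",
                 "Verrucomicrobia", "Acidobacteria")

kingdom_for <- function(phylum) {
  ifelse(phylum %in% c("Firmicutes", "Actinobacteria", "Chloroflexi"),
         "Terrabacteria", "Gracilicutes")
}

#' Configuration for the synthetic community generator
#'
#' Defaults reproduce the study conditions the package targets: five samples
#' along an ionic-liquid (IL) treatment gradient (inoculum, 0%, 0.5%, 1%,
#' 2% IL) in which Proteobacteria dominance gives way to Firmicutes, genome
#' bins of 150-250 genes with log-normal gene lengths around 900 bp, and
#' moderate annotation/taxonomy noise.
#'
#' @param n_bins Number of prokaryotic genome bins (>= 1).
#' @param n_phyla Number of phyla the bins are spread over (1-8).
#' @param genes_per_bin Integer range `c(min, max)` of genes per bin.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal law of gene
#'   lengths in bp.
#' @param n_samples Number of samples along the treatment gradient.
#' @param sample_names Optional sample names; default `inoculum, IL0, IL0.5,
#'   IL1, IL2` when `n_samples == 5`.
#' @param abundance_profiles Optional bin-by-sample matrix of non-negative
#'   weights; default is a planted gradient (see Details).
#' @param top5_share Optional target share (fraction in (0, 1]) of expression
#'   carried by the first five bins in every sample; when set, abundances
#'   are rescaled so the planted share is exact.
#' @param dispersion Negative-binomial dispersion shared by all genes
#'   (`size = 1/dispersion`).
#' @param depth Expected per-sample library size (reads).
#' @param depth_factors Optional per-sample depth multipliers.
#' @param annotation_consistency Probability that a planted enzyme gene's
#'   transferred EC agrees with its KO class.
#' @param taxonomy_noise Probability that a gene's best hit reports a wrong
#'   lineage (species and genus replaced; phylum kept with probability 0.5).
#' @param unbinned_fraction Fraction of each bin's scaffolds withheld from
#'   the membership table to create the unbinned pool.
#' @param genes_per_scaffold Approximate genes per scaffold.
#' @param class_genes_per_bin Planted genes per enzyme class per bin.
#' @param eukaryote_bins Number of additional eukaryote bins (excluded from
#'   prokaryotic totals downstream).
#' @param n_otus,otu_depth,otu_evenness OTU table size, sequencing depth and
#'   per-sample target Pielou evenness (default declines along the
#'   gradient from 0.60 to 0.35).
#' @param n_singleton_otus Singleton OTUs added to exercise removal.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_bins = 40, n_phyla = 6, genes_per_bin = c(150, 250),
                       gene_length_meanlog = log(900), gene_length_sdlog = 0.35,
                       n_samples = 5, sample_names = NULL,
                       abundance_profiles = NULL, top5_share = NULL,
                       dispersion = 0.3, depth = 2e6, depth_factors = NULL,
                       annotation_consistency = 0.9, taxonomy_noise = 0.1,
                       unbinned_fraction = 0.1, genes_per_scaffold = 10,
                       class_genes_per_bin = 2, eukaryote_bins = 0,
                       n_otus = 220, otu_depth = 20000, otu_evenness = NULL,
                       n_singleton_otus = 10, seed = 1) {
  stopifnot(n_bins >= 1, n_phyla >= 1, n_samples >= 1,
            length(genes_per_bin) == 2, all(genes_per_bin >= 1),
            genes_per_bin[1] <= genes_per_bin[2],
            dispersion > 0, depth > 0, genes_per_scaffold >= 1,
            class_genes_per_bin >= 0, eukaryote_bins >= 0,
            n_otus >= 2, otu_depth >= 1)
  for (p in c(annotation_consistency, taxonomy_noise, unbinned_fraction)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(sample_names)) {
    sample_names <- if (n_samples == 5) {
      c("inoculum", "IL0", "IL0.5", "IL1", "IL2")
    } else paste0("S", seq_len(n_samples))
  }
  stopifnot(length(sample_names) == n_samples)
  if (!is.null(abundance_profiles)) {
    abundance_profiles <- as.matrix(abundance_profiles)
    stopifnot(nrow(abundance_profiles) == n_bins,
              ncol(abundance_profiles) == n_samples,
              all(abundance_profiles >= 0),
              all(colSums(abundance_profiles) > 0))
  }
  if (!is.null(top5_share)) {
    stopifnot(top5_share > 0, top5_share <= 1, n_bins > 5)
  }
  if (is.null(depth_factors)) depth_factors <- rep(1, n_samples)
  stopifnot(length(depth_factors) == n_samples, all(depth_factors > 0))
  if (is.null(otu_evenness)) {
    otu_evenness <- if (n_samples == 1) 0.6 else
      seq(0.60, 0.35, length.out = n_samples)
  }
  stopifnot(length(otu_evenness) == n_samples,
            all(otu_evenness > 0), all(otu_evenness <= 1))
  structure(list(
    n_bins = n_bins, n_phyla = n_phyla, genes_per_bin = genes_per_bin,
    gene_length_meanlog = gene_length_meanlog,
    gene_length_sdlog = gene_length_sdlog,
    n_samples = n_samples, sample_names = sample_names,
    abundance_profiles = abundance_profiles, top5_share = top5_share,
    dispersion = dispersion, depth = depth, depth_factors = depth_factors,
    annotation_consistency = annotation_consistency,
    taxonomy_noise = taxonomy_noise, unbinned_fraction = unbinned_fraction,
    genes_per_scaffold = genes_per_scaffold,
    class_genes_per_bin = class_genes_per_bin,
    eukaryote_bins = eukaryote_bins,
    n_otus = n_otus, otu_depth = otu_depth, otu_evenness = otu_evenness,
    n_singleton_otus = n_singleton_otus, seed = seed),
    class = "sim_config")
}

# Default gradient: Proteobacteria-like phylum fades (0.55 -> 0.08) while a
# Firmicutes-like phylum takes over (0.12 -> 0.75); remaining phyla share
# the remainder equally. The response is sigmoidal in gradient position so
# the two no-treatment samples resemble each other, as do the two
# high-treatment samples, with the mid sample between the regimes.
# Per-bin weights get a log-normal jitter.
default_profiles <- function(cfg, phylum_of) {
  ns <- cfg$n_samples
  pos <- if (ns == 1) 0.5 else seq(0, 1, length.out = ns)
  shape <- stats::plogis((pos - 0.5) * 12)
  w_proteo <- 0.55 - 0.47 * shape
  w_firm <- 0.12 + 0.63 * shape
  rest <- pmax(1 - w_proteo - w_firm, 0.02)
  phyla <- unique(phylum_of)
  nph <- length(phyla)
  phylum_w <- matrix(rest / max(nph - 2, 1), nrow = nph, ncol = ns,
                     dimnames = list(phyla, NULL))
  if ("Proteobacteria" %in% phyla) phylum_w["Proteobacteria", ] <- w_proteo
  if ("Firmicutes" %in% phyla) phylum_w["Firmicutes", ] <- w_firm
  bins_in <- table(phylum_of)
  jitter <- matrix(stats::rlnorm(cfg$n_bins * ns, 0, 0.15), cfg$n_bins, ns)
  prof <- phylum_w[phylum_of, , drop = FALSE] /
    as.numeric(bins_in[phylum_of]) * jitter
  unname(prof)
}

#' Generate a synthetic binned community with planted ground truth
#'
#' Produces all tables the pipeline consumes — gene models, scaffold-to-bin
#' membership, best-hit records against a mock protein reference, KO
#' annotations, a reference EC table with query-vs-reference hits,
#' a negative-binomial gene-by-sample count matrix (mean proportional to
#' bin abundance x gene length x per-gene expression factor), bin
#' coverages, and an OTU table with planted evenness — together with the
#' ground truth needed to score recovery.
#'
#' @param config A [sim_config()].
#' @return A `community_sim` object: a list of tibbles (`genes`, `bin_map`,
#'   `hits`, `ko`, `reference_ec`, `ref_hits`, `il_hits`, `counts`,
#'   `coverage`, `otu`) plus `truth` and `config`.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_community_impl(config))
}

simulate_community_impl <- function(cfg) {
  n_prok <- cfg$n_bins
  n_all <- n_prok + cfg$eukaryote_bins
  bin_ids <- sprintf("bin%03d", seq_len(n_all))
  phyla <- if (cfg$n_phyla <= length(phylum_pool)) {
    phylum_pool[seq_len(cfg$n_phyla)]
  } else c(phylum_pool, paste0("Phylum", seq_len(cfg$n_phyla - length(phylum_pool))))
  phylum_of <- phyla[(seq_len(n_prok) - 1L) %% cfg$n_phyla + 1L]

  lineages <- vapply(seq_len(n_all), function(b) {
    if (b <= n_prok) {
      ph <- phylum_of[b]
      lineage_join(c("Bacteria", kingdom_for(ph), ph,
                     sprintf("Class_%03d", b), sprintf("Order_%03d", b),
                     sprintf("Family_%03d", b), sprintf("Genus_%03d", b),
                     sprintf("Genus_%03d species_%03d", b, b)))
    } else {
      lineage_join(c("Eukaryota", "Fungi", "Ascomycota",
                     sprintf("EukClass_%03d", b), sprintf("EukOrder_%03d", b),
                     sprintf("EukFamily_%03d", b), sprintf("EukGenus_%03d", b),
                     sprintf("EukGenus_%03d sp_%03d", b, b)))
    }
  }, character(1))

  # -- gene models -----------------------------------------------------------
  n_genes_bin <- sample(cfg$genes_per_bin[1]:cfg$genes_per_bin[2], n_all,
                        replace = TRUE)
  genes <- purrr::map_dfr(seq_len(n_all), function(b) {
    n <- n_genes_bin[b]
    len <- pmax(100L, as.integer(round(stats::rlnorm(
      n, cfg$gene_length_meanlog, cfg$gene_length_sdlog))))
    scf_idx <- ceiling(seq_len(n) / cfg$genes_per_scaffold)
    df <- tibble::tibble(
      bin_id = bin_ids[b],
      scaffold_id = sprintf("%s_scf%03d", bin_ids[b], scf_idx),
      length = len,
      strand = sample(c("+", "-"), n, replace = TRUE))
    df |>
      dplyr::group_by(.data$scaffold_id) |>
      dplyr::mutate(start = cumsum(dplyr::lag(.data$length + 50L, default = 1L)),
                    end = .data$start + .data$length - 1L) |>
      dplyr::ungroup()
  })
  genes$gene_id <- sprintf("g%06d", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "scaffold_id", "bin_id", "start", "end",
                     "strand", "length")]

  # unbinned pool: withhold each scaffold with probability unbinned_fraction,
  # keeping at least one scaffold per bin in the membership table
  scaffolds <- genes |>
    dplyr::distinct(.data$scaffold_id, .data$bin_id)
  withheld <- stats::runif(nrow(scaffolds)) < cfg$unbinned_fraction
  bin_map <- scaffolds |>
    dplyr::mutate(withheld = withheld) |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::mutate(withheld = .data$withheld & !(dplyr::row_number() == 1L &
                                                  all(.data$withheld))) |>
    dplyr::ungroup() |>
    dplyr::filter(!.data$withheld) |>
    dplyr::select("scaffold_id", "bin_id") |>
    dplyr::arrange(.data$scaffold_id)

  # -- best hits against the mock protein reference --------------------------
  aai_mean <- stats::runif(n_all, 70, 99)
  names(aai_mean) <- bin_ids
  b_idx <- match(genes$bin_id, bin_ids)
  identity <- pmin(100, pmax(50, stats::rnorm(
    nrow(genes), aai_mean[b_idx], 3)))
  wrong <- stats::runif(nrow(genes)) < cfg$taxonomy_noise
  wrong[b_idx > n_prok] <- FALSE  # eukaryote hits stay clean
  hit_lineage <- lineages[b_idx]
  if (any(wrong)) {
    hit_lineage[wrong] <- vapply(which(wrong), function(i) {
      b <- b_idx[i]
      keep_phylum <- stats::runif(1) < 0.5
      ph <- if (keep_phylum || cfg$n_phyla == 1) phylum_of[b] else
        sample(setdiff(phyla, phylum_of[b]), 1)
      k <- sample.int(10000L, 1)
      lineage_join(c("Bacteria", kingdom_for(ph), ph,
                     sprintf("NoiseClass_%04d", k), sprintf("NoiseOrder_%04d", k),
                     sprintf("NoiseFamily_%04d", k), sprintf("NoiseGenus_%04d", k),
                     sprintf("NoiseGenus_%04d sp_%04d", k, k)))
    }, character(1))
  }
  hits <- tibble::tibble(
    gene_id = genes$gene_id,
    subject_id = sprintf("NR%07d", sample.int(9999999L, nrow(genes))),
    pct_identity = round(identity, 1),
    aln_len = as.integer(round(genes$length / 3)),
    evalue = 10^-stats::runif(nrow(genes), 20, 180),
    query_coverage = round(stats::runif(nrow(genes), 50, 100), 1),
    lineage = hit_lineage)

  # -- planted enzyme classes and KO/EC annotations --------------------------
  classes <- enzyme_classes()
  n_class <- nrow(classes)
  class_plan <- NULL
  if (cfg$class_genes_per_bin > 0) {
    class_plan <- purrr::map_dfr(seq_len(n_prok), function(b) {
      pool <- genes$gene_id[genes$bin_id == bin_ids[b]]
      need <- n_class * cfg$class_genes_per_bin
      if (length(pool) < need) {
        stop("bins too small to hold the planted enzyme genes", call. = FALSE)
      }
      picked <- sample(pool, need)
      tibble::tibble(gene_id = picked,
                     class = rep(classes$class, each = cfg$class_genes_per_bin))
    })
  }
  ko_tbl <- tibble::tibble(gene_id = character(0), ko = character(0))
  ref_ec <- tibble::tibble(ref_id = character(0), ec = character(0))
  ref_hits <- hits[0, ]
  truth_class <- tibble::tibble(gene_id = character(0), class = character(0),
                                consistent = logical(0))
  if (!is.null(class_plan) && nrow(class_plan) > 0) {
    ref_ec <- tibble::tibble(
      ref_id = sprintf("REF_%s", gsub("[^A-Za-z0-9]+", "_", classes$class)),
      ec = vapply(classes$ec, `[[`, character(1), 1))
    ci <- match(class_plan$class, classes$class)
    ko_tbl <- tibble::tibble(
      gene_id = class_plan$gene_id,
      ko = vapply(ci, function(i) sample(classes$ko[[i]], 1), character(1)))
    consistent <- stats::runif(nrow(class_plan)) < cfg$annotation_consistency
    ec_class_idx <- ifelse(consistent, ci, vapply(ci, function(i) {
      sample(setdiff(seq_len(n_class), i), 1)
    }, integer(1)))
    gl <- genes$length[match(class_plan$gene_id, genes$gene_id)]
    ref_hits <- tibble::tibble(
      gene_id = class_plan$gene_id,
      subject_id = ref_ec$ref_id[ec_class_idx],
      pct_identity = round(stats::runif(nrow(class_plan), 96, 99.9), 1),
      aln_len = as.integer(round(gl / 3)),
      evalue = 10^-stats::runif(nrow(class_plan), 30, 120),
      query_coverage = round(stats::runif(nrow(class_plan), 50, 95), 1),
      lineage = "")
    truth_class <- tibble::tibble(gene_id = class_plan$gene_id,
                                  class = class_plan$class,
                                  consistent = consistent)
    # decoys: sub-threshold hits that must not receive an EC
    decoy_pool <- setdiff(genes$gene_id[b_idx <= n_prok], class_plan$gene_id)
    n_decoy <- min(length(decoy_pool), max(5L, round(0.05 * length(decoy_pool))))
    decoys <- sample(decoy_pool, n_decoy)
    dl <- genes$length[match(decoys, genes$gene_id)]
    ref_hits <- dplyr::bind_rows(ref_hits, tibble::tibble(
      gene_id = decoys,
      subject_id = sample(ref_ec$ref_id, n_decoy, replace = TRUE),
      pct_identity = round(stats::runif(n_decoy, 60, 94.8), 1),
      aln_len = as.integer(round(dl / 3)),
      evalue = 10^-stats::runif(n_decoy, 6, 30),
      query_coverage = round(stats::runif(n_decoy, 41, 95), 1),
      lineage = ""))
  }

  # -- ionic-liquid tolerance hits -------------------------------------------
  il_refs <- il_tolerance_genes()
  n_il <- stats::rbinom(n_prok, 2, 0.4)
  il_rows <- purrr::map_dfr(seq_len(n_prok), function(b) {
    pool <- setdiff(genes$gene_id[genes$bin_id == bin_ids[b]], truth_class$gene_id)
    k <- n_il[b]
    if (k == 0 || length(pool) < 2 * k) return(hits[0, c("gene_id", "subject_id", "evalue")])
    picked <- sample(pool, 2 * k)
    tibble::tibble(
      gene_id = picked,
      subject_id = sample(il_refs, 2 * k, replace = TRUE),
      evalue = c(10^-stats::runif(k, 6, 30),      # flagged (<= 1e-5... strictly below)
                 10^-stats::runif(k, 1, 4.5)))    # above cutoff, not flagged
  })
  il_hits <- tibble::tibble(
    gene_id = il_rows$gene_id, subject_id = il_rows$subject_id,
    pct_identity = round(stats::runif(nrow(il_rows), 40, 90), 1),
    aln_len = 150L, evalue = il_rows$evalue,
    query_coverage = round(stats::runif(nrow(il_rows), 40, 100), 1),
    lineage = "")
  truth_il <- sort(il_hits$gene_id[il_hits$evalue <= 1e-5])

  # -- expression and counts -------------------------------------------------
  expr <- stats::rlnorm(nrow(genes), 0, 0.8)
  e_sum <- tapply(expr, genes$bin_id, sum)[bin_ids]
  prof <- cfg$abundance_profiles
  if (is.null(prof)) prof <- default_profiles(cfg, phylum_of)
  if (cfg$eukaryote_bins > 0 && nrow(prof) == n_prok) {
    prof <- rbind(prof, matrix(0.01, cfg$eukaryote_bins, cfg$n_samples))
  }
  if (!is.null(cfg$top5_share)) {
    # rescale so the first five bins carry exactly top5_share of the
    # expression weight (abundance x per-bin expression sum) in every
    # sample; the remaining bins share the rest evenly so the designated
    # five really are the top five
    s <- cfg$top5_share
    if (s / 5 <= (1 - s) / (n_all - 5)) {
      stop("top5_share infeasible: need top5_share/5 > (1-top5_share)/(n_bins-5)",
           call. = FALSE)
    }
    top <- seq_len(5)
    rest <- setdiff(seq_len(n_all), top)
    for (j in seq_len(cfg$n_samples)) {
      prof[top, j] <- (s / 5) / e_sum[top]
      prof[rest, j] <- ((1 - s) / length(rest)) / e_sum[rest]
    }
  }
  rownames(prof) <- bin_ids

  gene_w <- matrix(0, nrow(genes), cfg$n_samples)
  for (j in seq_len(cfg$n_samples)) {
    gene_w[, j] <- prof[b_idx, j] * genes$length * expr
  }
  counts <- tibble::tibble(gene_id = genes$gene_id)
  size <- 1 / cfg$dispersion
  for (j in seq_len(cfg$n_samples)) {
    mu <- cfg$depth * cfg$depth_factors[j] * gene_w[, j] / sum(gene_w[, j])
    counts[[cfg$sample_names[j]]] <- stats::rnbinom(nrow(genes), mu = mu,
                                                    size = size)
  }

  # planted expression weights and top-5 shares (RPKM scale: length cancels)
  w_rpkm <- matrix(0, n_all, cfg$n_samples, dimnames = list(bin_ids, cfg$sample_names))
  binned_scf <- bin_map$scaffold_id
  w_binned <- w_rpkm
  for (j in seq_len(cfg$n_samples)) {
    w <- prof[b_idx, j] * expr
    w_rpkm[, j] <- tapply(w, factor(genes$bin_id, bin_ids), sum)
    in_map <- genes$scaffold_id %in% binned_scf
    w_binned[, j] <- tapply(w * in_map, factor(genes$bin_id, bin_ids), sum)
  }
  prok <- seq_len(n_prok)
  top5 <- function(x) sum(sort(x, decreasing = TRUE)[seq_len(min(5, length(x)))])
  truth_top5 <- tibble::tibble(
    sample = cfg$sample_names,
    share_included = vapply(seq_len(cfg$n_samples), function(j)
      100 * top5(w_binned[prok, j]) / sum(w_rpkm[prok, j]), numeric(1)),
    share_binned = vapply(seq_len(cfg$n_samples), function(j)
      100 * top5(w_binned[prok, j]) / sum(w_binned[prok, j]), numeric(1)))

  # -- bin coverage ----------------------------------------------------------
  coverage <- tibble::tibble(bin_id = bin_ids)
  for (j in seq_len(cfg$n_samples)) {
    coverage[[cfg$sample_names[j]]] <- round(
      300 * prof[, j] / sum(prof[, j]) * stats::rlnorm(n_all, 0, 0.1), 2)
  }

  # -- OTU table with planted evenness ---------------------------------------
  otu <- tibble::tibble(otu_id = sprintf("OTU%04d", seq_len(cfg$n_otus)))
  for (j in seq_len(cfg$n_samples)) {
    p <- geometric_abundance(cfg$n_otus, cfg$otu_evenness[j])
    otu[[cfg$sample_names[j]]] <- as.integer(
      stats::rmultinom(1, cfg$otu_depth, p))
  }
  if (cfg$n_singleton_otus > 0) {
    singles <- tibble::tibble(
      otu_id = sprintf("OTUS%03d", seq_len(cfg$n_singleton_otus)))
    which_sample <- sample(cfg$sample_names, cfg$n_singleton_otus, replace = TRUE)
    for (s in cfg$sample_names) {
      singles[[s]] <- as.integer(which_sample == s)
    }
    otu <- dplyr::bind_rows(otu, singles)
  }

  truth <- list(
    bin_lineages = tibble::tibble(bin_id = bin_ids, lineage = lineages,
                                  phylum = lineage_at_rank(lineages, "phylum"),
                                  is_eukaryote = seq_len(n_all) > n_prok),
    bin_aai = tibble::tibble(
      bin_id = bin_ids,
      mean_identity = as.numeric(tapply(hits$pct_identity[!wrong],
                                        factor(genes$bin_id[!wrong], bin_ids),
                                        mean))),
    bin_expression = w_rpkm,
    top5_share = truth_top5,
    enzyme_genes = truth_class,
    il_genes = truth_il,
    otu_evenness = tibble::tibble(sample = cfg$sample_names,
                                  target_pielou = cfg$otu_evenness),
    unbinned_scaffolds = setdiff(scaffolds$scaffold_id, bin_map$scaffold_id))

  structure(list(
    genes = genes, bin_map = bin_map, hits = hits, ko = ko_tbl,
    reference_ec = ref_ec, ref_hits = ref_hits, il_hits = il_hits,
    counts = counts, coverage = coverage, otu = otu,
    truth = truth, config = cfg), class = "community_sim")
}

# geometric-series relative abundances p_i proportional to theta^(i-1) whose
# Pielou evenness on n taxa equals the target; theta found by bisection.
geometric_abundance <- function(n, target_j) {
  if (target_j >= 1) return(rep(1 / n, n))
  j_of <- function(theta) {
    p <- theta^(seq_len(n) - 1)
    p <- p / sum(p)
    p <- p[p > 0]
    -sum(p * log(p)) / log(n)
  }
  theta <- stats::uniroot(function(t) j_of(t) - target_j,
                          c(1e-4, 1 - 1e-9), tol = 1e-10)$root
  p <- theta^(seq_len(n) - 1)
  p / sum(p)
}

#' Write a simulated community to disk
#'
#' Emits every table as TSV (gene models as GFF3) plus a `MANIFEST.tsv`
#' naming each file with its MD5 checksum. Identical seeds produce
#' byte-identical files.
#'
#' @param sim A `community_sim` from [simulate_community()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_community <- function(sim, dir) {
  stopifnot(inherits(sim, "community_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gff(sim$genes, p("genes.gff"))
  write_bin_map(sim$bin_map, p("bin_map.tsv"))
  write_hits(sim$hits, p("hits.tsv"))
  readr::write_tsv(sim$ko, p("ko.tsv"), progress = FALSE)
  readr::write_tsv(sim$reference_ec, p("reference_ec.tsv"), progress = FALSE)
  write_hits(sim$ref_hits, p("ref_hits.tsv"))
  write_hits(sim$il_hits, p("il_hits.tsv"))
  write_counts(sim$counts, p("counts.tsv"))
  readr::write_tsv(sim$coverage, p("coverage.tsv"), progress = FALSE)
  readr::write_tsv(sim$otu, p("otu.tsv"), progress = FALSE)
  files <- c(genes = "genes.gff", bin_map = "bin_map.tsv", hits = "hits.tsv",
             ko = "ko.tsv", reference_ec = "reference_ec.tsv",
             ref_hits = "ref_hits.tsv", il_hits = "il_hits.tsv",
             counts = "counts.tsv", coverage = "coverage.tsv", otu = "otu.tsv")
  manifest <- tibble::tibble(
    file = unname(files),
    md5 = unname(tools::md5sum(file.path(dir, files))))
  readr::write_tsv(manifest, p("MANIFEST.tsv"), progress = FALSE)
  invisible(stats::setNames(file.path(dir, files), names(files)))
}

#' Simulate a respirometry trace with a planted cumulative respiration
#'
#' The CO2 evolution rate follows a smooth rise-and-decay curve
#' `CER(t) = c_max (t/t_peak) exp(1 - t/t_peak)` whose integral over the
#' incubation equals `total_ccer`; the effluent CO2 fraction is back-derived
#' from the flow, molar volume and dry mass, with optional Gaussian sensor
#' noise. Alternatively an explicit `co2_fraction` profile can be supplied.
#'
#' @param time Sampling times in hours (strictly increasing).
#' @param flow Flow in L min^-1, scalar or per-time vector.
#' @param dry_mass Dry matter, g.
#' @param total_ccer Planted integral of CER over the time span,
#'   mg CO2 g^-1 dry matter.
#' @param peak_time Time of the CER peak, hours.
#' @param co2_fraction Optional explicit CO2 fraction profile (overrides the
#'   planted curve).
#' @param noise_sd Gaussian noise on the CO2 fraction (fraction units).
#' @param molar_volume Gas molar volume, L mol^-1.
#' @param seed Optional seed for the noise.
#' @return A trace tibble (see [resp_trace()]) with attributes
#'   `target_ccer` and `analytic_cer` (the noise-free CER function of time).
#' @export
simulate_respirometry <- function(time = seq(0, 168, by = 1), flow = 1,
                                  dry_mass = 50, total_ccer = 299,
                                  peak_time = 24, co2_fraction = NULL,
                                  noise_sd = 0, molar_volume = 24,
                                  seed = NULL) {
  stopifnot(dry_mass > 0, all(flow >= 0), total_ccer >= 0)
  flow <- rep_len(flow, length(time))
  if (is.null(co2_fraction)) {
    tp <- peak_time
    span <- range(time)
    # integral of (t/tp) exp(1 - t/tp) from t0 to t1 (closed form)
    prim <- function(t) -exp(1) * tp * exp(-t / tp) * (t / tp + 1)
    c_max <- total_ccer / (prim(span[2]) - prim(span[1]))
    cer_fun <- function(t) c_max * (t / tp) * exp(1 - t / tp)
    frac <- cer_fun(time) * dry_mass / (flow * 60 * (44.01 / molar_volume) * 1000)
    frac[flow == 0] <- 0
  } else {
    cer_fun <- NULL
    frac <- rep_len(co2_fraction, length(time))
  }
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(time), 0, noise_sd) else
      withr::with_seed(seed, stats::rnorm(length(time), 0, noise_sd))
    frac <- frac + noise
  }
  frac <- pmin(pmax(frac, 0), 1)
  out <- resp_trace(time, frac, flow, dry_mass)
  attr(out, "target_ccer") <- total_ccer
  attr(out, "analytic_cer") <- cer_fun
  out
}

#' @export
print.community_sim <- function(x, ...) {
  cat("<community_sim> ", x$config$n_bins, " bins (+",
      x$config$eukaryote_bins, " eukaryote), ",
      nrow(x$genes), " genes, ", x$config$n_samples, " samples, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Tidy the planted truth of a simulated community
#'
#' @param x A `community_sim`.
#' @param ... Unused.
#' @return One row per bin: lineage, phylum, gene count, and the planted
#'   per-sample expression weights.
#' @export
tidy.community_sim <- function(x, ...) {
  w <- tibble::as_tibble(x$truth$bin_expression, rownames = "bin_id")
  x$truth$bin_lineages |>
    dplyr::left_join(dplyr::count(x$genes, .data$bin_id, name = "n_genes"),
                     by = "bin_id") |>
    dplyr::left_join(w, by = "bin_id")
}

#' One-row summary of a simulated community
#'
#' @inheritParams tidy.community_sim
#' @return Tibble with bin/gene/sample counts and the noise settings.
#' @export
glance.community_sim <- function(x, ...) {
  tibble::tibble(
    n_bins = x$config$n_bins, n_eukaryote_bins = x$config$eukaryote_bins,
    n_genes = nrow(x$genes), n_samples = x$config$n_samples,
    n_phyla = x$config$n_phyla,
    taxonomy_noise = x$config$taxonomy_noise,
    annotation_consistency = x$config$annotation_consistency,
    seed = x$config$seed)
}
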