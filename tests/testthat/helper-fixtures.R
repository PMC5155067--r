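# Small in-code fixtures shared across test files.

# A hit row with sensible defaults; override what matters per test.
make_hit <- function(gene_id, lineage = "", pct_identity = 90,
                     evalue = 1e-50, query_coverage = 80,
                     subject_id = "S1", aln_len = 100L) {
  tibble::tibble(gene_id = gene_id, subject_id = subject_id,
                 pct_identity = pct_identity, aln_len = aln_len,
                 evalue = evalue, query_coverage = query_coverage,
                 lineage = lineage)
}

# Three-phylum toy taxonomy: full 8-rank lineages used by the LCA oracle
# tests, sharing ancestry at controlled depths.
toy_lineages <- function() {
  c(
    firmi_a  = "Bacteria;Terrabacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus;Bacillus alpha",
    firmi_b  = "Bacteria;Terrabacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus;Bacillus beta",
    firmi_c  = "Bacteria;Terrabacteria;Firmicutes;Clostridia;Clostridiales;Clostridiaceae;Clostridium;Clostridium gamma",
    actino   = "Bacteria;Terrabacteria;Actinobacteria;Actinomycetia;Streptomycetales;Streptomycetaceae;Streptomyces;Streptomyces delta",
    proteo   = "Bacteria;Gracilicutes;Proteobacteria;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Escherichia;Escherichia coli",
    euk      = "Eukaryota;Fungi;Ascomycota;Sordariomycetes;Hypocreales;Nectriaceae;Fusarium;Fusarium epsilon",
    dom_only = "Bacteria"
  )
}

# Independent LCA oracle: rank-by-rank prefix intersection, written as a
# plain loop so it shares no code with the package implementation.
oracle_lca <- function(lineages) {
  split <- lapply(strsplit(lineages, ";", fixed = TRUE),
                  function(x) x[nzchar(x)])
  out <- character(0)
  for (i in seq_len(min(vapply(split, length, integer(1))))) {
    lab <- unique(vapply(split, `[`, character(1), i))
    if (length(lab) != 1L) break
    out <- c(out, lab)
  }
  paste(out, collapse = ";")
}

# Independent UPGMA oracle: naive average-linkage agglomeration returning
# the cophenetic distance matrix.
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best[1]) best <- c(avg, i, j)
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# Tiny simulation config for fast unit tests.
tiny_config <- function(...) {
  sim_config(n_bins = 8, n_phyla = 3, genes_per_bin = c(30, 40),
             class_genes_per_bin = 1, n_otus = 60, otu_depth = 5000,
             n_singleton_otus = 4, ...)
}
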