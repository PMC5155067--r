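# bintrans

Genome-resolved metatranscriptome analysis for binned microbial
communities.

When a microbial community — say, a compost-derived consortium degrading
switchgrass under increasing doses of the ionic liquid
1-ethyl-3-methylimidazolium acetate — is studied by metagenome
co-assembly, genome binning and metatranscriptome read mapping, a stack of
downstream bookkeeping stands between the count matrix and the biology.
`bintrans` implements that stack as composable, tested functions over
tibbles:

* **Taxonomy** — bins are assigned the modal lineage of their genes'
  closest reference hits, with amino-acid identity (AAI) averaged over the
  winner-voting genes; unbinned scaffolds get lowest-common-ancestor (LCA)
  labels with the standard exclusion vocabulary ("eukaryotes", "cellular
  organisms", "unassigned" are dropped from prokaryotic totals,
  "unclassified bacteria" is kept).
* **Annotation** — EC numbers transferred by homology at ≥ 95% identity
  and ≥ 40% coverage; genes classified into five enzyme classes
  (endoglucanase, cellulose 1,4-beta-cellobiosidase, beta-glucosidase,
  xylanase, acetate kinase) only when KO and EC agree — except
  cellobiosidase, where the EC alone decides; KO/EC agreement ratios;
  ionic-liquid tolerance flagging at E ≤ 1e−5 against *eilA*, *sugE*,
  *emrE*, *smvA*, *ykkC*, *ykkD*.
* **Quantification** — RPKM = 10⁹ · count / (gene length · library size),
  summed to bins, phyla and enzyme classes; top-k transcriber shares with
  both community-denominator conventions; per-bin top-gene percentages.
* **Ecology** — singleton removal, richness, Shannon H (natural log),
  Pielou's evenness J = H / ln S, and Bray–Curtis/UPGMA sample trees
  written as newick.
* **Respirometry** — CO₂ evolution rate
  CER = flow · 60 · CO₂ fraction · (44.01 / V_m) · 1000 / dry mass
  (mg CO₂ g⁻¹ h⁻¹) and its trapezoidal time integral cCER.
* **Synthetic data** — `simulate_community()` generates a complete input
  set (GFF3, membership, hits, KO/EC tables, counts, coverages, OTU
  table) with planted ground truth, so the whole pipeline is testable
  without sequencing data.

See `vignettes/genome-resolved-metatranscriptomics.Rmd` for the methods
and modelling choices.

## Worked example

```r
library(bintrans)
library(dplyr)

sim <- simulate_community(sim_config(seed = 1))

# bin taxonomy by best-hit voting
bt <- vote_bin_taxonomy(sim$hits, sim$genes[, c("gene_id", "bin_id")])
head(bt, 3)
#>   bin_id lineage                     vote_fraction mean_aai n_genes is_eukaryote
#> 1 bin001 Bacteria;Gracilicutes;Prot…         0.917     84.2     217 FALSE
#> 2 bin002 Bacteria;Terrabacteria;Fir…         0.862     73.7     188 FALSE
#> 3 bin003 Bacteria;Terrabacteria;Act…         0.947     72.4     150 FALSE

# RPKM, aggregation to bins, top-5 transcriber share per sample
rpkm <- compute_rpkm(sim$counts, sim$genes)
expr <- aggregate_expression(rpkm, sim$genes |> select(gene_id, group = bin_id))
top_k_share(expr, k = 5)
#>   sample   share_pct
#> 1 inoculum      48.4
#> 2 IL0           42.9
#> 3 IL0.5         32.9
#> 4 IL1           52.2
#> 5 IL2           57.8

# diversity after singleton removal
diversity_metrics(remove_singletons(sim$otu))
#>   sample   richness shannon pielou
#> 1 inoculum       69    3.23  0.762
#> 2 IL0            59    2.91  0.714
#> 3 IL0.5          40    2.56  0.693
#> 4 IL1            30    2.22  0.653
#> 5 IL2            23    1.89  0.602

# respirometry: a 7-day trace integrating to ~299 mg CO2 per g dry matter
tr <- compute_cer(simulate_respirometry())
round(integrate_ccer(tr$time, tr$cer), 1)
#> [1] 299
```

With a 10% lineage-noise rate, most genes still vote for the true lineage
(`vote_fraction` ≈ 0.9) and the voted lineages match the planted ones. The
top-5 share rises toward the high-IL samples — the planted gradient
concentrates transcription in a few resilient bins — and diversity falls
monotonically along the same gradient. `run_pipeline(pipeline_config(...))`
chains all stages and writes one report TSV per stage;
`inst/scripts/bintrans-pipeline.R` wraps it for shell use.

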