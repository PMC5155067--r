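---
title: "Genome-resolved metatranscriptome analysis with bintrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-resolved metatranscriptome analysis with bintrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bintrans)
library(dplyr)
```

## The problem

Lignocellulose-degrading microbial communities — for example compost-derived
consortia adapting to the ionic liquid (IL) [C~2~mim][OAc] used in biomass
pretreatment — are studied by co-assembling metagenomes, binning scaffolds
into genome bins (MAGs), and mapping metatranscriptome reads back onto the
predicted genes. `bintrans` implements everything downstream of those steps:
given gene models, bin memberships, homology-hit tables, KO annotations and
a gene-by-sample count matrix, it assigns taxonomy to bins and unbinned
scaffolds, reconciles KO and EC functional annotations, normalizes and
aggregates transcription to bins, phyla and enzyme classes, computes
community diversity, and integrates respirometry traces. A synthetic
community generator with planted ground truth makes every stage testable
without sequencing data.

## Taxonomy: best-hit voting and LCA labels

Each gene votes with the full lineage of its closest reference hit (lowest
E-value; ties broken by higher identity, then subject id, so results never
depend on row order). A bin's taxonomy is the modal lineage and its
amino-acid identity (AAI) is the mean percent identity over the genes that
voted for the winner; genes without hits do not vote. We vote on the full
lineage — species level when available — and report coarser ranks by
truncation, which matches how per-genome species calls with an AAI
percentage are usually tabulated. Voting ties are broken by higher mean
identity, then lexicographic lineage.

Unbinned scaffolds are labelled by a simplified lowest-common-ancestor
rule. All hits of a scaffold's genes are pooled; hits within 10% of the
scaffold's best score are retained, using −log10 E-value as the score proxy
because tabular hit files reliably carry E-values but not bit scores. The
deepest rank shared by all retained hits is the label, with the standard
vocabulary: hits that agree on no domain give *cellular organisms*
(excluded downstream), a eukaryotic LCA gives *eukaryotes* (excluded),
domain Bacteria with no phylum resolved gives *unclassified bacteria*
(included), no hits at all gives *unassigned* (excluded). We treat "no
phylum resolved" — rather than strictly "domain only" — as the boundary for
*unclassified bacteria* because intermediate kingdom-level groupings
(e.g. Terrabacteria) carry no practical phylum information.

## Annotation reconciliation

EC numbers are transferred from a reference annotation when a gene's
closest reference hit has **≥ 95% identity and ≥ 40% coverage** (both
inclusive, per the usual "at least" phrasing of such thresholds). Coverage
is interpreted as query coverage and is configurable. Enzyme classification
then requires **both** a class KO and the class EC:

| class | KO set | EC |
|---|---|---|
| endoglucanase | K01179, K19356, K19357, K20542 | 3.2.1.4 |
| cellulose 1,4-beta-cellobiosidase | K01225, K19668 | 3.2.1.91 |
| beta-glucosidase | K01188, K05349, K05350 | 3.2.1.21 |
| xylanase | K01181, K13465 | 3.2.1.8 |
| acetate kinase | K00925 | 2.7.2.1 |

Cellobiosidase is the exception: its KO annotations agree poorly with EC
assignments (agreement ratios are what `ko_ec_agreement()` reports), so
membership rests on the EC number alone — *provided* the gene's KO does not
point at a different class. A gene carrying the KO of one class and the EC
of another is inconsistent and stays unclassified. Ionic-liquid tolerance
genes (*eilA*, *sugE*, *emrE*, *smvA*, *ykkC*, *ykkD*) are flagged from
hits at E ≤ 1e−5; the cutoff is inclusive, a convention we fix explicitly
because "cutoff set to 1e−5" leaves the boundary open.

## Quantification

RPKM = 10^9^ × count / (gene length in bp × library size). By default the
library size is the per-sample column sum of gene-assigned counts, which
reproduces the count-matrix-only normalization exactly and keeps runs
reproducible without alignment files; externally measured totals can be
supplied. Transcription is aggregated by summing member-gene RPKM per
group. Eukaryote bins and scaffolds labelled *eukaryotes*, *cellular
organisms* or *unassigned* are excluded from prokaryotic totals because
eukaryotic gene structure breaks both the gene prediction and the RPKM
denominator.

`top_k_share()` reports the percentage of prokaryotic transcription carried
by the k most transcribed genome bins. Because it is genuinely ambiguous
whether unbinned prokaryotic transcription ("unclassified bacteria" and
phylum-labelled unbinned scaffolds) belongs in the community denominator,
both modes are implemented: `"included"` (default; unbinned prokaryotic
groups count) and `"binned"` (genome bins only). Similarly,
`top_genes_in_bin()` uses the bin's own total — not the sample total — as
the percent denominator, matching how "a single gene accounted for X% of
this organism's transcription" statements are made.

## Ecology

Diversity uses natural-log Shannon H, richness S, and Pielou's evenness
J = H / ln S; the published triplets (H = 2.97, S = 190, J = 0.57 and
H = 1.74, S = 143, J = 0.35) are consistent with the natural log to two
decimals, which fixes the base. Singletons are OTUs with **total count
across the whole dataset ≤ 1** (the common global convention; a per-sample
rule is not used) and are removed before diversity is computed. The sample
distance tree uses Bray–Curtis distances on per-sample relative abundances
with UPGMA (average-linkage) agglomeration — the standard abundance-tree
recipe; both the metric and linkage are configurable since neither is
canonical. `hclust` breaks zero-distance ties by input order, so identical
samples cluster deterministically.

## Respirometry

CER(t) = flow × 60 × CO₂ fraction × (44.01 / V~m~) × 1000 / dry mass, in
mg CO₂ g⁻¹ dry matter h⁻¹. The molar volume defaults to 24.0 L mol⁻¹
(ambient sensor conditions) and is configurable; an optional baseline
column supports inlet-CO₂ subtraction (default 0, floored at zero).
cCER is the trapezoidal integral of CER over time. The trapezoid is
second-order accurate: on the planted 7-day curve, hourly sampling agrees
with fine-grid quadrature to well under 1%.

## What the generator emulates — and what it does not

`simulate_community()` plants a known truth behind every downstream stage:

* **Community**: 40 bins over 6 phyla by default, five samples along the
  IL gradient (inoculum, 0%, 0.5%, 1%, 2%). Phylum weights follow a
  sigmoidal response in gradient position — a Proteobacteria-like phylum
  fades from 0.55 to 0.08 of the community while a Firmicutes-like phylum
  rises from 0.12 to 0.75 — so the two no-IL samples resemble each other,
  as do the two high-IL samples, with the mid sample between regimes.
  Per-bin weights get log-normal jitter (sd 0.15) and coverages log-normal
  noise (sd 0.1), both deliberately below the between-regime signal so the
  planted pair structure is real.
* **Genes**: 150–250 per bin, log-normal lengths around 900 bp (sd 0.35 on
  the log scale) — typical prokaryotic gene-length variation; ~10 genes per
  scaffold; a random ~10% of scaffolds withheld from the membership table
  to create the unbinned pool that exercises the LCA path.
* **Hits**: per-bin identity means drawn from 70–99% with per-gene jitter;
  with probability `taxonomy_noise` a hit's genus and species are replaced
  (phylum kept correct with probability 0.5) to exercise rank-dependent
  voting and LCA behaviour.
* **Counts**: negative binomial with shared dispersion 0.3 and mean
  proportional to bin abundance × gene length × a per-gene log-normal
  expression factor, scaled to an expected library of 2 × 10⁶ reads. The
  paper trail for real count models is thin at this level, so the simplest
  mean–dispersion structure sufficient for recovery testing is used.
* **Annotations**: each bin carries planted genes for the five enzyme
  classes; with probability `annotation_consistency` the transferred EC
  matches the KO class, otherwise an EC from another class is planted —
  so KO/EC agreement is directly controlled. Sub-threshold decoy hits
  (60–94.8% identity) verify that EC transfer respects its thresholds.
* **OTU tables**: geometric-series abundances whose evenness on the full
  community equals a per-sample target (default declining 0.60 → 0.35
  along the gradient), sampled multinomially at depth 20,000, plus a few
  singleton OTUs to exercise removal.

The truth object records bin lineages, realized per-bin identity means,
expression weights, exact top-5 shares (when `top5_share` is set the
abundances are rescaled so the share is exact), planted enzyme and
IL-tolerance gene sets, and target evenness values.

Not emulated: sequence content (no reads, no alignment), rRNA depletion or
library-prep biases, strain heterogeneity within bins, chimeric binning
errors, and compositional coupling between the OTU table and the bin set.
Passing recovery tests therefore demonstrates the *bookkeeping and
statistics* of the pipeline are right, not that upstream assembly, binning
or mapping artifacts are handled — those live outside this package's scope.
One known bias worth naming: the multinomially sampled OTU tables lose
rare taxa, so realized richness is below the generating community's and
realized evenness is above the planted target; the gradient ordering is
preserved and that ordering, not the absolute value, is what the tests
assert.

## Numerical choices and degenerate inputs

* E-values of 0 are capped at 1e−300 before the −log10 score proxy.
* Zero-hit bins report `"unassigned"` with absent (NA) statistics; zero-KO
  classes report an absent agreement ratio rather than 0.
* All-zero samples yield an absent top-k share; zero-total bins yield an
  empty top-gene list; S = 1 yields an absent evenness (ln 1 = 0).
* Single-point respirometry traces integrate to 0 with a warning.
* All generator randomness flows through one seed (`withr::with_seed`), so
  identical seeds give byte-identical output files and no global RNG state
  leaks.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic
communities sized for completeness of coverage: 8–12-bin communities for
unit recovery, the default 40-bin community for top-share recovery, a
50-bin community giving 500 KO genes per class for the agreement-ratio
check, 100 independent 12-bin communities for the gradient-topology rate,
and exhaustive enumeration (1,715 instances) for the LCA oracle
equivalence. Published sequencing-scale inputs (about 10⁶ scaffolds,
138 bins) are not redistributable and are out of scope for the test suite;
the statistics above are the package's evidence of correctness.
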