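test_that("bin voting counts modal lineage and averages identity over voters", {
  tl <- toy_lineages()
  hits <- dplyr::bind_rows(
    make_hit("g1", tl[["firmi_a"]], pct_identity = 90),
    make_hit("g2", tl[["firmi_a"]], pct_identity = 80),
    make_hit("g3", tl[["proteo"]], pct_identity = 99))
  gene_bins <- tibble::tibble(gene_id = c("g1", "g2", "g3"), bin_id = "b1")
  bt <- vote_bin_taxonomy(hits, gene_bins)
  expect_equal(bt$lineage, tl[["firmi_a"]], ignore_attr = TRUE)
  expect_equal(bt$vote_fraction, 2 / 3)
  expect_equal(bt$mean_aai, 85.0)
  expect_equal(bt$n_genes, 3L)
  expect_false(bt$is_eukaryote)
})

test_that("unanimous bins reach vote_fraction 1 and eukaryote bins are flagged", {
  tl <- toy_lineages()
  hits <- dplyr::bind_rows(make_hit("g1", tl[["euk"]], pct_identity = 70),
                           make_hit("g2", tl[["euk"]], pct_identity = 80))
  bt <- vote_bin_taxonomy(hits, tibble::tibble(gene_id = c("g1", "g2"),
                                               bin_id = "b9"))
  expect_equal(bt$vote_fraction, 1)
  expect_true(bt$is_eukaryote)
})

test_that("voting is permutation-invariant and ties break by identity then lineage", {
  tl <- toy_lineages()
  hits <- dplyr::bind_rows(
    make_hit("g1", tl[["firmi_a"]], pct_identity = 95),
    make_hit("g2", tl[["proteo"]], pct_identity = 60),
    make_hit("g3", tl[["firmi_a"]], pct_identity = 75),
    make_hit("g4", tl[["proteo"]], pct_identity = 70))
  gene_bins <- tibble::tibble(gene_id = paste0("g", 1:4), bin_id = "b1")
  bt1 <- vote_bin_taxonomy(hits, gene_bins)
  bt2 <- vote_bin_taxonomy(hits[4:1, ], gene_bins)
  expect_equal(bt1, bt2)
  expect_equal(bt1$lineage, tl[["firmi_a"]], ignore_attr = TRUE)  # 85 > 65 mean identity
})

test_that("bins whose genes lack hits are reported unassigned", {
  hits <- make_hit("g1", toy_lineages()[["proteo"]])
  bt <- vote_bin_taxonomy(hits, tibble::tibble(gene_id = c("g1", "g2"),
                                               bin_id = c("b1", "b2")))
  row <- bt[bt$bin_id == "b2", ]
  expect_equal(row$lineage, "unassigned")
  expect_true(is.na(row$mean_aai))
})

test_that("a bin planted with a 98.9% identity distribution is recovered as such", {
  lin <- "Bacteria;Terrabacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus;Bacillus thermoamylovorans"
  set.seed(132)
  n <- 400
  hits <- make_hit(sprintf("g%03d", 1:n), lin,
                   pct_identity = round(pmin(100, rnorm(n, 98.9, 0.5)), 1))
  bt <- vote_bin_taxonomy(hits, tibble::tibble(gene_id = hits$gene_id,
                                               bin_id = "bin132"))
  expect_equal(bt$vote_fraction, 1)
  expect_equal(bt$mean_aai, 98.9, tolerance = 0.005)
  expect_equal(lineage_at_rank(bt$lineage, "species"),
               "Bacillus thermoamylovorans")
})

test_that("LCA labels follow the exclusion vocabulary", {
  tl <- toy_lineages()
  genes <- tibble::tibble(gene_id = paste0("g", 1:2), scaffold_id = "s1")
  # all one genus -> genus-level lineage, included
  r <- lca_assign(dplyr::bind_rows(make_hit("g1", tl[["firmi_a"]]),
                                   make_hit("g2", tl[["firmi_b"]])), genes)
  expect_identical(lineage_at_rank(r$lineage, "genus"), "Bacillus")
  expect_true(r$include)
  # split across phyla -> unclassified bacteria, included
  r <- lca_assign(dplyr::bind_rows(make_hit("g1", tl[["firmi_a"]]),
                                   make_hit("g2", tl[["proteo"]])), genes)
  expect_identical(r$label, "unclassified bacteria")
  expect_true(r$include)
  # split across domains -> cellular organisms, excluded
  r <- lca_assign(dplyr::bind_rows(make_hit("g1", tl[["firmi_a"]]),
                                   make_hit("g2", tl[["euk"]])), genes)
  expect_identical(r$label, "cellular organisms")
  expect_false(r$include)
  # eukaryote consensus -> eukaryotes, excluded
  r <- lca_assign(make_hit(c("g1", "g2"), tl[["euk"]]), genes)
  expect_identical(r$label, "eukaryotes")
  expect_false(r$include)
  # no hits at all -> unassigned, excluded
  r <- lca_assign(make_hit("gX", tl[["proteo"]]),
                  tibble::tibble(gene_id = "g9", scaffold_id = "s9"))
  expect_identical(r$label[r$scaffold_id == "s9"], "unassigned")
  expect_false(r$include[r$scaffold_id == "s9"])
})

test_that("the LCA score window discards weak outlier hits", {
  tl <- toy_lineages()
  genes <- tibble::tibble(gene_id = paste0("g", 1:3), scaffold_id = "s1")
  hits <- dplyr::bind_rows(
    make_hit("g1", tl[["firmi_a"]], evalue = 1e-100),
    make_hit("g2", tl[["firmi_b"]], evalue = 1e-95),
    make_hit("g3", tl[["proteo"]], evalue = 1e-20))  # outside the 10% window
  r <- lca_assign(hits, genes, top_percent = 10)
  expect_identical(lineage_at_rank(r$lineage, "genus"), "Bacillus")
  # widening the window to 100% pulls the outlier in, pushing the LCA up
  r2 <- lca_assign(hits, genes, top_percent = 100)
  expect_identical(r2$label, "unclassified bacteria")
})

test_that("with zero taxonomy noise the planted bin lineages are recovered exactly", {
  sim <- simulate_community(tiny_config(taxonomy_noise = 0, seed = 3))
  gene_bins <- sim$genes[, c("gene_id", "bin_id")]
  bt <- vote_bin_taxonomy(sim$hits, gene_bins)
  truth <- sim$truth$bin_lineages
  expect_equal(bt$lineage[match(truth$bin_id, bt$bin_id)], truth$lineage)
  expect_true(all(bt$vote_fraction == 1))
  aai <- sim$truth$bin_aai
  expect_equal(bt$mean_aai[match(aai$bin_id, bt$bin_id)], aai$mean_identity,
               tolerance = 1e-12)
})
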