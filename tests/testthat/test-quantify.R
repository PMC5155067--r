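genes3 <- tibble::tibble(
  gene_id = c("g1", "g2", "g3"),
  scaffold_id = "s1", start = 1L, end = 1L, strand = "+",
  length = c(1000L, 500L, 2000L))

test_that("RPKM formula on unit cases", {
  counts <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                           A = c(1000L, 250L, 0L))
  r <- compute_rpkm(counts, genes3, lib_sizes = c(A = 1e6))
  expect_equal(r$A, c(1e9 * 1000 / (1000 * 1e6), 1e9 * 250 / (500 * 1e6), 0))
  expect_equal(r$A[1], 1000)
  r2 <- compute_rpkm(counts, genes3, lib_sizes = c(A = 2e6))
  expect_equal(r2$A[2], 250)
})

test_that("genes missing from the models are reported as an error", {
  counts <- tibble::tibble(gene_id = c("g1", "gX"), A = c(1L, 1L))
  expect_error(compute_rpkm(counts, genes3), "gX")
})

test_that("RPKM agrees with the edgeR reference implementation", {
  set.seed(21)
  n <- 200
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                          length = sample(200:3000, n, TRUE))
  counts <- tibble::tibble(gene_id = genes$gene_id,
                           A = rpois(n, 40), B = rpois(n, 15))
  mine <- compute_rpkm(counts, genes)
  m <- as.matrix(counts[, c("A", "B")])
  rownames(m) <- counts$gene_id
  ref <- edgeR::rpkm(m, gene.length = genes$length,
                     lib.size = colSums(m), normalized.lib.sizes = FALSE)
  expect_equal(as.matrix(mine[, c("A", "B")]), unname(ref),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("RPKM conservation: sum of RPKM x length_kb is 1e6 per sample", {
  set.seed(2)
  n <- 500
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                          length = sample(150:4000, n, TRUE))
  counts <- tibble::tibble(gene_id = genes$gene_id,
                           A = rpois(n, 30), B = rnbinom(n, mu = 10, size = 2))
  r <- compute_rpkm(counts, genes)
  len_kb <- genes$length / 1000
  expect_equal(sum(r$A * len_kb), 1e6, tolerance = 1e-9)
  expect_equal(sum(r$B * len_kb), 1e6, tolerance = 1e-9)
})

test_that("aggregation sums member RPKM, honors exclusion flags, matches oracle", {
  rpkm <- tibble::tibble(gene_id = paste0("g", 1:5),
                         A = c(3.5, 6.5, 1, 2, 4), B = c(0, 1, 2, 3, 4))
  grouping <- tibble::tibble(gene_id = paste0("g", 1:4),
                             group = c("b1", "b1", "b2", "euk"),
                             included = c(TRUE, TRUE, TRUE, FALSE))
  agg <- aggregate_expression(rpkm, grouping)
  expect_equal(agg$A[agg$group == "b1"], 10.0)
  expect_false(agg$included[agg$group == "euk"])
  expect_equal(agg$group[!agg$group %in% c("b1", "b2", "euk")], "(ungrouped)")
  # brute-force group-sum oracle
  oracle <- tapply(rpkm$A, c("b1", "b1", "b2", "euk", "(ungrouped)"), sum)
  expect_equal(agg$A[match(names(oracle), agg$group)], as.numeric(oracle))
})

test_that("aggregation is linear in the count matrix", {
  set.seed(31)
  genes <- tibble::tibble(gene_id = paste0("g", 1:50),
                          length = sample(300:2000, 50, TRUE))
  grouping <- tibble::tibble(gene_id = genes$gene_id,
                             group = sample(c("b1", "b2", "b3"), 50, TRUE))
  lib <- c(A = 1e6)
  c1 <- tibble::tibble(gene_id = genes$gene_id, A = rpois(50, 20))
  c2 <- tibble::tibble(gene_id = genes$gene_id, A = rpois(50, 5))
  csum <- dplyr::mutate(c1, A = .data$A + c2$A)
  a1 <- aggregate_expression(compute_rpkm(c1, genes, lib), grouping)
  a2 <- aggregate_expression(compute_rpkm(c2, genes, lib), grouping)
  asum <- aggregate_expression(compute_rpkm(csum, genes, lib), grouping)
  expect_equal(asum$A, a1$A + a2$A)
})

test_that("top_k_share on a worked example, with monotonicity and saturation", {
  expr <- tibble::tibble(group = paste0("b", 1:6), included = TRUE,
                         A = c(50, 30, 10, 5, 3, 2))
  expect_equal(top_k_share(expr, k = 5)$share_pct, 98.0)
  expect_equal(top_k_share(expr, k = 10)$share_pct, 100)
  shares <- vapply(1:6, function(k) top_k_share(expr, k = k)$share_pct,
                   numeric(1))
  expect_true(all(diff(shares) >= 0))
})

test_that("top_k_share denominator modes differ only through unbinned groups", {
  expr <- tibble::tibble(
    group = c("b1", "b2", "unbinned:unclassified bacteria", "unbinned:eukaryotes"),
    included = c(TRUE, TRUE, TRUE, FALSE),
    A = c(60, 20, 20, 100))
  expect_equal(top_k_share(expr, k = 1, denominator = "binned")$share_pct, 75)
  expect_equal(top_k_share(expr, k = 1, denominator = "included")$share_pct, 60)
  # excluded groups never enter either denominator
  zero <- dplyr::mutate(expr, A = c(60, 20, 20, 0))
  expect_equal(top_k_share(zero, k = 1, denominator = "included")$share_pct, 60)
})

test_that("all-zero samples give an absent share", {
  expr <- tibble::tibble(group = "b1", included = TRUE, A = 0)
  expect_true(is.na(top_k_share(expr, k = 1)$share_pct))
})

test_that("top genes within a bin rank by RPKM with percent-of-bin totals", {
  rpkm <- tibble::tibble(gene_id = paste0("g", 1:4),
                         A = c(70, 20, 10, 999))
  grouping <- tibble::tibble(gene_id = paste0("g", 1:4),
                             group = c("b1", "b1", "b1", "b2"))
  top <- top_genes_in_bin(rpkm, grouping, "b1", "A")
  expect_equal(top$pct_of_bin, c(70, 20, 10))
  single <- top_genes_in_bin(rpkm, grouping, "b2", "A")
  expect_equal(single$pct_of_bin, 100)
})

test_that("a gene planted at 12% of bin transcription is recovered exactly", {
  genes <- tibble::tibble(gene_id = paste0("g", 1:5),
                          length = c(500L, 1000L, 2000L, 800L, 1200L))
  # counts chosen so gene RPKM ratios are 12 : 22 : 22 : 22 : 22
  lib <- c(A = 1e6)
  rpkm_target <- c(12, 22, 22, 22, 22)
  counts <- tibble::tibble(gene_id = genes$gene_id,
                           A = as.integer(rpkm_target * genes$length))
  r <- compute_rpkm(counts, genes, lib_sizes = c(A = 1e9 / 1e3))
  grouping <- tibble::tibble(gene_id = genes$gene_id, group = "b1")
  top <- top_genes_in_bin(r, grouping, "b1", "A", n = 5)
  expect_equal(top$pct_of_bin[top$gene_id == "g1"], 12)
})
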