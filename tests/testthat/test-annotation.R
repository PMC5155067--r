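test_that("EC transfer applies inclusive identity and coverage thresholds", {
  ref_ec <- tibble::tibble(ref_id = c("r1", "r2"), ec = c("3.2.1.8", "3.2.1.4"))
  hits <- dplyr::bind_rows(
    make_hit("g1", subject_id = "r1", pct_identity = 96, query_coverage = 45),
    make_hit("g2", subject_id = "r1", pct_identity = 95, query_coverage = 40),
    make_hit("g3", subject_id = "r1", pct_identity = 94.9, query_coverage = 90),
    make_hit("g4", subject_id = "r2", pct_identity = 99, query_coverage = 39.9))
  ec <- transfer_ec(hits, ref_ec)
  expect_setequal(ec$gene_id, c("g1", "g2"))
  expect_equal(unique(ec$ec), "3.2.1.8")
})

test_that("EC transfer uses the closest usable hit and skips EC-less references", {
  ref_ec <- tibble::tibble(ref_id = "r1", ec = "2.7.2.1")
  hits <- dplyr::bind_rows(
    make_hit("g1", subject_id = "noEC", evalue = 1e-80, pct_identity = 99),
    make_hit("g1", subject_id = "r1", evalue = 1e-40, pct_identity = 97))
  ec <- transfer_ec(hits, ref_ec)
  expect_equal(ec$ec, "2.7.2.1")
})

test_that("dual KO+EC classification and the cellobiosidase exception", {
  ann <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    ko = c("K01179", "K01179", "", "K01225", "K00925", ""),
    ec = c("3.2.1.4", "3.2.1.91", "3.2.1.91", "3.2.1.91", "", "3.2.1.4"))
  out <- classify_enzymes(ann)
  expect_equal(out$enzyme_class, c(
    "endoglucanase",                      # consistent KO + EC
    NA,                                   # KO of one class, EC of another
    "cellulose 1,4-beta-cellobiosidase",  # EC alone suffices for this class
    "cellulose 1,4-beta-cellobiosidase",  # consistent
    NA,                                   # KO without EC: both required
    NA))                                  # EC without KO for a dual class
})

test_that("classification is order-independent and monotone in requires_both", {
  set.seed(5)
  ann <- tibble::tibble(
    gene_id = paste0("g", 1:50),
    ko = sample(c("", "K01179", "K01181", "K00925", "K01225"), 50, TRUE),
    ec = sample(c("", "3.2.1.4", "3.2.1.8", "2.7.2.1", "3.2.1.91"), 50, TRUE))
  a <- classify_enzymes(ann)
  b <- classify_enzymes(ann[sample(50), ]) |> dplyr::arrange(.data$gene_id)
  expect_equal(dplyr::arrange(a, .data$gene_id), b)

  relaxed <- enzyme_classes()
  relaxed$requires_both <- FALSE
  r <- classify_enzymes(ann, relaxed)
  in_a <- !is.na(a$enzyme_class)
  in_r <- !is.na(r$enzyme_class)
  expect_true(all(in_r[in_a]))  # relaxing can only grow class membership
})

test_that("KO/EC agreement ratio counts per-class matches over KO-bearing genes", {
  ann <- tibble::tibble(
    gene_id = paste0("g", 1:11),
    ko = c(rep("K01181", 10), "K01179"),
    ec = c(rep("3.2.1.8", 9), "", "3.2.1.4"))
  agr <- ko_ec_agreement(ann)
  expect_equal(agr$agreement_pct[agr$class == "xylanase"], 90)
  expect_equal(agr$agreement_pct[agr$class == "endoglucanase"], 100)
  expect_true(is.na(agr$agreement_pct[agr$class == "acetate kinase"]))
})

test_that("IL tolerance flagging is inclusive at the E-value cutoff", {
  hits <- dplyr::bind_rows(
    make_hit("g1", subject_id = "eilA", evalue = 1e-6),
    make_hit("g2", subject_id = "ykkC", evalue = 1e-5),
    make_hit("g3", subject_id = "sugE", evalue = 2e-5),
    make_hit("g4", subject_id = "not_a_pump", evalue = 1e-40))
  fl <- flag_il_tolerance(hits)
  expect_equal(fl$il_tolerance[match(paste0("g", 1:4), fl$gene_id)],
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("planted enzyme gene sets are recovered exactly at full consistency", {
  sim <- simulate_community(tiny_config(annotation_consistency = 1, seed = 9))
  ec <- transfer_ec(sim$ref_hits, sim$reference_ec)
  ann <- sim$ko |>
    dplyr::full_join(ec, by = "gene_id") |>
    dplyr::mutate(ko = dplyr::coalesce(.data$ko, ""),
                  ec = dplyr::coalesce(.data$ec, "")) |>
    classify_enzymes()
  got <- ann |> dplyr::filter(!is.na(.data$enzyme_class))
  truth <- sim$truth$enzyme_genes
  expect_equal(nrow(got), nrow(truth))
  joined <- dplyr::inner_join(got, truth, by = "gene_id")
  expect_equal(nrow(joined), nrow(truth))
  expect_equal(joined$enzyme_class, joined$class)
})

test_that("planted IL tolerance genes are recovered exactly", {
  sim <- simulate_community(tiny_config(seed = 13))
  fl <- flag_il_tolerance(sim$il_hits)
  expect_setequal(fl$gene_id[fl$il_tolerance], sim$truth$il_genes)
})
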