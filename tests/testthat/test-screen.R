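test_that("gene classification reproduces the worked-example statuses", {
  crit <- screen_criteria()
  # specific candidate: strong treatment signal, comparator below 2, protein concordant
  expect_equal(classify_gene(list(fc = 2.24956, pfp = 0.0002),
                             list(fc = 1.97551, pfp = 0.0009),
                             list(ratio = 3.81, p_value = 0.00913822),
                             crit),
               "specific_candidate")
  # comparator exclusion fires before anything else
  expect_equal(classify_gene(list(fc = 2.43005, pfp = 0.0038),
                             list(fc = 2.20802, pfp = 0.0178),
                             list(ratio = 9, p_value = 1e-6), crit),
               "excluded_comparator")
  # strict transcript boundary: fc exactly 2.0 fails
  expect_equal(classify_gene(list(fc = 2.0, pfp = 0.0001),
                             list(fc = 1.0, pfp = 0.5), NULL, crit),
               "fails_transcript")
  expect_equal(classify_gene(list(fc = 2.33556, pfp = 0.0018),
                             list(fc = 1.92234, pfp = 0.02), NULL, crit),
               "no_protein_data")
  expect_equal(classify_gene(list(fc = 2.10864, pfp = 0.0037),
                             list(fc = 1.61716, pfp = 0),
                             list(ratio = 1.97, p_value = 0.0728559651),
                             crit),
               "fails_protein")
  expect_error(classify_gene(list(gene_id = "A", fc = 3, pfp = 0),
                             list(gene_id = "B", fc = 1, pfp = 0)),
               "different genes")
})

test_that("step 1 screen yields the worked-example candidates and audit table", {
  tabs <- paper_tables()
  res <- screen_step1(tabs$treatment, tabs$comparator,
                      filter_min_peptides(tabs$proteins, 1))
  expect_setequal(res$candidates$gene_id, c("FGA", "FDFT"))
  # candidates ordered by treatment fold change descending
  expect_equal(res$candidates$gene_id, c("FDFT", "FGA"))
  # the status partition is exhaustive and mutually exclusive
  expect_equal(sort(res$status$gene_id), sort(unique(tabs$treatment$gene_id)))
  expect_true(all(res$status$status %in%
                    c("specific_candidate", "excluded_comparator",
                      "fails_transcript", "no_protein_data",
                      "fails_protein")))
  expect_equal(res$status$status[res$status$gene_id == "FGL1"],
               "excluded_comparator")
  expect_equal(res$status$status[res$status$gene_id == "CST3"],
               "excluded_comparator")
  expect_equal(res$status$status[res$status$gene_id == "FGB"],
               "no_protein_data")
  expect_equal(res$status$status[res$status$gene_id == "FGG"],
               "fails_protein")
  # rerunning gives an identical audit table
  expect_identical(res$status,
                   screen_step1(tabs$treatment, tabs$comparator,
                                filter_min_peptides(tabs$proteins, 1))$status)
})

test_that("the default peptide rule drops single-peptide evidence", {
  tabs <- paper_tables()
  res <- screen_step1(tabs$treatment, tabs$comparator,
                      filter_min_peptides(tabs$proteins, 2))
  # FGA's only protein row has one unique peptide
  expect_equal(res$status$status[res$status$gene_id == "FGA"],
               "no_protein_data")
  expect_equal(res$candidates$gene_id, "FDFT")
})

test_that("relaxing any threshold never removes a candidate", {
  set.seed(31)
  for (i in 1:5) {
    n <- 40
    trt <- data.frame(gene_id = sprintf("g%02d", 1:n), direction = "up",
                      fc = exp(rnorm(n, 0.6, 0.5)),
                      pfp = runif(n, 0, 0.2), stringsAsFactors = FALSE)
    cmp <- data.frame(gene_id = trt$gene_id, direction = "up",
                      fc = exp(rnorm(n, 0.3, 0.5)),
                      pfp = runif(n), stringsAsFactors = FALSE)
    prot <- data.frame(protein_id = paste0("p", 1:n),
                       gene_symbol = trt$gene_id,
                       unique_peptides = sample(1:5, n, TRUE),
                       ratio = exp(rnorm(n, 0.6, 0.5)),
                       p_value = runif(n, 0, 0.2),
                       stringsAsFactors = FALSE)
    strict <- screen_step1(trt, cmp, prot, screen_criteria())
    relaxed <- screen_step1(trt, cmp, prot, screen_criteria(
      fc_threshold = 1.5, pfp_threshold = 0.15,
      comparator_fc_exclusion = 3.0, protein_ratio_threshold = 1.5,
      protein_p_threshold = 0.15, require_protein = FALSE))
    expect_true(all(strict$candidates$gene_id %in%
                      relaxed$candidates$gene_id))
  }
})

test_that("a fully null dataset yields no candidates", {
  n <- 30
  trt <- data.frame(gene_id = sprintf("g%02d", 1:n), direction = "up",
                    fc = rep(1, n), pfp = rep(1, n),
                    stringsAsFactors = FALSE)
  res <- screen_step1(trt, trt, NULL,
                      screen_criteria(require_protein = FALSE))
  expect_equal(nrow(res$candidates), 0)
  expect_error(screen_step1(trt, data.frame(gene_id = "other", fc = 1,
                                            pfp = 1)),
               "share no genes")
})

test_that("screen on planted data admits specific genes only", {
  cfg <- sim_config(n_genes = 300, n_specific = 10, n_shared = 10,
                    proteome_coverage = 1, seed = 17)
  sim <- simulate_expression(cfg)
  prot <- simulate_proteomics(cfg, sim$truth)
  trt <- estimate_pfp(sim$expression, "control", "LPON", "up",
                      n_perm = 300, seed = 18)
  cmp <- estimate_pfp(sim$expression, "control", "OLE", "up",
                      n_perm = 300, seed = 19)
  stats_tab <- protein_stats(prot$proteins, prot$conditions,
                             "control", "LPON")
  res <- screen_step1(trt, cmp, filter_min_peptides(stats_tab, 1))
  expect_true(all(res$candidates$gene_id %in% sim$truth$specific_genes))
  expect_false(any(res$candidates$gene_id %in% sim$truth$shared_genes))
})
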