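test_that("symmetric and repeated edges collapse to the maximum score", {
  f <- withr::local_tempfile(lines = c("protein1 protein2 combined_score",
                                       "A B 950", "B A 950", "A C 700",
                                       "A C 820", "D D 999"))
  net <- load_interactions(f)
  expect_equal(nrow(net), 2)  # self-edge dropped, duplicates merged
  expect_equal(net$combined_score[net$protein1 == "A" &
                                    net$protein2 == "B"], 950)
  expect_equal(net$combined_score[net$protein1 == "A" &
                                    net$protein2 == "C"], 820)
  expect_equal(attr(net, "scale"), "integer")
})

test_that("fractional and integer score scales are auto-detected", {
  frac <- interaction_network(data.frame(protein1 = c("A", "A"),
                                         protein2 = c("B", "C"),
                                         combined_score = c(0.95, 0.80)))
  expect_equal(attr(frac, "scale"), "fractional")
  expect_setequal(partners(frac, "A", 0.9), "B")
  expect_error(interaction_network(data.frame(protein1 = "A",
                                              protein2 = "B",
                                              combined_score = 1200)),
               "outside")
})

test_that("the 0.900 confidence threshold is inclusive", {
  net <- interaction_network(data.frame(
    protein1 = "X", protein2 = c("AT", "BELOW", "ABOVE"),
    combined_score = c(900, 899, 950)))
  expect_setequal(partners(net, "X", 0.900), c("AT", "ABOVE"))
  expect_warning(p <- partners(net, "GHOST"), "not present")
  expect_length(p, 0)
})

test_that("a large edge file parses identically to a line-by-line oracle", {
  set.seed(5)
  ids <- sprintf("N%03d", 1:60)
  raw <- data.frame(protein1 = sample(ids, 1000, TRUE),
                    protein2 = sample(ids, 1000, TRUE),
                    combined_score = sample(100:999, 1000, TRUE))
  f <- withr::local_tempfile()
  write.table(raw, f, sep = " ", quote = FALSE, row.names = FALSE)
  net <- load_interactions(f)
  # oracle: canonicalize and keep max per pair with plain loops
  seen <- new.env()
  for (i in seq_len(nrow(raw))) {
    if (raw$protein1[i] == raw$protein2[i]) next
    key <- paste(sort(c(raw$protein1[i], raw$protein2[i])), collapse = "|")
    prev <- if (!is.null(seen[[key]])) seen[[key]] else -Inf
    seen[[key]] <- max(prev, raw$combined_score[i])
  }
  got <- setNames(net$combined_score,
                  paste(net$protein1, net$protein2, sep = "|"))
  expect_equal(sort(names(got)), sort(ls(seen)))
  expect_equal(got[ls(seen)],
               setNames(unlist(mget(ls(seen), seen)), ls(seen)))
})

test_that("partner retrieval is symmetric and anti-monotone in threshold", {
  cfg <- sim_config(n_genes = 80, n_specific = 5, n_shared = 5, seed = 8)
  sim <- simulate_expression(cfg)
  net <- simulate_network(sim$truth, partners_per_candidate = 6,
                          decoy_edges = 60, seed = 9)
  genes <- unique(c(net$protein1, net$protein2))
  for (thr in c(0.5, 0.9)) {
    for (g in genes[1:10]) {
      for (h in partners(net, g, thr))
        expect_true(g %in% partners(net, h, thr))
    }
  }
  for (g in sim$truth$specific_genes)
    expect_true(all(partners(net, g, 0.95) %in% partners(net, g, 0.90)))
})

test_that("partner cross-validation retains and excludes the known partners", {
  tabs <- paper_tables()
  pset <- partners(tabs$network, "FGA", 0.900)
  expect_length(pset, 32)
  v <- crossval_partners(pset, tabs$treatment, tabs$comparator)
  expect_setequal(v$partner_id[v$verdict == "retained"], c("FGG", "FGB"))
  expect_setequal(v$partner_id[v$verdict == "excluded_comparator"],
                  c("FGL1", "CST3"))
  expect_equal(sum(v$verdict == "fails_transcript"), 28)
  expect_equal(nrow(crossval_partners(character(0), tabs$treatment,
                                      tabs$comparator)), 0)
  # partners absent from the contrasts are flagged, not dropped
  v2 <- crossval_partners(c("FGG", "MISSING"), tabs$treatment,
                          tabs$comparator)
  expect_equal(v2$verdict, c("retained", "unevaluable"))
})

test_that("partner verdicts reuse exactly the transcript sub-criteria", {
  tabs <- paper_tables()
  crit <- screen_criteria(require_protein = FALSE)
  ids <- tabs$treatment$gene_id
  v <- crossval_partners(ids, tabs$treatment, tabs$comparator)
  s <- screen_step1(tabs$treatment, tabs$comparator, NULL, crit)
  mapped <- ifelse(s$status$status == "specific_candidate", "retained",
                   s$status$status)
  expect_equal(v$verdict[match(s$status$gene_id, v$partner_id)], mapped)
})

test_that("the final candidate set unions primaries with retained partners", {
  tabs <- paper_tables()
  res <- screen_step1(tabs$treatment, tabs$comparator,
                      filter_min_peptides(tabs$proteins, 1))
  fga <- res$candidates[res$candidates$gene_id == "FGA", ]
  v <- crossval_partners(partners(tabs$network, "FGA"), tabs$treatment,
                         tabs$comparator)
  branch <- final_candidates(fga, v)
  expect_equal(branch, c("FGB", "FGA", "FGG"))  # fc descending
  # the FDFT branch keeps only the primary candidate
  fdft <- res$candidates[res$candidates$gene_id == "FDFT", ]
  v2 <- crossval_partners(partners(tabs$network, "FDFT"), tabs$treatment,
                          tabs$comparator)
  expect_equal(final_candidates(fdft, v2), "FDFT")
  expect_length(final_candidates(res$candidates[0, ], v[0, ]), 0)
})

test_that("alias mapping renames identifiers and reports unmapped ones", {
  net <- interaction_network(data.frame(
    protein1 = c("9606.ENSP1", "9606.ENSP1"),
    protein2 = c("9606.ENSP2", "ORPHAN"),
    combined_score = c(950, 910)))
  expect_warning(
    mapped <- map_aliases(net, data.frame(protein_id = c("9606.ENSP1",
                                                         "9606.ENSP2"),
                                          gene_symbol = c("FGA", "FGB"))),
    "ORPHAN")
  expect_setequal(partners(mapped, "FGA", 0.9), c("FGB", "ORPHAN"))
})
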