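# Independent brute-force oracles used to check the implementation.
# These deliberately avoid the package's own code paths.

# rank product by explicit loops over every replicate pairing
brute_rank_products <- function(values, cond_of, cond_a, cond_b,
                                direction = "up") {
  sa <- names(cond_of)[cond_of == cond_a]
  sb <- names(cond_of)[cond_of == cond_b]
  rp <- rep(1, nrow(values))
  k <- 0
  for (b in sb) for (a in sa) {
    ratio <- values[, b] / values[, a]
    r <- if (direction == "up") rank(-ratio) else rank(ratio)
    rp <- rp * r
    k <- k + 1
  }
  stats::setNames(rp^(1 / k), rownames(values))
}

# hypergeometric upper tail by direct summation of binomial coefficients
brute_tail <- function(N, B, n, b) {
  if (b == 0) return(1)
  i <- b:min(n, B)
  sum(choose(B, i) * choose(N - B, n - i)) / choose(N, n)
}

# exhaustive prefix scan for the minimum hypergeometric statistic
brute_mhg <- function(flags) {
  N <- length(flags)
  B <- sum(flags)
  best <- list(n = 1, b = 0, p = 1)
  b <- 0
  for (n in 1:N) {
    b <- b + flags[n]
    p <- brute_tail(N, B, n, b)
    if (p < best$p) best <- list(n = n, b = b, p = p)
  }
  best
}

# Benjamini-Hochberg step-up by the textbook formula
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  if (m > 1)
    for (i in (m - 1):1)
      q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# pooled two-sample t-test on arcsinh values, from the closed form
brute_arcsinh_t <- function(a, b) {
  ta <- asinh(a); tb <- asinh(b)
  na <- length(ta); nb <- length(tb)
  sp2 <- ((na - 1) * var(ta) + (nb - 1) * var(tb)) / (na + nb - 2)
  tstat <- (mean(tb) - mean(ta)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(abs(tstat), na + nb - 2, lower.tail = FALSE)
}

# small deterministic expression object: one row per gene, values given
# per condition as a list of replicate vectors
tiny_expr <- function(per_gene_values, conditions = names(per_gene_values[[1]])) {
  genes <- names(per_gene_values)
  n_rep <- length(per_gene_values[[1]][[1]])
  samples <- paste(rep(conditions, each = n_rep), seq_len(n_rep), sep = "_")
  m <- do.call(rbind, lapply(per_gene_values, function(v) unlist(v)))
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, setNames(rep(conditions, each = n_rep), samples))
}

# log-normal three-condition matrix with no planted structure
null_expr <- function(n_genes, n_rep = 3, seed = 1, sd = 0.3,
                      conditions = c("ctrl", "trt", "cmp")) {
  set.seed(seed)
  samples <- paste(rep(conditions, each = n_rep), seq_len(n_rep), sep = "_")
  m <- matrix(exp(rnorm(n_genes * length(samples), 5, sd)),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), samples))
  expression_matrix(m, setNames(rep(conditions, each = n_rep), samples))
}

# the published worked-example tables, loaded through the fixture writer
paper_tables <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- make_fixtures(dir)
  list(paths = paths,
       treatment = read_contrast(paths[["treatment_contrast"]]),
       comparator = read_contrast(paths[["comparator_contrast"]]),
       proteins = read_proteins(paths[["proteins"]]),
       network = load_interactions(paths[["network"]]),
       annotations = read_annotations(paths[["annotations"]]))
}

run_synthetic_pipeline <- function(seed, n_perm = 1000, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_expression(cfg)
  prot <- simulate_proteomics(cfg, sim$truth)
  net <- simulate_network(sim$truth, seed = seed + 2L)
  ann <- simulate_annotations(rownames(sim$truth$fc),
                              planted = sim$truth$specific_genes,
                              seed = seed + 3L)
  d <- withr::local_tempdir(.local_envir = parent.frame())
  write_expression(sim$expression, file.path(d, "e.tsv"),
                   file.path(d, "c.tsv"))
  write_proteins(prot$proteins, file.path(d, "p.tsv"))
  write.table(data.frame(sample_id = names(prot$conditions),
                         condition = unname(prot$conditions)),
              file.path(d, "pc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(net), file.path(d, "n.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ann, file.path(d, "a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg_run <- pipeline_config(
    expression = file.path(d, "e.tsv"), conditions = file.path(d, "c.tsv"),
    proteins = file.path(d, "p.tsv"),
    protein_conditions = file.path(d, "pc.tsv"),
    network = file.path(d, "n.tsv"), annotations = file.path(d, "a.tsv"),
    control = cfg$conditions[1], treatment = cfg$conditions[2],
    comparator = cfg$conditions[3],
    n_perm = n_perm, seed = seed, outdir = file.path(d, "out"))
  list(report = run_pipeline(cfg_run), truth = sim$truth, outdir = cfg_run$outdir)
}
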