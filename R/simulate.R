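#' Simulation configuration for the planted-candidate benchmark
#'
#' Defines a three-condition (control, treatment, comparator) replicated
#' log-normal intensity design with planted treatment-specific,
#' shared (up in treatment and comparator) and null genes. Intensities
#' are drawn as `exp(Normal(base_log_mean, noise_sd))` scaled by the
#' planted condition-specific fold change, so every value is strictly
#' positive and right-skewed, as microarray and LC-MS intensities are.
#'
#' @param n_genes number of genes (default 500).
#' @param n_replicates replicates per condition (default 3).
#' @param conditions ordered labels: control, treatment, comparator.
#' @param n_specific planted treatment-specific up-regulated genes
#'   (default 10).
#' @param n_shared genes planted up in both treatment and comparator
#'   (default 10).
#' @param specific_fc fold change of specific genes in the treatment
#'   (default 2.2, `>= 1`).
#' @param shared_fc fold change of shared genes in treatment and
#'   comparator (default 2.3, `>= 1`).
#' @param base_log_mean location of the log-intensity distribution
#'   (natural log, unitless; default 7).
#' @param noise_sd log-scale standard deviation (`> 0`; default 0.05,
#'   the tight replicate variability of a controlled cell-culture
#'   design; see the methods vignette).
#' @param proteome_coverage fraction of genes with a protein row in
#'   `[0, 1]` (default 0.6).
#' @param peptide_count_range inclusive integer interval for unique
#'   peptide counts (default `c(1, 8)`).
#' @param seed integer seed; identical seeds give identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500,
                       n_replicates = 3,
                       conditions = c("control", "LPON", "OLE"),
                       n_specific = 10,
                       n_shared = 10,
                       specific_fc = 2.2,
                       shared_fc = 2.3,
                       base_log_mean = 7,
                       noise_sd = 0.05,
                       proteome_coverage = 0.6,
                       peptide_count_range = c(1, 8),
                       seed = 1) {
  check_count <- function(x, name, min = 0) {
    if (length(x) != 1 || is.na(x) || x < min || x != round(x))
      stop("invalid '", name, "': must be an integer >= ", min)
  }
  check_count(n_genes, "n_genes", 1)
  check_count(n_replicates, "n_replicates", 1)
  check_count(n_specific, "n_specific")
  check_count(n_shared, "n_shared")
  if (length(conditions) != 3 || anyDuplicated(conditions))
    stop("invalid 'conditions': need 3 distinct labels ",
         "(control, treatment, comparator)")
  if (n_specific + n_shared > n_genes)
    stop("invalid 'n_specific'/'n_shared': n_specific + n_shared > n_genes")
  if (specific_fc < 1) stop("invalid 'specific_fc': must be >= 1")
  if (shared_fc < 1) stop("invalid 'shared_fc': must be >= 1")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("invalid 'noise_sd': must be > 0")
  if (proteome_coverage < 0 || proteome_coverage > 1)
    stop("invalid 'proteome_coverage': must be in [0, 1]")
  if (length(peptide_count_range) != 2 ||
      peptide_count_range[1] > peptide_count_range[2] ||
      peptide_count_range[1] < 1)
    stop("invalid 'peptide_count_range': need c(lo, hi) with 1 <= lo <= hi")
  check_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 conditions = as.character(conditions),
                 n_specific = as.integer(n_specific),
                 n_shared = as.integer(n_shared),
                 specific_fc = specific_fc,
                 shared_fc = shared_fc,
                 base_log_mean = base_log_mean,
                 noise_sd = noise_sd,
                 proteome_coverage = proteome_coverage,
                 peptide_count_range = as.integer(peptide_count_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# planted per-gene, per-condition fold-change matrix and gene partition
planted_truth <- function(config) {
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  picked <- sample(genes, config$n_specific + config$n_shared)
  specific <- sort(utils::head(picked, config$n_specific))
  shared <- sort(utils::tail(picked, config$n_shared))
  nulls <- sort(setdiff(genes, c(specific, shared)))
  fc <- matrix(1, nrow = config$n_genes, ncol = 3,
               dimnames = list(genes, config$conditions))
  fc[specific, config$conditions[2]] <- config$specific_fc
  fc[shared, config$conditions[2]] <- config$shared_fc
  fc[shared, config$conditions[3]] <- config$shared_fc
  list(specific_genes = specific, shared_genes = shared,
       null_genes = nulls, fc = fc)
}

#' Simulate a planted-truth expression matrix
#'
#' @param config a [sim_config()] object.
#' @return List with `expression` (an [expression_matrix()]) and
#'   `truth` (lists `specific_genes`, `shared_genes`, `null_genes`,
#'   which partition the gene universe, and the per-gene, per-condition
#'   true fold-change matrix `fc`).
#' @export
simulate_expression <- function(config) {
  with_seed(config$seed, {
    truth <- planted_truth(config)
    samples <- paste(rep(config$conditions, each = config$n_replicates),
                     seq_len(config$n_replicates), sep = "_")
    cond_of <- stats::setNames(rep(config$conditions,
                                   each = config$n_replicates), samples)
    base <- matrix(exp(stats::rnorm(config$n_genes * length(samples),
                                    config$base_log_mean, config$noise_sd)),
                   nrow = config$n_genes,
                   dimnames = list(rownames(truth$fc), samples))
    values <- base * truth$fc[, cond_of[samples]]
    list(expression = expression_matrix(values, cond_of), truth = truth)
  })
}

#' Simulate a matching label-free proteomics table
#'
#' A `proteome_coverage` fraction of genes receives one protein row.
#' Protein intensities share the planted transcript fold change but
#' carry independent log-normal noise (conservative coupling); unique
#' peptide counts are uniform over `peptide_count_range`.
#'
#' @param config a [sim_config()] object.
#' @param truth the `truth` element from [simulate_expression()] run
#'   with the same config.
#' @return List with `proteins` (`data.frame`: `protein_id`,
#'   `gene_symbol`, `unique_peptides`, then one intensity column per
#'   sample) and `conditions` (named sample-to-condition vector).
#' @export
simulate_proteomics <- function(config, truth) {
  if (!setequal(rownames(truth$fc),
                c(truth$specific_genes, truth$shared_genes,
                  truth$null_genes)))
    stop("'truth' is inconsistent with its own gene universe")
  with_seed(config$seed + 1L, {
    genes <- rownames(truth$fc)
    n_cov <- round(config$proteome_coverage * length(genes))
    covered <- sort(sample(genes, n_cov))
    samples <- paste(rep(config$conditions, each = config$n_replicates),
                     seq_len(config$n_replicates), sep = "_")
    cond_of <- stats::setNames(rep(config$conditions,
                                   each = config$n_replicates), samples)
    tab <- data.frame(protein_id = if (length(covered))
                        paste0("P_", covered) else character(0),
                      gene_symbol = covered,
                      unique_peptides = sample(
                        config$peptide_count_range[1]:
                          config$peptide_count_range[2],
                        length(covered), replace = TRUE),
                      stringsAsFactors = FALSE)
    if (length(covered)) {
      base <- matrix(exp(stats::rnorm(length(covered) * length(samples),
                                      config$base_log_mean,
                                      config$noise_sd)),
                     nrow = length(covered))
      intens <- base * truth$fc[covered, cond_of[samples]]
      colnames(intens) <- samples
      tab <- cbind(tab, as.data.frame(intens))
    } else {
      for (s in samples) tab[[s]] <- numeric(0)
    }
    rownames(tab) <- NULL
    list(proteins = tab, conditions = cond_of)
  })
}

#' Simulate an interaction network around the planted candidates
#'
#' Each planted specific gene is linked at high confidence (score >=
#' 900 on the integer scale) to `partners_per_candidate` partners: the
#' other specific genes first — planted candidates form a co-regulated
#' module, the way subunits of one protein complex do — then null genes
#' to fill the remaining slots. Decoy edges between random genes get
#' scores below 900 and must not survive a highest-confidence query.
#'
#' @param truth the `truth` element from [simulate_expression()].
#' @param partners_per_candidate partners per specific gene (default
#'   8, `>= 0`).
#' @param decoy_edges number of sub-threshold edges (default 100).
#' @param seed integer seed.
#' @return An [interaction_network()] on the integer score scale.
#' @export
simulate_network <- function(truth, partners_per_candidate = 8,
                             decoy_edges = 100, seed = 1) {
  if (partners_per_candidate < 0)
    stop("'partners_per_candidate' must be >= 0")
  with_seed(seed, {
    genes <- rownames(truth$fc)
    edges <- list()
    for (g in truth$specific_genes) {
      mates <- setdiff(truth$specific_genes, g)
      if (length(mates) > partners_per_candidate)
        mates <- mates[seq_len(partners_per_candidate)]
      extra <- partners_per_candidate - length(mates)
      if (extra > 0)
        mates <- c(mates, sample(truth$null_genes, extra))
      if (length(mates))
        edges[[g]] <- data.frame(
          protein1 = g, protein2 = mates,
          combined_score = sample(900:999, length(mates), replace = TRUE),
          stringsAsFactors = FALSE)
    }
    if (decoy_edges > 0) {
      a <- sample(genes, decoy_edges, replace = TRUE)
      b <- sample(genes, decoy_edges, replace = TRUE)
      ok <- a != b
      edges[["decoys"]] <- data.frame(
        protein1 = a[ok], protein2 = b[ok],
        combined_score = sample(150:899, sum(ok), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    if (!length(edges))
      return(interaction_network(
        data.frame(protein1 = character(0), protein2 = character(0),
                   combined_score = numeric(0)), scale = "integer"))
    interaction_network(do.call(rbind, edges), scale = "integer")
  })
}

#' Simulate term annotations over a gene universe
#'
#' Random term memberships, plus one planted term covering a supplied
#' gene set (e.g. a candidate's planted partners) so that ranked
#' enrichment has a known positive.
#'
#' @param universe character vector of gene identifiers.
#' @param planted optional character vector; when given, term
#'   `TERM_PLANTED` covers exactly these genes.
#' @param n_terms number of random terms (default 20).
#' @param term_size_range inclusive size interval for random terms
#'   (default `c(5, 15)`); sizes are capped at the universe size.
#' @param seed integer seed.
#' @return `data.frame` with columns `term_id`, `gene_id`.
#' @export
simulate_annotations <- function(universe, planted = NULL, n_terms = 20,
                                 term_size_range = c(5, 15), seed = 1) {
  if (term_size_range[1] > length(universe))
    stop("'term_size_range' exceeds the universe size")
  with_seed(seed, {
    rows <- list()
    if (n_terms > 0) {
      for (i in seq_len(n_terms)) {
        size <- sample(term_size_range[1]:
                         min(term_size_range[2], length(universe)), 1)
        rows[[i]] <- data.frame(term_id = sprintf("TERM%03d", i),
                                gene_id = sort(sample(universe, size)),
                                stringsAsFactors = FALSE)
      }
    }
    if (!is.null(planted) && length(planted))
      rows[["planted"]] <- data.frame(term_id = "TERM_PLANTED",
                                      gene_id = sort(planted),
                                      stringsAsFactors = FALSE)
    if (!length(rows))
      return(data.frame(term_id = character(0), gene_id = character(0),
                        stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
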