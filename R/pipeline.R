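#' Pipeline configuration
#'
#' Two input modes are supported. In *expression mode* the pipeline
#' starts from a normalized intensity matrix and computes both
#' contrasts (rank products + pfp) itself; supply `expression` and
#' `conditions`. In *contrast mode* the transcript statistics were
#' computed elsewhere (e.g. published tables); supply
#' `treatment_contrast` and `comparator_contrast` TSVs with `gene_id`,
#' `fc`, `pfp` columns. The protein table may likewise carry per-sample
#' intensities (tested here) or precomputed `ratio`/`p_value` columns.
#'
#' @param expression,conditions paths to the intensity TSV and
#'   sample-to-condition TSV (expression mode).
#' @param treatment_contrast,comparator_contrast paths to precomputed
#'   contrast TSVs (contrast mode).
#' @param proteins path to the protein TSV.
#' @param protein_conditions path to the protein sample-to-condition
#'   TSV (only when the protein table carries intensities).
#' @param network path to the STRING-dialect edge table.
#' @param annotations path to the two-column term-to-gene TSV.
#' @param term_names optional path to a term-description TSV.
#' @param aliases optional path to a `protein_id`/`gene_symbol` alias
#'   TSV applied to the network.
#' @param control,treatment,comparator condition labels.
#' @param criteria a [screen_criteria()] object.
#' @param min_peptides unique-peptide retention threshold (default 2;
#'   use 1 to admit single-peptide quantifications).
#' @param min_confidence partner confidence threshold (default 0.900).
#' @param alpha enrichment reporting threshold (default 0.05).
#' @param n_perm permutations for pfp estimation (default 1000).
#' @param seed integer seed; mandatory in expression mode.
#' @param outdir output directory (created if needed).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression = NULL, conditions = NULL,
                            treatment_contrast = NULL,
                            comparator_contrast = NULL,
                            proteins, protein_conditions = NULL,
                            network, annotations, term_names = NULL,
                            aliases = NULL,
                            control = "control", treatment = "LPON",
                            comparator = "OLE",
                            criteria = screen_criteria(),
                            min_peptides = 2, min_confidence = 0.900,
                            alpha = 0.05, n_perm = 1000, seed = NULL,
                            outdir) {
  expr_mode <- !is.null(expression)
  if (expr_mode) {
    if (is.null(conditions))
      stop("expression mode needs 'conditions'")
    if (is.null(seed))
      stop("'seed' is mandatory when the pipeline estimates pfp")
  } else if (is.null(treatment_contrast) || is.null(comparator_contrast)) {
    stop("supply either 'expression' or both contrast tables")
  }
  paths <- c(expression = expression, conditions = conditions,
             treatment_contrast = treatment_contrast,
             comparator_contrast = comparator_contrast,
             proteins = proteins, protein_conditions = protein_conditions,
             network = network, annotations = annotations,
             term_names = term_names, aliases = aliases)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", names(missing), missing), collapse = ", "))
  structure(list(paths = as.list(paths), expr_mode = expr_mode,
                 control = control, treatment = treatment,
                 comparator = comparator, criteria = criteria,
                 min_peptides = min_peptides,
                 min_confidence = min_confidence, alpha = alpha,
                 n_perm = n_perm, seed = seed, outdir = outdir),
            class = "pipeline_config")
}

#' Run the full three-step candidate-identification pipeline
#'
#' Step 1 screens for genes specifically up-regulated by the treatment
#' (transcript fold change and pfp, comparator exclusion, protein
#' concordance). Step 2 retrieves each candidate's high-confidence
#' network partners and re-screens them with the transcript criteria,
#' rescuing partners lacking proteomics. Step 3 runs confidence-ranked
#' gene-set enrichment over each candidate's neighbourhood. All stage
#' tables, a final candidate list and a markdown report are written to
#' `config$outdir`; identical config and seed give identical output
#' bytes.
#'
#' @param config a [pipeline_config()] object.
#' @return Invisibly, the run report: a list with `status`,
#'   `candidates`, per-candidate `branches` (partner verdicts, branch
#'   candidate set, enrichment), `final` and `provenance`.
#' @export
run_pipeline <- function(config) {
  p <- config$paths
  if (config$expr_mode) {
    expr <- read_expression(p$expression, p$conditions)
    trt <- estimate_pfp(expr, config$control, config$treatment, "up",
                        n_perm = config$n_perm, seed = config$seed)
    cmp <- estimate_pfp(expr, config$control, config$comparator, "up",
                        n_perm = config$n_perm,
                        seed = config$seed + 1L)
  } else {
    trt <- read_contrast(p$treatment_contrast)
    cmp <- read_contrast(p$comparator_contrast)
  }

  prot <- read_proteins(p$proteins)
  prot <- filter_min_peptides(prot, config$min_peptides)
  if (!all(c("ratio", "p_value") %in% names(prot))) {
    if (is.null(p$protein_conditions))
      stop("protein table lacks ratio/p_value columns and no ",
           "'protein_conditions' map was given")
    pconds <- utils::read.delim(p$protein_conditions,
                                stringsAsFactors = FALSE)
    prot <- protein_stats(prot,
                          stats::setNames(pconds$condition,
                                          pconds$sample_id),
                          config$control, config$treatment)
  }

  step1 <- screen_step1(trt, cmp, prot, config$criteria)

  net <- load_interactions(p$network)
  if (!is.null(p$aliases))
    net <- map_aliases(net, utils::read.delim(p$aliases,
                                              stringsAsFactors = FALSE))
  ann <- read_annotations(p$annotations)
  term_names <- if (!is.null(p$term_names))
    utils::read.delim(p$term_names, stringsAsFactors = FALSE)

  branches <- lapply(step1$candidates$gene_id, function(g) {
    pset <- suppressWarnings(partners(net, g, config$min_confidence))
    verdicts <- crossval_partners(pset, trt, cmp, config$criteria)
    branch_final <- final_candidates(
      step1$candidates[step1$candidates$gene_id == g, , drop = FALSE],
      verdicts)
    enr <- enrich_all(ranked_universe(net, g, config$min_confidence),
                      ann, alpha = config$alpha, term_names = term_names)
    list(candidate = g, partners = pset, verdicts = verdicts,
         final = branch_final, enrichment = enr)
  })
  names(branches) <- step1$candidates$gene_id

  all_verdicts <- do.call(rbind, c(lapply(branches, `[[`, "verdicts"),
                                   make.row.names = FALSE))
  final <- final_candidates(step1$candidates, all_verdicts)

  report <- list(status = step1$status, candidates = step1$candidates,
                 branches = branches, final = final,
                 provenance = provenance_block(config))
  write_report(report, config)
  invisible(report)
}

provenance_block <- function(config) {
  list(package = "proteoscreen",
       version = as.character(utils::packageVersion("proteoscreen")),
       inputs = config$paths,
       criteria = unclass(config$criteria),
       min_peptides = config$min_peptides,
       min_confidence = config$min_confidence,
       alpha = config$alpha,
       n_perm = if (config$expr_mode) config$n_perm,
       seed = config$seed)
}

write_report <- function(report, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  utils::write.table(report$status, out("status.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(report$candidates$gene_id, out("candidates.txt"))
  for (g in names(report$branches)) {
    br <- report$branches[[g]]
    utils::write.table(br$verdicts, out(sprintf("partners_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(br$enrichment, out(sprintf("enrichment_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(report$final, out("final_candidates.txt"))

  md <- c("# Proteogenomic screen report", "",
          "## Provenance", "",
          sprintf("- package: proteoscreen %s",
                  report$provenance$version),
          sprintf("- seed: %s",
                  if (is.null(report$provenance$seed)) "none (contrast mode)"
                  else report$provenance$seed),
          sprintf("- thresholds: transcript FC > %g, pfp < %g, comparator FC exclusion > %g, protein ratio > %g, protein p < %g",
                  config$criteria$fc_threshold,
                  config$criteria$pfp_threshold,
                  config$criteria$comparator_fc_exclusion,
                  config$criteria$protein_ratio_threshold,
                  config$criteria$protein_p_threshold),
          sprintf("- min unique peptides: %d; partner confidence >= %.3f; enrichment alpha %g",
                  config$min_peptides, config$min_confidence, config$alpha),
          "",
          "## Step 1: specificity screen", "",
          sprintf("- genes screened: %d", nrow(report$status)),
          sprintf("- status counts: %s",
                  paste(sprintf("%s=%d",
                                names(table(report$status$status)),
                                table(report$status$status)),
                        collapse = ", ")),
          sprintf("- primary candidates: %s",
                  if (nrow(report$candidates))
                    paste(report$candidates$gene_id, collapse = ", ")
                  else "none"),
          "",
          "## Step 2: partner cross-validation", "")
  for (g in names(report$branches)) {
    br <- report$branches[[g]]
    md <- c(md,
            sprintf("- %s: %d partner(s) at >= %.3f; %d retained (%s); branch set: %s",
                    g, length(br$partners), config$min_confidence,
                    sum(br$verdicts$verdict == "retained"),
                    if (any(br$verdicts$verdict == "retained"))
                      paste(br$verdicts$partner_id[
                        br$verdicts$verdict == "retained"], collapse = ", ")
                    else "none",
                    paste(br$final, collapse = ", ")))
  }
  md <- c(md, "", "## Step 3: enrichment", "")
  for (g in names(report$branches)) {
    enr <- report$branches[[g]]$enrichment
    md <- c(md, sprintf("- %s: %d term(s) at p < %g", g, nrow(enr),
                        config$alpha))
    if (nrow(enr))
      md <- c(md, sprintf("    - %s (%s): p=%.3g, q=%.3g, enrichment=%.2f (N=%d, B=%d, n=%d, b=%d)",
                          enr$term_id, enr$description, enr$p_value,
                          enr$q_value, enr$enrichment, enr$N, enr$B,
                          enr$n, enr$b))
  }
  md <- c(md, "",
          sprintf("## Final candidates (%d)", length(report$final)), "",
          if (length(report$final)) paste("-", report$final) else "- none")
  writeLines(md, out("report.md"))
  invisible(config$outdir)
}

#' Write the in-study worked-example fixture tables
#'
#' Emits a small, fully synthetic fixture encoding the published
#' worked example this screen is benchmarked against: two primary
#' candidates (FGA, FDFT) with their treatment/comparator transcript
#' statistics and protein evidence, the FGA neighbourhood (32 partners
#' at confidence >= 0.900, of which FGG, FGB, FGL1 and CST3 are
#' up-regulated and only FGG/FGB survive the comparator exclusion), the
#' FDFT neighbourhood (10 partners, none passing), decoy edges below
#' threshold, and term annotations over the ranked FGA neighbourhood.
#' Partner identifiers beyond the named genes are synthetic
#' placeholders (`PFP05`..`PFP32`, `QFP01`..`QFP10`).
#'
#' @param dir output directory (created if needed).
#' @return Named character vector of the file paths written
#'   (`treatment_contrast`, `comparator_contrast`, `proteins`,
#'   `network`, `annotations`, `term_names`).
#' @export
make_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fga_pfp <- sprintf("PFP%02d", 5:32)
  fdft_pfp <- sprintf("QFP%02d", 1:10)

  trt <- data.frame(
    gene_id = c("FGA", "FDFT", "FGG", "FGB", "FGL1", "CST3",
                fga_pfp, fdft_pfp),
    direction = "up",
    fc = c(2.24956, 2.37121, 2.10864, 2.33556, 2.43005, 2.42948,
           round(seq(1.02, 1.94, length.out = length(fga_pfp)), 2),
           round(seq(1.05, 1.95, by = 0.1), 2)),
    pfp = c(0.0002, 0, 0.0037, 0.0018, 0.0038, 0,
            rep(c(0.02, 0.6), 14),
            rep(c(0.01, 0.4), 5)),
    stringsAsFactors = FALSE)
  cmp <- data.frame(
    gene_id = trt$gene_id,
    direction = "up",
    fc = c(1.97551, 1.47764, 1.61716, 1.92234, 2.20802, 2.19668,
           round(seq(0.95, 1.85, length.out = length(fga_pfp)), 2),
           round(seq(1.00, 1.90, by = 0.1), 2)),
    pfp = c(0.0009, 0.0194, 0, 0.02, 0.0178, 0,
            rep(0.5, length(fga_pfp)),
            rep(0.5, 10)),
    stringsAsFactors = FALSE)

  prot <- data.frame(
    protein_id = c("NP_000499", "NP_004453", "NP_000500"),
    gene_symbol = c("FGA", "FDFT", "FGG"),
    unique_peptides = c(1L, 3L, 3L),
    ratio = c(3.81, 3.22, 1.97),
    p_value = c(0.00913822, 0.01571137, 0.07285596),
    stringsAsFactors = FALSE)

  fga_partners <- c("FGG", "FGB", "FGL1", "CST3", fga_pfp)
  net <- rbind(
    data.frame(protein1 = "FGA", protein2 = fga_partners,
               combined_score = seq(999, by = -1,
                                    length.out = length(fga_partners)),
               stringsAsFactors = FALSE),
    data.frame(protein1 = "FDFT", protein2 = fdft_pfp,
               combined_score = seq(955, by = -5,
                                    length.out = length(fdft_pfp)),
               stringsAsFactors = FALSE),
    data.frame(protein1 = c("FGA", "FGG"), protein2 = c("DEC01", "DEC02"),
               combined_score = c(850, 420), stringsAsFactors = FALSE))

  # ranked FGA universe: FGA, then partners by score descending
  ranked <- c("FGA", fga_partners)
  at <- function(pos) ranked[pos]
  ann <- rbind(
    data.frame(term_id = "GO:0030168", gene_id = at(c(1:8, 31:33))),
    data.frame(term_id = "GO:0051592", gene_id = at(1:3)),
    data.frame(term_id = "GO:0050817", gene_id = at(c(6:20, 33))),
    data.frame(term_id = "GO:0007599", gene_id = at(c(6:20, 33))),
    data.frame(term_id = "GO:0007596", gene_id = at(c(6:20, 33))),
    data.frame(term_id = "GO:0001775", gene_id = at(c(1:8, 27:32))),
    data.frame(term_id = "GO:0006887", gene_id = at(c(1:5, 7, 8, 31:33))),
    data.frame(term_id = "GO:0002576", gene_id = at(c(1:5, 7, 8, 31:33))),
    data.frame(term_id = "GO:0032940", gene_id = at(c(1:5, 7, 8, 31:33))))
  nm <- data.frame(
    term_id = c("GO:0030168", "GO:0051592", "GO:0050817", "GO:0007599",
                "GO:0007596", "GO:0001775", "GO:0006887", "GO:0002576",
                "GO:0032940"),
    description = c("Platelet activation", "Response to calcium ion",
                    "Coagulation", "Hemostasis", "Blood coagulation",
                    "Cell activation", "Exocytosis",
                    "Platelet degranulation", "Secretion by cell"),
    stringsAsFactors = FALSE)

  paths <- c(treatment_contrast = file.path(dir, "treatment_contrast.tsv"),
             comparator_contrast = file.path(dir, "comparator_contrast.tsv"),
             proteins = file.path(dir, "proteins.tsv"),
             network = file.path(dir, "network.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             term_names = file.path(dir, "term_names.tsv"))
  write_contrast(trt, paths["treatment_contrast"])
  write_contrast(cmp, paths["comparator_contrast"])
  write_proteins(prot, paths["proteins"])
  utils::write.table(net, paths["network"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ann, paths["annotations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(nm, paths["term_names"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
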