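#' Screening criteria for treatment-specific up-regulation
#'
#' All fold-change and significance comparisons in the screen are
#' strict: a transcript qualifies with fold change strictly greater
#' than `fc_threshold` and pfp strictly below `pfp_threshold`, and is
#' excluded when its comparator fold change strictly exceeds
#' `comparator_fc_exclusion` (the comparator rule tests fold change
#' only, not significance).
#'
#' @param fc_threshold treatment-vs-control fold-change threshold
#'   (default 2.0).
#' @param pfp_threshold rank-products pfp threshold (default 0.05).
#' @param comparator_fc_exclusion comparator-vs-control fold change
#'   above which a gene is excluded as non-specific (default 2.0).
#' @param protein_ratio_threshold protein fold-change threshold
#'   (default 2.0).
#' @param protein_p_threshold protein t-test p threshold (default 0.05).
#' @param require_protein must primary candidates show concordant
#'   protein evidence? Default `TRUE`; partner cross-validation uses
#'   `FALSE`.
#' @return An object of class `screen_criteria`.
#' @export
screen_criteria <- function(fc_threshold = 2.0,
                            pfp_threshold = 0.05,
                            comparator_fc_exclusion = 2.0,
                            protein_ratio_threshold = 2.0,
                            protein_p_threshold = 0.05,
                            require_protein = TRUE) {
  thresholds <- c(fc_threshold, pfp_threshold, comparator_fc_exclusion,
                  protein_ratio_threshold, protein_p_threshold)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop("all thresholds must be strictly positive")
  structure(list(fc_threshold = fc_threshold,
                 pfp_threshold = pfp_threshold,
                 comparator_fc_exclusion = comparator_fc_exclusion,
                 protein_ratio_threshold = protein_ratio_threshold,
                 protein_p_threshold = protein_p_threshold,
                 require_protein = isTRUE(require_protein)),
            class = "screen_criteria")
}

#' Classify one gene against the specificity screen
#'
#' Statuses are assigned in a fixed order so every gene gets exactly
#' one: `excluded_comparator` (comparator fold change exceeds the
#' exclusion threshold), `fails_transcript` (treatment fold change or
#' pfp fails), `no_protein_data` / `fails_protein` (protein evidence
#' required but absent or non-concordant), else `specific_candidate`.
#'
#' @param treatment list or one-row `data.frame` with `fc` and `pfp`
#'   for the treatment-vs-control contrast (optionally `gene_id`).
#' @param comparator same for the comparator-vs-control contrast.
#' @param protein optional list with `ratio` and `p_value`; `NULL`
#'   means no protein was quantified for this gene.
#' @param criteria a [screen_criteria()] object.
#' @return A single status string.
#' @export
#' @examples
#' classify_gene(list(fc = 2.25, pfp = 2e-4), list(fc = 1.98, pfp = 9e-4),
#'               list(ratio = 3.81, p_value = 0.009))
classify_gene <- function(treatment, comparator, protein = NULL,
                          criteria = screen_criteria()) {
  if (!is.null(treatment$gene_id) && !is.null(comparator$gene_id) &&
      !identical(as.character(treatment$gene_id),
                 as.character(comparator$gene_id)))
    stop("contrast rows refer to different genes: ",
         treatment$gene_id, " vs ", comparator$gene_id)
  if (comparator$fc > criteria$comparator_fc_exclusion)
    return("excluded_comparator")
  if (!(treatment$fc > criteria$fc_threshold &&
        treatment$pfp < criteria$pfp_threshold))
    return("fails_transcript")
  if (criteria$require_protein) {
    if (is.null(protein) || anyNA(c(protein$ratio, protein$p_value)))
      return("no_protein_data")
    if (!passes_protein_criterion(protein$ratio, protein$p_value, criteria))
      return("fails_protein")
  }
  "specific_candidate"
}

# pick the evidence row used for a gene when several proteins map to it:
# largest ratio, then most peptides, then protein id
best_protein_row <- function(proteins, gene) {
  rows <- proteins[proteins$gene_symbol == gene, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  rows <- rows[order(-rows$ratio, -rows$unique_peptides, rows$protein_id), ]
  as.list(rows[1, ])
}

#' Step 1 screen: treatment-specific candidates with protein concordance
#'
#' Applies [classify_gene()] over the shared gene universe of the two
#' contrasts and returns the candidates together with the full audit
#' status table.
#'
#' @param treatment contrast `data.frame` (columns `gene_id`, `fc`,
#'   `pfp`) for treatment vs control.
#' @param comparator contrast `data.frame` for comparator vs control.
#' @param proteins optional protein `data.frame` with `gene_symbol`,
#'   `ratio`, `p_value` (already peptide-filtered); genes without a row
#'   have no protein evidence.
#' @param criteria a [screen_criteria()] object.
#' @return List with `candidates` (status table rows with status
#'   `specific_candidate`, sorted by treatment fold change descending,
#'   ties by gene id) and `status` (one row per gene in the shared
#'   universe: `gene_id`, `status`, `treatment_fc`, `treatment_pfp`,
#'   `comparator_fc`, `protein_ratio`, `protein_p`).
#' @export
screen_step1 <- function(treatment, comparator, proteins = NULL,
                         criteria = screen_criteria()) {
  universe <- intersect(treatment$gene_id, comparator$gene_id)
  if (!length(universe))
    stop("the two contrasts share no genes")
  universe <- sort(universe)
  ti <- match(universe, treatment$gene_id)
  ci <- match(universe, comparator$gene_id)

  status <- character(length(universe))
  pratio <- rep(NA_real_, length(universe))
  pp <- rep(NA_real_, length(universe))
  for (i in seq_along(universe)) {
    prot <- if (!is.null(proteins)) best_protein_row(proteins, universe[i])
    if (!is.null(prot)) {
      pratio[i] <- prot$ratio
      pp[i] <- prot$p_value
    }
    status[i] <- classify_gene(
      list(gene_id = universe[i], fc = treatment$fc[ti[i]],
           pfp = treatment$pfp[ti[i]]),
      list(gene_id = universe[i], fc = comparator$fc[ci[i]],
           pfp = comparator$pfp[ci[i]]),
      prot, criteria)
  }

  status_tab <- data.frame(gene_id = universe,
                           status = status,
                           treatment_fc = treatment$fc[ti],
                           treatment_pfp = treatment$pfp[ti],
                           comparator_fc = comparator$fc[ci],
                           protein_ratio = pratio,
                           protein_p = pp,
                           stringsAsFactors = FALSE)
  cand <- status_tab[status_tab$status == "specific_candidate", ,
                     drop = FALSE]
  cand <- cand[order(-cand$treatment_fc, cand$gene_id), ]
  rownames(cand) <- rownames(status_tab) <- NULL
  list(candidates = cand, status = status_tab)
}
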