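#' Retain proteins quantified with at least k unique peptides
#'
#' @param table protein `data.frame` with a `unique_peptides` column.
#' @param k minimum unique-peptide count, default 2. Quantification from
#'   a single peptide is fragile, but `k = 1` is available for
#'   replication of published screens that reported single-peptide hits.
#' @return The filtered `data.frame`.
#' @export
filter_min_peptides <- function(table, k = 2) {
  if (k < 1) stop("'k' must be >= 1")
  if (!"unique_peptides" %in% names(table))
    stop("protein table must have a 'unique_peptides' column")
  table[table$unique_peptides >= k, , drop = FALSE]
}

#' Protein abundance ratio and arcsinh t-test
#'
#' The fold change is the ratio of arithmetic mean intensities on the
#' untransformed scale, `mean(group_b) / mean(group_a)`; the p-value
#' comes from a two-tailed pooled-variance t-test on arcsinh-transformed
#' intensities, the variance-stabilizing transform of choice for
#' label-free LC-MS data (it behaves like log for large intensities but
#' is defined at zero).
#'
#' Degenerate inputs: if both groups have zero variance after transform,
#' p is 1 when the means agree and 0 otherwise.
#'
#' @param group_a numeric intensities of the reference group (>= 2).
#' @param group_b numeric intensities of the group of interest (>= 2).
#' @return List with elements `ratio` and `p_value`.
#' @export
#' @examples
#' protein_test(c(1, 2, 3), c(2, 4, 6))$ratio  # 2
protein_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 values")
  ratio <- mean(group_b) / mean(group_a)
  ta <- asinh(group_a)
  tb <- asinh(group_b)
  if (stats::var(ta) == 0 && stats::var(tb) == 0) {
    p <- if (isTRUE(all.equal(mean(ta), mean(tb)))) 1 else 0
  } else {
    p <- stats::t.test(tb, ta, var.equal = TRUE)$p.value
  }
  list(ratio = ratio, p_value = p)
}

#' Add ratio and p-value columns to a protein intensity table
#'
#' @param table protein `data.frame` whose intensity columns are named
#'   by sample id.
#' @param conditions named character vector, sample id to condition.
#' @param cond_a reference condition (denominator).
#' @param cond_b condition of interest (numerator).
#' @return `table` with `ratio` and `p_value` columns appended.
#' @export
protein_stats <- function(table, conditions, cond_a, cond_b) {
  sa <- names(conditions)[conditions == cond_a]
  sb <- names(conditions)[conditions == cond_b]
  missing_cols <- setdiff(c(sa, sb), names(table))
  if (length(missing_cols))
    stop("intensity column(s) missing from protein table: ",
         paste(missing_cols, collapse = ", "))
  res <- lapply(seq_len(nrow(table)), function(i)
    protein_test(as.numeric(table[i, sa]), as.numeric(table[i, sb])))
  table$ratio <- vapply(res, `[[`, numeric(1), "ratio")
  table$p_value <- vapply(res, `[[`, numeric(1), "p_value")
  table
}

#' Does a protein pass the concordance criterion?
#'
#' @param ratio protein abundance fold change (treatment over control).
#' @param p_value two-tailed t-test p-value.
#' @param criteria a [screen_criteria()] object supplying
#'   `protein_ratio_threshold` and `protein_p_threshold`.
#' @return Logical vector; `TRUE` where `ratio` strictly exceeds the
#'   ratio threshold and `p_value` is strictly below the p threshold.
#' @export
passes_protein_criterion <- function(ratio, p_value,
                                     criteria = screen_criteria()) {
  ratio > criteria$protein_ratio_threshold &
    p_value < criteria$protein_p_threshold
}

#' Read or write protein quantification tables
#'
#' Protein tables are TSV with columns `protein_id`, `gene_symbol`,
#' `unique_peptides`, then either per-sample intensity columns (paired
#' with a condition-map sidecar) or precomputed `ratio` / `p_value`
#' columns for externally reported statistics.
#'
#' @param path file path.
#' @return `read_proteins()` returns the `data.frame`.
#' @export
read_proteins <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  needed <- c("protein_id", "gene_symbol", "unique_peptides")
  if (!all(needed %in% names(tab)))
    stop("protein table must have columns: ", paste(needed, collapse = ", "))
  tab
}

#' @param table protein `data.frame`.
#' @rdname read_proteins
#' @export
write_proteins <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
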