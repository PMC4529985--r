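#' Expression matrix with sample-to-condition labels
#'
#' Container for a normalized, strictly positive intensity matrix
#' (genes x samples) together with the mapping from sample to
#' experimental condition. Normalization (e.g. RMA for microarrays) is
#' assumed to have happened upstream.
#'
#' @param values numeric matrix, genes in rows and samples in columns;
#'   all values strictly positive, with unique rownames (gene ids) and
#'   unique colnames (sample ids).
#' @param conditions named character vector mapping every sample id in
#'   `colnames(values)` to a condition label.
#' @return An object of class `expr_matrix`: a list with elements
#'   `values` and `conditions` (reordered to match the matrix columns).
#' @export
#' @examples
#' m <- matrix(rexp(12) + 1, 2, 6,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' expr <- expression_matrix(m, setNames(rep(c("ctrl", "trt"), each = 3),
#'                                       paste0("s", 1:6)))
expression_matrix <- function(values, conditions) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("'values' must have unique rownames (gene ids)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("'values' must have unique colnames (sample ids)")
  if (anyNA(values))
    stop("'values' must not contain missing values")
  if (any(values <= 0))
    stop("'values' must be strictly positive")
  if (is.null(names(conditions)))
    stop("'conditions' must be a named character vector (sample -> condition)")
  missing_samples <- setdiff(colnames(values), names(conditions))
  if (length(missing_samples))
    stop("no condition label for sample(s): ",
         paste(missing_samples, collapse = ", "))
  structure(
    list(values = values,
         conditions = as.character(conditions)[match(colnames(values),
                                                     names(conditions))] |>
           stats::setNames(colnames(values))),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  tab <- table(x$conditions)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# sample ids belonging to one condition; errors on unknown condition
samples_of <- function(expr, condition) {
  s <- names(expr$conditions)[expr$conditions == condition]
  if (!length(s)) stop("unknown or empty condition: ", condition)
  s
}

#' Read an expression matrix and its condition map from TSV
#'
#' The matrix file has a `gene_id` first column and one column per sample;
#' the condition map has columns `sample_id` and `condition`.
#'
#' @param path path to the intensity TSV.
#' @param conditions_path path to the two-column sample-to-condition TSV.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, conditions_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  cmap <- utils::read.delim(conditions_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(cmap)))
    stop("condition map must have columns 'sample_id' and 'condition'")
  expression_matrix(m, stats::setNames(cmap$condition, cmap$sample_id))
}

#' Write an expression matrix and its condition map as TSV
#'
#' @param expr an [expression_matrix()] object.
#' @param path output path for the intensity TSV.
#' @param conditions_path output path for the sample-to-condition TSV.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path, conditions_path) {
  out <- data.frame(gene_id = rownames(expr$values), expr$values,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cmap <- data.frame(sample_id = names(expr$conditions),
                     condition = unname(expr$conditions))
  utils::write.table(cmap, conditions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# run code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  code
}
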