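#' Per-gene fold change between two conditions
#'
#' Ratio of arithmetic mean intensities, condition `cond_b` over
#' `cond_a` (treatment-over-control convention).
#'
#' @param expr an [expression_matrix()] object.
#' @param cond_a reference condition label (denominator).
#' @param cond_b condition label of interest (numerator).
#' @param genes optional character vector restricting the result to a
#'   subset of genes; unknown genes are an error.
#' @return Named numeric vector of strictly positive fold changes.
#' @export
#' @examples
#' m <- matrix(c(10, 10, 10, 20, 20, 20), 1, 6,
#'             dimnames = list("g1", paste0("s", 1:6)))
#' expr <- expression_matrix(m, setNames(rep(c("a", "b"), each = 3),
#'                                       paste0("s", 1:6)))
#' fold_change(expr, "a", "b")  # 2
fold_change <- function(expr, cond_a, cond_b, genes = NULL) {
  sa <- samples_of(expr, cond_a)
  sb <- samples_of(expr, cond_b)
  fc <- rowMeans(expr$values[, sb, drop = FALSE]) /
    rowMeans(expr$values[, sa, drop = FALSE])
  if (!is.null(genes)) {
    unknown <- setdiff(genes, names(fc))
    if (length(unknown))
      stop("unknown gene(s): ", paste(unknown, collapse = ", "))
    fc <- fc[genes]
  }
  fc
}

# per-pairing up/down-regulation ranks: one column per replicate pairing
# (n_b x n_a ratios cond_b/cond_a), ties averaged, rank 1 = strongest
# change in the requested direction
pairing_ranks <- function(expr, cond_a, cond_b, direction) {
  sa <- samples_of(expr, cond_a)
  sb <- samples_of(expr, cond_b)
  if (length(sa) < 2 || length(sb) < 2)
    stop("rank products need >= 2 replicates per condition (got ",
         length(sa), " and ", length(sb), ")")
  pairs <- expand.grid(b = sb, a = sa, stringsAsFactors = FALSE)
  ranks <- vapply(seq_len(nrow(pairs)), function(i) {
    ratio <- expr$values[, pairs$b[i]] / expr$values[, pairs$a[i]]
    if (direction == "up") rank(-ratio, ties.method = "average")
    else rank(ratio, ties.method = "average")
  }, numeric(nrow(expr$values)))
  ranks <- matrix(ranks, nrow = nrow(expr$values),
                  dimnames = list(rownames(expr$values), NULL))
  ranks
}

#' Rank-products statistic for a two-condition contrast
#'
#' For each of the `n_a x n_b` replicate pairings the per-gene ratio
#' `cond_b / cond_a` is ranked across genes (rank 1 = most up-regulated
#' for `direction = "up"`, most down-regulated for `"down"`, ties
#' averaged); the rank product is the geometric mean of a gene's ranks
#' over all pairings. Small values indicate consistent regulation.
#'
#' @inheritParams fold_change
#' @param direction `"up"` or `"down"`.
#' @return Named numeric vector of rank products (all `>= 1`).
#' @export
rank_products <- function(expr, cond_a, cond_b, direction = c("up", "down")) {
  direction <- match.arg(direction)
  ranks <- pairing_ranks(expr, cond_a, cond_b, direction)
  exp(rowMeans(log(ranks)))
}

#' Rank products with permutation-estimated percentage of false positives
#'
#' Computes the rank product (rp) for every gene and estimates, for each
#' gene, the percentage of false positives (pfp) incurred by calling all
#' genes with an rp at least as small. The permutation null is built by
#' independently shuffling each pairing's rank vector across genes
#' `n_perm` times; for a gene with observed rank product `rp` at
#' ascending rank position `r`, `E = #(null rp <= rp) / n_perm` and
#' `pfp = E / r`. A step-down cumulative maximum enforces that pfp is
#' non-decreasing down the sorted list, so significance sets are nested.
#' pfp is not capped at 1. Residual ordering ties are broken by gene id.
#'
#' @inheritParams rank_products
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation null (required).
#' @return A `data.frame` with columns `gene_id`, `direction`, `fc`,
#'   `rp`, `rank` (ascending rp position) and `pfp`, in the gene order
#'   of `expr`.
#' @export
estimate_pfp <- function(expr, cond_a, cond_b, direction = c("up", "down"),
                         n_perm = 1000, seed = NULL) {
  direction <- match.arg(direction)
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  ranks <- pairing_ranks(expr, cond_a, cond_b, direction)
  log_ranks <- log(ranks)
  n <- nrow(ranks)
  k <- ncol(ranks)
  obs <- rowMeans(log_ranks)  # log rank product

  null_log <- with_seed(seed, {
    out <- numeric(n * n_perm)
    for (p in seq_len(n_perm)) {
      acc <- numeric(n)
      for (j in seq_len(k))
        acc <- acc + log_ranks[sample.int(n), j]
      out[((p - 1L) * n + 1L):(p * n)] <- acc / k
    }
    out
  })
  null_sorted <- sort(null_log)

  ord <- order(obs, rownames(ranks))
  E <- findInterval(obs[ord], null_sorted) / n_perm
  pfp_sorted <- cummax(E / seq_len(n))
  pfp <- numeric(n)
  pfp[ord] <- pfp_sorted
  position <- integer(n)
  position[ord] <- seq_len(n)

  data.frame(gene_id = rownames(ranks),
             direction = direction,
             fc = unname(fold_change(expr, cond_a, cond_b)),
             rp = unname(exp(obs)),
             rank = position,
             pfp = pfp,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Collapse probe-level results to gene level by maximum fold change
#'
#' When several probes map to one gene symbol, the probe with the
#' largest fold change in the contrast is retained and carries its rp
#' and pfp (the "maximum" convention); ties go to the lexicographically
#' smallest probe id.
#'
#' @param contrast a contrast result `data.frame` as returned by
#'   [estimate_pfp()] (probe ids in `gene_id`).
#' @param gene_of named character vector mapping probe id to gene
#'   symbol; probes without a mapping keep their own id.
#' @return The collapsed `data.frame` with `gene_id` replaced by the
#'   gene symbol and an extra `probe_id` column.
#' @export
collapse_probes <- function(contrast, gene_of) {
  symbol <- gene_of[contrast$gene_id]
  symbol[is.na(symbol)] <- contrast$gene_id[is.na(symbol)]
  ord <- order(symbol, -contrast$fc, contrast$gene_id)
  picked <- contrast[ord, ][!duplicated(symbol[ord]), , drop = FALSE]
  picked$probe_id <- picked$gene_id
  picked$gene_id <- symbol[ord][!duplicated(symbol[ord])]
  rownames(picked) <- NULL
  picked[order(picked$gene_id), ]
}

#' Read or write contrast result tables
#'
#' Contrast tables are TSV with columns `gene_id`, `direction`, `fc`,
#' `rp`, `pfp` (plus any extras); `rp` may be absent when the table
#' encodes externally reported statistics.
#'
#' @param path file path.
#' @return `read_contrast()` returns the `data.frame`.
#' @export
read_contrast <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "fc", "pfp")
  if (!all(needed %in% names(tab)))
    stop("contrast table must have columns: ", paste(needed, collapse = ", "))
  tab
}

#' @param contrast a contrast result `data.frame`.
#' @rdname read_contrast
#' @export
write_contrast <- function(contrast, path) {
  utils::write.table(contrast, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
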