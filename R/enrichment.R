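#' Enrichment ratio (b/n) / (B/N)
#'
#' Over-representation of a term's genes within the top `n` of a ranked
#' universe of `N` genes: `b` of the top `n` carry the term, which has
#' `B` carriers in the whole universe.
#'
#' @param N universe size (`>= 1`).
#' @param B term carriers in the universe (`0 <= B <= N`).
#' @param n threshold depth (`1 <= n <= N`).
#' @param b term carriers within the top `n` (`0 <= b <= min(n, B)`).
#' @return `(b/n) / (B/N)`; `NaN` when `B = 0` (undefined, not an
#'   error).
#' @export
#' @examples
#' enrichment_ratio(33, 11, 8, 8)  # 3
enrichment_ratio <- function(N, B, n, b) {
  check_enrichment_bounds(N, B, n, b)
  if (B == 0) return(NaN)
  (b / n) / (B / N)
}

check_enrichment_bounds <- function(N, B, n, b) {
  if (N < 1) stop("'N' must be >= 1")
  if (B < 0 || B > N) stop("'B' must be in [0, N]")
  if (n < 1 || n > N) stop("'n' must be in [1, N]")
  if (b < 0 || b > min(n, B)) stop("'b' must be in [0, min(n, B)]")
  invisible(TRUE)
}

#' Upper hypergeometric tail P(X >= b)
#'
#' Probability that at least `b` of `n` draws without replacement from
#' a population of `N` with `B` successes are successes. Computed by
#' exact summation of the hypergeometric mass over the support; no
#' normal approximation.
#'
#' @inheritParams enrichment_ratio
#' @return Probability in `[0, 1]`; `b = 0` gives 1.
#' @export
#' @examples
#' hypergeom_tail(33, 3, 3, 3)  # 1 / choose(33, 3)
hypergeom_tail <- function(N, B, n, b) {
  check_enrichment_bounds(N, B, n, b)
  if (b == 0) return(1)
  stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
}

#' Minimum hypergeometric statistic over all prefix depths
#'
#' Scans every prefix depth `n = 1..N` of a ranked binary membership
#' vector, evaluates the hypergeometric tail at `(n, b(n))` and returns
#' the depth minimizing it (smallest `n` on ties). This is the
#' threshold-free ranked enrichment statistic (mHG) popularized by
#' GOrilla-style tools.
#'
#' @param flags logical or 0/1 vector: membership of each ranked gene,
#'   best rank first.
#' @return List with `n` (optimal depth), `b` (members within it),
#'   `p` (the minimum tail probability) and `B` (total members).
#' @export
min_hypergeom <- function(flags) {
  flags <- as.integer(as.logical(flags))
  N <- length(flags)
  if (N < 1) stop("'flags' must have length >= 1")
  B <- sum(flags)
  if (B == 0) return(list(n = 1L, b = 0L, p = 1, B = 0L))
  b_at <- cumsum(flags)
  p_at <- stats::phyper(b_at - 1, B, N - B, seq_len(N), lower.tail = FALSE)
  p_at[b_at == 0] <- 1
  # smallest n on ties; the tolerance absorbs floating-point noise between
  # mathematically identical tail probabilities at different depths
  n_star <- which(p_at <= min(p_at) * (1 + 1e-9))[1]
  list(n = n_star, b = b_at[n_star], p = p_at[n_star], B = B)
}

#' Exact mHG-corrected p-value
#'
#' The minimum over N dependent hypergeometric tails is an optimistic
#' p-value. This computes the exact null probability that the minimum
#' tail statistic is at most `s`, by counting, with a dynamic program
#' over the rank lattice, the arrangements of `B` members among `N`
#' positions whose prefix path avoids every cell with tail probability
#' `<= s`. Runs in O(N * B).
#'
#' @param N universe size.
#' @param B number of members.
#' @param s the observed minimum hypergeometric tail (e.g. `p` from
#'   [min_hypergeom()]).
#' @return `P(mHG <= s)` under uniform random ranking.
#' @export
mhg_pvalue <- function(N, B, s) {
  if (B < 0 || B > N) stop("'B' must be in [0, N]")
  if (B == 0) return(if (s >= 1) 1 else 0)
  # logf[b + 1] = log #paths reaching (n, b) avoiding significant cells
  logf <- c(0, rep(-Inf, B))
  for (n in seq_len(N)) {
    b_hi <- min(n, B)
    b_lo <- max(0L, n - (N - B))
    new <- rep(-Inf, B + 1)
    for (b in b_lo:b_hi) {
      stay <- if (b <= n - 1) logf[b + 1] else -Inf      # position n not a member
      step <- if (b >= 1) logf[b] else -Inf              # position n a member
      v <- max(stay, step)
      if (is.finite(v))
        v <- v + log(exp(stay - v) + exp(step - v))
      # kill paths entering a cell at least as extreme as observed
      if (stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE) <= s)
        v <- -Inf
      new[b + 1] <- v
    }
    logf <- new
  }
  1 - exp(logf[B + 1] - lchoose(N, B))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order, `q >= p` elementwise.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Ranked enrichment universe around a target gene
#'
#' The universe is the target gene followed by its high-confidence
#' partners ranked by network confidence score descending (ties broken
#' by identifier), as used for confidence-ranked enrichment.
#'
#' @param network an [interaction_network()] object.
#' @param target target gene identifier.
#' @param min_confidence inclusive fractional confidence threshold
#'   (default 0.900).
#' @return Character vector: `target` first, then its ranked partners.
#' @export
ranked_universe <- function(network, target, min_confidence = 0.900) {
  c(target, partners(network, target, min_confidence))
}

#' Ranked gene-set enrichment over an annotated universe
#'
#' For every term with at least one carrier in the universe, the
#' minimum-hypergeometric scan picks the optimal prefix depth, the
#' enrichment ratio `(b/n)/(B/N)` is reported at that depth, and
#' Benjamini-Hochberg q-values are computed across all tested terms.
#'
#' By default `p_value` is the raw minimum hypergeometric tail;
#' `mhg_correct = TRUE` replaces it with the exact mHG-corrected
#' p-value from [mhg_pvalue()].
#'
#' @param ranked character vector of ranked gene identifiers (no
#'   duplicates), e.g. from [ranked_universe()].
#' @param annotations `data.frame` with columns `term_id`, `gene_id`.
#' @param alpha report only terms with `p_value < alpha` (default
#'   0.05); BH correction always runs over all tested terms.
#' @param term_names optional `data.frame` with columns `term_id`,
#'   `description`.
#' @param mhg_correct apply the exact mHG correction (default `FALSE`).
#' @return `data.frame` sorted by `p_value` ascending (ties by term id)
#'   with columns `term_id`, `description`, `p_value`, `q_value`,
#'   `enrichment`, `N`, `B`, `n`, `b`.
#' @export
enrich_all <- function(ranked, annotations, alpha = 0.05,
                       term_names = NULL, mhg_correct = FALSE) {
  if (!length(ranked)) stop("'ranked' must be non-empty")
  if (anyDuplicated(ranked)) stop("'ranked' must not contain duplicates")
  if (!all(c("term_id", "gene_id") %in% names(annotations)))
    stop("annotations must have columns 'term_id' and 'gene_id'")
  N <- length(ranked)
  ann <- annotations[annotations$gene_id %in% ranked, , drop = FALSE]
  terms <- sort(unique(ann$term_id))
  if (!length(terms))
    return(empty_enrichment(term_names))

  rows <- lapply(terms, function(tm) {
    members <- unique(ann$gene_id[ann$term_id == tm])
    flags <- ranked %in% members
    mh <- min_hypergeom(flags)
    p <- if (mhg_correct) mhg_pvalue(N, mh$B, mh$p) else mh$p
    data.frame(term_id = tm, p_value = p,
               enrichment = enrichment_ratio(N, mh$B, mh$n, mh$b),
               N = N, B = mh$B, n = mh$n, b = mh$b,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res$description <- term_description(res$term_id, term_names)
  res <- res[res$p_value < alpha, , drop = FALSE]
  res <- res[order(res$p_value, res$term_id),
             c("term_id", "description", "p_value", "q_value",
               "enrichment", "N", "B", "n", "b")]
  rownames(res) <- NULL
  res
}

term_description <- function(term_ids, term_names) {
  if (is.null(term_names)) return(term_ids)
  i <- match(term_ids, term_names$term_id)
  ifelse(is.na(i), term_ids, term_names$description[i])
}

empty_enrichment <- function(term_names) {
  data.frame(term_id = character(0), description = character(0),
              p_value = numeric(0), q_value = numeric(0),
              enrichment = numeric(0), N = integer(0), B = integer(0),
              n = integer(0), b = integer(0), stringsAsFactors = FALSE)
}

#' Read a two-column term-to-gene annotation TSV
#'
#' @param path annotation TSV with columns `term_id`, `gene_id`.
#' @param names_path optional TSV with columns `term_id`,
#'   `description`.
#' @return `data.frame` (the annotation table; with `names_path`, a
#'   list with elements `annotations` and `term_names`).
#' @export
read_annotations <- function(path, names_path = NULL) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(ann)))
    stop("annotation table must have columns 'term_id' and 'gene_id'")
  if (is.null(names_path)) return(ann)
  nm <- utils::read.delim(names_path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "description") %in% names(nm)))
    stop("term-name table must have columns 'term_id' and 'description'")
  list(annotations = ann, term_names = nm)
}
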