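#' Undirected scored interaction network
#'
#' Edge-table container in the STRING `protein.links` dialect:
#' `protein1`, `protein2`, `combined_score`. Self-edges are dropped and
#' symmetric or repeated pairs are collapsed keeping the maximum score.
#' The score scale is auto-detected: all scores `<= 1` means fractional
#' (0-1 probabilities), otherwise the STRING integer scale (0-1000);
#' scores above 1000 are an error.
#'
#' @param edges `data.frame` with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param scale `"auto"` (default), `"integer"` or `"fractional"`.
#' @return An object of class `interaction_network`: the canonical edge
#'   `data.frame` with attribute `scale`.
#' @export
interaction_network <- function(edges, scale = c("auto", "integer",
                                                 "fractional")) {
  scale <- match.arg(scale)
  needed <- c("protein1", "protein2", "combined_score")
  if (!all(needed %in% names(edges)))
    stop("edge table must have columns: ", paste(needed, collapse = ", "))
  edges$protein1 <- as.character(edges$protein1)
  edges$protein2 <- as.character(edges$protein2)
  score <- edges$combined_score
  if (anyNA(score) || !is.numeric(score))
    stop("non-numeric combined_score in row(s): ",
         paste(utils::head(which(is.na(suppressWarnings(as.numeric(score)))),
                           5), collapse = ", "))
  if (any(score < 0) || any(score > 1000))
    stop("combined_score outside [0, 1000]")
  if (scale == "auto")
    scale <- if (nrow(edges) && max(score) <= 1) "fractional" else "integer"

  keep <- edges$protein1 != edges$protein2
  edges <- edges[keep, , drop = FALSE]
  a <- pmin(edges$protein1, edges$protein2)
  b <- pmax(edges$protein1, edges$protein2)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -edges$combined_score)
  first <- !duplicated(key[ord])
  out <- data.frame(protein1 = a[ord][first],
                    protein2 = b[ord][first],
                    combined_score = edges$combined_score[ord][first],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, scale = scale, class = c("interaction_network",
                                          "data.frame"))
}

#' Load a STRING-dialect interaction file
#'
#' Accepts space- or tab-separated files with a
#' `protein1 protein2 combined_score` header.
#'
#' @param path file path.
#' @return An [interaction_network()] object.
#' @export
load_interactions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  needed <- c("protein1", "protein2", "combined_score")
  if (!all(needed %in% names(raw)))
    stop("malformed header in ", path, "; need columns: ",
         paste(needed, collapse = " "))
  score_num <- suppressWarnings(as.numeric(raw$combined_score))
  bad <- which(is.na(score_num))
  if (length(bad))
    stop("malformed combined_score in ", path, " at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  raw$combined_score <- score_num
  interaction_network(raw)
}

# scores on the fractional 0-1 scale regardless of storage scale
fractional_scores <- function(network) {
  s <- network$combined_score
  if (identical(attr(network, "scale"), "integer")) s / 1000 else s
}

#' High-confidence interaction partners of a gene
#'
#' @param network an [interaction_network()] object.
#' @param gene gene/protein identifier; unknown identifiers yield an
#'   empty set with a warning.
#' @param min_confidence inclusive confidence threshold on the
#'   fractional scale (default 0.900, the "highest confidence" STRING
#'   band).
#' @return Character vector of partner identifiers (sorted by
#'   confidence descending, ties by identifier).
#' @export
partners <- function(network, gene, min_confidence = 0.900) {
  sc <- partner_scores(network, gene, min_confidence)
  names(sc)
}

#' @return `partner_scores()` returns the same set as a named numeric
#'   vector of fractional confidence scores.
#' @rdname partners
#' @export
partner_scores <- function(network, gene, min_confidence = 0.900) {
  known <- gene %in% network$protein1 | gene %in% network$protein2
  if (!known) {
    warning("gene not present in the network: ", gene)
    return(stats::setNames(numeric(0), character(0)))
  }
  frac <- fractional_scores(network)
  hit <- (network$protein1 == gene | network$protein2 == gene) &
    frac >= min_confidence
  other <- ifelse(network$protein1[hit] == gene,
                  network$protein2[hit], network$protein1[hit])
  sc <- stats::setNames(frac[hit], other)
  sc[order(-sc, names(sc))]
}

#' Rename network identifiers through an alias table
#'
#' @param network an [interaction_network()] object.
#' @param aliases `data.frame` with columns `protein_id`,
#'   `gene_symbol`. Identifiers without an alias are kept unchanged and
#'   reported in a warning, never dropped.
#' @return A re-canonicalized [interaction_network()].
#' @export
map_aliases <- function(network, aliases) {
  if (!all(c("protein_id", "gene_symbol") %in% names(aliases)))
    stop("alias table must have columns 'protein_id' and 'gene_symbol'")
  lut <- stats::setNames(as.character(aliases$gene_symbol),
                         as.character(aliases$protein_id))
  ids <- unique(c(network$protein1, network$protein2))
  unmapped <- setdiff(ids, names(lut))
  if (length(unmapped))
    warning("identifier(s) without alias kept as-is: ",
            paste(utils::head(unmapped, 10), collapse = ", "))
  remap <- function(x) ifelse(x %in% names(lut), unname(lut[x]), x)
  out <- data.frame(protein1 = remap(network$protein1),
                    protein2 = remap(network$protein2),
                    combined_score = network$combined_score,
                    stringsAsFactors = FALSE)
  interaction_network(out, scale = attr(network, "scale"))
}

#' Cross-validate network partners against the transcript criteria
#'
#' Partners are re-screened with exactly the transcript sub-criteria of
#' the primary screen (fold change and pfp in the treatment contrast,
#' comparator fold-change exclusion); protein evidence is not required
#' at this step, which is how partners lacking proteomics can be
#' rescued. Partners without contrast data are reported as
#' `unevaluable`, never dropped.
#'
#' @param partner_ids character vector of partner identifiers.
#' @param treatment,comparator contrast `data.frame`s as in
#'   [screen_step1()].
#' @param criteria a [screen_criteria()] object (its `require_protein`
#'   flag is ignored here).
#' @return `data.frame` with columns `partner_id`, `treatment_fc`,
#'   `treatment_pfp`, `comparator_fc`, `verdict` (one of `retained`,
#'   `excluded_comparator`, `fails_transcript`, `unevaluable`).
#' @export
crossval_partners <- function(partner_ids, treatment, comparator,
                              criteria = screen_criteria()) {
  transcript_only <- criteria
  transcript_only$require_protein <- FALSE
  ti <- match(partner_ids, treatment$gene_id)
  ci <- match(partner_ids, comparator$gene_id)
  verdict <- character(length(partner_ids))
  for (i in seq_along(partner_ids)) {
    if (is.na(ti[i]) || is.na(ci[i])) {
      verdict[i] <- "unevaluable"
      next
    }
    cls <- classify_gene(
      list(gene_id = partner_ids[i], fc = treatment$fc[ti[i]],
           pfp = treatment$pfp[ti[i]]),
      list(gene_id = partner_ids[i], fc = comparator$fc[ci[i]],
           pfp = comparator$pfp[ci[i]]),
      NULL, transcript_only)
    verdict[i] <- if (cls == "specific_candidate") "retained" else cls
  }
  data.frame(partner_id = partner_ids,
             treatment_fc = treatment$fc[ti],
             treatment_pfp = treatment$pfp[ti],
             comparator_fc = comparator$fc[ci],
             verdict = verdict,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Final candidate set: primary candidates plus retained partners
#'
#' @param candidates the `candidates` table from [screen_step1()].
#' @param verdicts a [crossval_partners()] result (or several,
#'   row-bound).
#' @return Character vector of gene identifiers: the union of primary
#'   candidates and retained partners, ordered by treatment fold change
#'   descending, ties by identifier.
#' @export
final_candidates <- function(candidates, verdicts = NULL) {
  ids <- candidates$gene_id
  fc <- candidates$treatment_fc
  if (!is.null(verdicts) && nrow(verdicts)) {
    kept <- verdicts[verdicts$verdict == "retained", , drop = FALSE]
    ids <- c(ids, kept$partner_id)
    fc <- c(fc, kept$treatment_fc)
  }
  keep <- !duplicated(ids)
  ids <- ids[keep]
  fc <- fc[keep]
  ids[order(-fc, ids)]
}
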