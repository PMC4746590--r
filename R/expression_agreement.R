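#' Expression breadth per gene
#'
#' Number of tissues in which a gene's abundance strictly exceeds the
#' detection threshold.
#'
#' @param expr Numeric matrix, genes x tissues (row names = genes).
#' @param detect_threshold Abundance threshold (default 0: any non-zero
#'   signal counts as detected).
#' @return Named integer vector gene -> number of tissues detected.
#' @export
tissue_breadth <- function(expr, detect_threshold = 0) {
  stopifnot(detect_threshold >= 0)
  stats::setNames(as.integer(rowSums(expr > detect_threshold)),
                  rownames(expr))
}

#' Correlate expression breadth with cancer gene specificity
#'
#' Pearson correlation (with Fisher-transform p value) between per-gene
#' expression breadth and (a) the specificity score and (b) the raw number
#' of significantly mutated tumor types, over the gene intersection.
#'
#' @param breadth Named vector from [tissue_breadth()].
#' @param scores A \code{specificity_table}.
#' @return List with \code{score} and \code{raw_k}, each a
#'   [correlate()] result.
#' @export
breadth_specificity_correlation <- function(breadth, scores) {
  s <- stats::setNames(scores$score, scores$gene)
  k <- stats::setNames(as.numeric(scores$k), scores$gene)
  list(score = correlate(breadth, s), raw_k = correlate(breadth, k))
}

#' Match highest-expression tissue against tissue of pathology
#'
#' For genes specifically associated with a single solid tumor type, finds
#' the tissue(s) of maximal abundance and labels each gene
#' \code{direct} (an argmax tissue is the mapped pathology tissue),
#' \code{adjacent} (an argmax tissue is adjacent to it) or \code{none}.
#' Ties at the maximum count as a match if any tied tissue qualifies —
#' deliberately generous toward agreement, so a negative result cannot be
#' blamed on tie handling.
#'
#' @param specific_types Named character: gene -> its single cancer type.
#' @param expr Expression matrix (genes x tissues).
#' @param tmap A \code{tissue_map}; cancer types are mapped to tissues and
#'   adjacency is looked up on the fine labels.
#' @return List with \code{match} (named character per evaluable gene) and
#'   \code{counts} (table over direct/adjacent/none).
#' @details Genes absent from the expression matrix or with an unmappable
#'   cancer type are excluded with a log message.
#' @export
top_tissue_match <- function(specific_types, expr, tmap) {
  genes <- names(specific_types)
  in_expr <- genes %in% rownames(expr)
  mapped <- specific_types %in% names(tmap$cancer_to_tissue)
  excluded <- genes[!(in_expr & mapped)]
  if (length(excluded) > 0) {
    message(length(excluded),
            " gene(s) unmappable or without expression; excluded")
  }
  genes <- genes[in_expr & mapped]
  match_lab <- vapply(genes, function(g) {
    target <- unname(tmap$cancer_to_tissue[[specific_types[[g]]]])
    row <- expr[g, ]
    if (all(row <= 0)) return("none")
    argmax <- colnames(expr)[row == max(row)]
    if (target %in% argmax) return("direct")
    adj <- adjacent_tissues(tmap, target)
    if (length(intersect(argmax, adj)) > 0) return("adjacent")
    "none"
  }, "")
  counts <- table(factor(match_lab, levels = c("direct", "adjacent", "none")))
  list(match = match_lab, counts = counts)
}

#' Binomial test for expression/pathology agreement
#'
#' Upper-tail binomial probability of observing at least \code{n_matches}
#' agreements among \code{n_genes} genes when each gene matches by chance
#' with probability \code{p0}.
#'
#' @param n_matches Observed number of matching genes.
#' @param n_genes Number of evaluable genes.
#' @param p0 Per-gene chance probability of a match, in (0, 1). A natural
#'   default is (1 + number of adjacent tissues) / number of expression
#'   tissues, averaged over genes.
#' @return One-sided p value, P(X >= n_matches).
#' @export
binomial_match_test <- function(n_matches, n_genes, p0) {
  stopifnot(n_matches >= 0, n_matches <= n_genes)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly inside (0, 1)")
  stats::pbinom(n_matches - 1, n_genes, p0, lower.tail = FALSE)
}

#' Default chance probability of an expression/pathology match
#'
#' For each gene, (1 + number of tissues adjacent to its mapped pathology
#' tissue) / number of expression tissues; averaged over genes.
#'
#' @param specific_types Named character: gene -> cancer type.
#' @param expr Expression matrix.
#' @param tmap A \code{tissue_map}.
#' @return A probability in (0, 1).
#' @export
match_null_probability <- function(specific_types, expr, tmap) {
  n_tissues <- ncol(expr)
  types <- specific_types[specific_types %in% names(tmap$cancer_to_tissue)]
  p_per_gene <- vapply(types, function(ty) {
    target <- unname(tmap$cancer_to_tissue[[ty]])
    (1 + length(adjacent_tissues(tmap, target))) / n_tissues
  }, 0)
  mean(p_per_gene)
}
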