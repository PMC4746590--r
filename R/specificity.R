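#' Cancer gene specificity score
#'
#' Combines, for one gene, the smallest single tumor-type mutation
#' enrichment q value (\code{mostQ}), the pan-cancer q value (\code{panQ})
#' and the number of tumor types in which the gene is significantly mutated
#' (\code{k}):
#' \deqn{S = \log_{10}\frac{mostQ + \epsilon}{panQ + \epsilon} + k}
#' A gene highly significant in a single type but not in the pooled
#' pan-cancer cohort gets a small (negative) score — it is tissue-specific.
#' A gene with strong pan-cancer significance and/or many significant types
#' gets a large score — it is a general cancer gene. S is strictly
#' increasing in \code{mostQ} and \code{k} and strictly decreasing in
#' \code{panQ}.
#'
#' @param mostQ Smallest per-type q value in [0, 1].
#' @param panQ Pan-cancer q value in [0, 1].
#' @param k Number of tumor types with q below the significance threshold.
#' @param epsilon Pseudocount guarding q = 0 entries (mutation significance
#'   tables do contain exact zeros). Default 1e-16.
#' @return Numeric score (unitless); small = specific, large = general.
#' @examples
#' compute_specificity(1e-10, 1.0, 1)   # -9: highly specific
#' compute_specificity(1e-2, 1e-12, 8)  # 18: highly general
#' @export
compute_specificity <- function(mostQ, panQ, k, epsilon = 1e-16) {
  stopifnot(epsilon > 0)
  if (any(mostQ < 0 | mostQ > 1) || any(panQ < 0 | panQ > 1)) {
    stop("q values must lie in [0, 1]")
  }
  log10((mostQ + epsilon) / (panQ + epsilon)) + k
}

#' Score and rank all genes of a mutation significance table
#'
#' Derives per gene: \code{mostQ} (minimum over the tumor-type q values),
#' \code{panQ}, \code{k} (count of types with q strictly below \code{tau})
#' and the specificity score, then ranks ascending (rank 1 = most
#' specific). Score ties are broken by placing the gene with the smaller
#' \code{panQ} (more pan-significant, hence more general) later, then by
#' gene identifier; ranking is therefore deterministic and independent of
#' input row order.
#'
#' @param table A \code{mutsig} object from [read_mutation_table()].
#' @param tau Per-type significance threshold defining \code{k}
#'   (default 0.1).
#' @param epsilon Pseudocount for the score; see [compute_specificity()].
#' @return A \code{specificity_table}: data.frame with columns \code{gene},
#'   \code{mostQ}, \code{panQ}, \code{k}, \code{score}, \code{rank} and a
#'   list column \code{sig_types} (the tumor types with q < tau), sorted by
#'   rank.
#' @export
rank_genes <- function(table, tau = 0.1, epsilon = 1e-16) {
  stopifnot(inherits(table, "mutsig"), tau > 0, tau < 1)
  if (length(table$gene) < 2) stop("need at least 2 genes to rank")
  mostQ <- apply(table$q_type, 1, min)
  k <- as.integer(rowSums(table$q_type < tau))
  panQ <- table$pan_q
  if (any(k == 0 & mostQ < tau)) {
    # cannot happen by construction; keep the guard for clarity
  }
  zero_k_sig <- k == 0 & (panQ < tau)
  if (any(zero_k_sig)) {
    warning(sum(zero_k_sig), " gene(s) pan-significant but significant in ",
            "no single tumor type (k = 0); kept", call. = FALSE)
  }
  score <- compute_specificity(mostQ, panQ, k, epsilon)
  ord <- order(score, -panQ, table$gene)
  sig_types <- lapply(seq_along(table$gene), function(i) {
    colnames(table$q_type)[table$q_type[i, ] < tau]
  })
  out <- data.frame(gene = table$gene[ord], mostQ = unname(mostQ[ord]),
                    panQ = unname(panQ[ord]), k = k[ord],
                    score = unname(score[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$sig_types <- sig_types[ord]
  attr(out, "tau") <- tau
  attr(out, "epsilon") <- epsilon
  class(out) <- c("specificity_table", "data.frame")
  out
}

#' Drop heavily studied genes and re-rank
#'
#' Study-bias control: genes linked to more than \code{max_studies}
#' publications are removed and ranks recomputed on the remaining genes.
#' Genes absent from the count table count as unstudied (0).
#'
#' @param table A \code{specificity_table}.
#' @param counts Named integer vector gene -> publication count, as from
#'   [read_study_counts()].
#' @param max_studies Retain genes with count <= this value (default 500).
#' @return The filtered, re-ranked \code{specificity_table}.
#' @export
filter_by_study_count <- function(table, counts, max_studies = 500) {
  stopifnot(inherits(table, "specificity_table"), max_studies >= 0)
  n <- counts[table$gene]
  n[is.na(n)] <- 0L
  keep <- n <= max_studies
  if (sum(keep) < 2) {
    stop("fewer than 2 genes left after the study-count filter")
  }
  out <- table[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- class(table)
  attr(out, "tau") <- attr(table, "tau")
  attr(out, "epsilon") <- attr(table, "epsilon")
  out
}

#' Compare specificity scores between two gene groups
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum test on the scores of two
#' disjoint gene groups. The exact null distribution is used when the
#' smaller group has at most 8 members: via the closed-form distribution
#' without ties, or by full enumeration of group assignments (with
#' midranks) when ties are present. Larger groups use the normal
#' approximation with tie correction. The method actually applied is
#' recorded in the result.
#'
#' @param scores A \code{specificity_table} (or any data.frame with
#'   \code{gene} and \code{score} columns).
#' @param groupA,groupB Character vectors of gene ids; intersected with the
#'   scored genes, and required to be disjoint afterwards.
#' @param values Optional named numeric vector to compare instead of the
#'   score column (used e.g. for tissue-breadth comparisons).
#' @return A \code{score_comparison}: list with group sizes, the rank-sum
#'   statistic W, the two-sided p value and the method used.
#' @export
compare_score_groups <- function(scores, groupA, groupB, values = NULL) {
  if (is.null(values)) {
    values <- stats::setNames(scores$score, scores$gene)
  }
  a <- intersect(groupA, names(values))
  b <- intersect(groupB, names(values))
  shared <- intersect(a, b)
  if (length(shared) > 0) {
    stop("groups overlap in scored genes: ", paste(shared, collapse = ", "))
  }
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 scored genes")
  }
  xa <- unname(values[a]); xb <- unname(values[b])
  if (length(unique(c(xa, xb))) == 1) {
    # fully tied data carry no ordering information
    return(structure(list(n_a = length(a), n_b = length(b),
                          statistic = length(a) * length(b) / 2,
                          p_value = 1, method = "degenerate"),
                     class = "score_comparison"))
  }
  ties <- anyDuplicated(c(xa, xb)) > 0
  small <- min(length(xa), length(xb)) <= 8 &&
    choose(length(xa) + length(xb), length(xa)) <= 2e4
  if (small && ties) {
    # exact null by enumeration of group assignments (midranks for ties);
    # wilcox.test only offers a normal approximation here
    pooled <- c(xa, xb)
    r <- rank(pooled)
    na <- length(xa)
    u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    us <- utils::combn(length(pooled), na,
                       function(idx) sum(r[idx]) - na * (na + 1) / 2)
    center <- na * length(xb) / 2
    p <- if (u_obs > center) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
    return(structure(list(n_a = length(a), n_b = length(b),
                          statistic = u_obs, p_value = min(1, p),
                          method = "exact_enumeration"),
                     class = "score_comparison"))
  }
  exact <- !ties && small
  wt <- suppressWarnings(
    stats::wilcox.test(xa, xb, alternative = "two.sided", exact = exact,
                       correct = !exact))
  structure(list(n_a = length(a), n_b = length(b),
                 statistic = unname(wt$statistic),
                 p_value = min(1, wt$p.value),
                 method = if (exact) "exact" else "normal_approx"),
            class = "score_comparison")
}

#' @export
print.score_comparison <- function(x, ...) {
  cat(sprintf(
    "Rank-sum comparison: n = %d vs %d, W = %g, two-sided p = %.4g (%s)\n",
    x$n_a, x$n_b, x$statistic, x$p_value, x$method))
  invisible(x)
}

#' Pearson correlation with Fisher-transform p value
#'
#' Product-moment correlation over the paired values; the two-sided p value
#' comes from the Fisher z-transform, \eqn{z = \mathrm{atanh}(r)\sqrt{n-3}},
#' referred to the standard normal.
#'
#' @param x,y Named numeric vectors; correlated over the intersection of
#'   their names (or positionally if unnamed and equal length).
#' @return List with \code{r}, \code{p_value} and \code{n}.
#' @export
correlate <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the vectors")
  }
  r <- stats::cor(x, y)
  z <- atanh(r) * sqrt(n - 3)
  p <- 2 * stats::pnorm(-abs(z))
  list(r = r, p_value = p, n = n)
}
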