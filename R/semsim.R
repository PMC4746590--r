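#' Information content of ontology terms
#'
#' Annotation-frequency information content: with annotations propagated
#' along \code{is_a} (true-path rule), \eqn{p(t)} is the fraction of
#' annotated genes carrying term \eqn{t}, and \eqn{IC(t) = -\log_2 p(t)}.
#' The root of a namespace annotates every gene reachable from it, so its
#' IC is 0; IC can only grow from parent to child. Terms annotating no gene
#' are dropped with a log message.
#'
#' @param graph An \code{ontology} object (annotations already propagated).
#' @return Named numeric vector term -> IC in bits.
#' @export
term_ic <- function(graph) {
  stopifnot(inherits(graph, "ontology"))
  n_genes <- length(graph$annotations_prop)
  if (n_genes == 0) stop("ontology has no annotated genes")
  tab <- table(unlist(graph$annotations_prop))
  freq <- stats::setNames(as.integer(tab), names(tab))
  dropped <- setdiff(graph$terms$id, names(freq))
  if (length(dropped) > 0) {
    message(length(dropped), " term(s) with zero annotation frequency dropped")
  }
  -log2(freq / n_genes)
}

#' Lin semantic similarity between two terms
#'
#' \deqn{sim(t_1, t_2) = \frac{2\,IC(MICA)}{IC(t_1) + IC(t_2)}}
#' where MICA is the common ancestor with maximal information content.
#' Bounded in [0, 1]; equal to 1 for identical terms with positive IC, and
#' 0 when the only shared ancestor is the root. Terms from different
#' namespaces share no ancestor and get similarity 0.
#'
#' @param t1,t2 Term ids present in \code{ic}.
#' @param ic Named IC vector from [term_ic()].
#' @param graph The \code{ontology}.
#' @return Similarity in [0, 1].
#' @export
term_similarity <- function(t1, t2, ic, graph) {
  if (!t1 %in% names(ic) || !t2 %in% names(ic)) {
    stop("both terms must have an information content")
  }
  common <- intersect(graph$ancestors[[t1]], graph$ancestors[[t2]])
  common <- intersect(common, names(ic))
  if (length(common) == 0) return(0)
  mica <- max(ic[common])
  denom <- ic[[t1]] + ic[[t2]]
  if (denom == 0) return(0)
  unname(2 * mica / denom)
}

# all-pairs term similarity matrix for a term universe; the cache that
# makes repeated gene-level similarity affordable
term_similarity_matrix <- function(terms, ic, graph) {
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- term_similarity(terms[i], terms[j], ic, graph)
      m[i, j] <- s; m[j, i] <- s
    }
  }
  m
}

#' Functional similarity between two genes
#'
#' The mean of the pairwise term similarities over all ordered pairs of the
#' two genes' direct (non-propagated) annotations. Direct annotations are
#' used deliberately: averaging over propagated sets degenerates toward 1
#' because every gene shares the upper levels of the ontology. Terms
#' without an IC (never annotated) are ignored.
#'
#' @param g1,g2 Gene ids present in the ontology's annotations.
#' @param graph The \code{ontology}.
#' @param ic Named IC vector from [term_ic()].
#' @param sim_matrix Optional precomputed term similarity matrix (internal
#'   speed-up for large all-pairs computations).
#' @return Similarity in [0, 1].
#' @export
gene_similarity <- function(g1, g2, graph, ic, sim_matrix = NULL) {
  for (g in c(g1, g2)) {
    if (!g %in% names(graph$annotations)) {
      stop("gene without annotations: ", g)
    }
  }
  t1 <- intersect(graph$annotations[[g1]], names(ic))
  t2 <- intersect(graph$annotations[[g2]], names(ic))
  if (length(t1) == 0 || length(t2) == 0) {
    stop("gene without IC-bearing annotations: ",
         if (length(t1) == 0) g1 else g2)
  }
  if (!is.null(sim_matrix)) {
    return(mean(sim_matrix[t1, t2, drop = FALSE]))
  }
  tot <- 0
  for (a in t1) for (b in t2) {
    tot <- tot + term_similarity(a, b, ic, graph)
  }
  tot / (length(t1) * length(t2))
}

#' Pairwise gene similarities within a gene group
#'
#' All \code{choose(n, 2)} within-group functional similarities, with the
#' term-level similarities computed once and cached.
#'
#' @param genes Character vector of annotated genes (n >= 2).
#' @param graph The \code{ontology}.
#' @param ic Named IC vector.
#' @return Numeric vector of length \code{choose(n, 2)}.
#' @export
pairwise_gene_similarity <- function(genes, graph, ic) {
  stopifnot(length(genes) >= 2)
  terms <- unique(unlist(graph$annotations[genes]))
  terms <- intersect(terms, names(ic))
  sm <- term_similarity_matrix(terms, ic, graph)
  pairs <- utils::combn(genes, 2)
  vapply(seq_len(ncol(pairs)), function(i) {
    gene_similarity(pairs[1, i], pairs[2, i], graph, ic, sim_matrix = sm)
  }, 0)
}

#' Contrast functional coherence of the most specific vs most general genes
#'
#' Takes the \code{n_top} most specific and \code{n_top} most general
#' scored genes (restricted to genes with usable annotations), computes all
#' within-group pairwise gene similarities and compares the two similarity
#' distributions with a two-sided rank-sum test. A higher median similarity
#' among general genes indicates that general cancer genes are functionally
#' more coherent, while specific ones are functionally scattered.
#'
#' @param scores A \code{specificity_table} (apply any study-bias filter
#'   upstream).
#' @param n_top Number of genes per extreme (>= 3; default 30).
#' @param graph The \code{ontology}.
#' @param ic Named IC vector from [term_ic()].
#' @return List with \code{specific_similarities},
#'   \code{general_similarities}, their medians, and \code{comparison}
#'   (a \code{score_comparison} on the two distributions).
#' @export
compare_extremes <- function(scores, n_top = 30, graph, ic) {
  if (n_top < 3) stop("n_top must be at least 3")
  usable <- vapply(scores$gene, function(g) {
    !is.null(graph$annotations[[g]]) &&
      length(intersect(graph$annotations[[g]], names(ic))) > 0
  }, TRUE)
  pool <- scores[usable, , drop = FALSE]
  if (nrow(pool) < 2 * n_top) {
    stop("need at least ", 2 * n_top, " scored annotated genes; have ",
         nrow(pool))
  }
  pool <- pool[order(pool$rank), , drop = FALSE]
  spec_genes <- pool$gene[seq_len(n_top)]
  gen_genes <- pool$gene[seq(nrow(pool) - n_top + 1, nrow(pool))]
  s_spec <- pairwise_gene_similarity(spec_genes, graph, ic)
  s_gen <- pairwise_gene_similarity(gen_genes, graph, ic)
  xa <- stats::setNames(s_spec, paste0("s", seq_along(s_spec)))
  xb <- stats::setNames(s_gen, paste0("g", seq_along(s_gen)))
  cmp <- compare_score_groups(NULL, names(xa), names(xb),
                              values = c(xa, xb))
  list(specific_similarities = s_spec, general_similarities = s_gen,
       median_specific = stats::median(s_spec),
       median_general = stats::median(s_gen),
       comparison = cmp)
}
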