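#' Default ontology ids of the three DNA repair pathway classes
#'
#' Nucleotide-excision repair, mismatch repair and double-strand break
#' repair: three repair pathways with low mutual gene overlap, which makes
#' a unique per-gene assignment meaningful.
#' @return Named character vector (NER, MM, DSBR).
#' @export
default_repair_terms <- function() {
  c(NER = "GO:0006289", MM = "GO:0006298", DSBR = "GO:0006302")
}

#' Assign catalog genes to DNA repair pathway classes
#'
#' A gene annotated (with true-path propagation) to exactly one of the
#' three repair classes gets that class; to more than one, the label
#' \code{multiple}; to none, \code{none}. Only uniquely assigned genes
#' enter the tissue count matrix downstream — a gene in two pathways would
#' otherwise blur the tissue contrast the counts are meant to expose.
#'
#' @param catalog A \code{cancer_catalog}.
#' @param graph An \code{ontology} carrying the three class terms.
#' @param terms Named character (names NER/MM/DSBR) of class term ids;
#'   default [default_repair_terms()].
#' @return The catalog with \code{repair_pathway} filled.
#' @export
assign_repair_pathways <- function(catalog, graph,
                                   terms = default_repair_terms()) {
  missing <- setdiff(terms, graph$terms$id)
  if (length(missing) > 0) {
    stop("repair class term(s) absent from ontology: ",
         paste(missing, collapse = ", "))
  }
  catalog$repair_pathway <- vapply(catalog$gene, function(g) {
    ann <- graph$annotations_prop[[g]]
    hits <- names(terms)[terms %in% ann]
    if (length(hits) == 0) "none"
    else if (length(hits) == 1) hits
    else "multiple"
  }, "")
  catalog
}

#' Tissue x pathway count matrix over uniquely assigned repair genes
#'
#' Each uniquely assigned repair gene contributes one count to every tissue
#' it is associated with (multi-tissue genes count once per tissue, no
#' fractional weighting).
#'
#' @param catalog A \code{cancer_catalog} with repair pathways assigned.
#' @return Integer matrix, tissues x pathways (NER, MM, DSBR).
#' @export
pathway_tissue_counts <- function(catalog) {
  classes <- c("NER", "MM", "DSBR")
  rows <- catalog[catalog$repair_pathway %in% classes, , drop = FALSE]
  tissues <- sort(unique(unlist(rows$tissues)))
  m <- matrix(0L, length(tissues), length(classes),
              dimnames = list(tissues, classes))
  for (i in seq_len(nrow(rows))) {
    for (t in rows$tissues[[i]]) {
      m[t, rows$repair_pathway[i]] <- m[t, rows$repair_pathway[i]] + 1L
    }
  }
  m
}

#' Fisher test of one pathway against one tissue
#'
#' 2x2 table over uniquely assigned repair gene-tissue incidences:
#' the focal pathway vs the other two, in the focal tissue vs all other
#' tissues. Two-sided exact p by the point-probability rule (all tables
#' with probability at most that of the observed one).
#'
#' @param counts Matrix from [pathway_tissue_counts()].
#' @param pathway One of "NER", "MM", "DSBR".
#' @param tissue A row name of \code{counts}.
#' @return List with \code{odds_ratio}, \code{p_value} and \code{table}.
#' @export
pathway_tissue_fisher <- function(counts, pathway, tissue) {
  stopifnot(pathway %in% colnames(counts), tissue %in% rownames(counts))
  a <- counts[tissue, pathway]
  b <- sum(counts[, pathway]) - a
  c_ <- sum(counts[tissue, ]) - a
  d <- sum(counts) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("empty margin in the 2x2 table; p = 1")
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab))
  }
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Specificity contrast among hallmark classes
#'
#' Pairwise rank-sum comparisons of specificity scores among the oncogene,
#' tumor-suppressor and DNA-repair hallmark classes of the catalog.
#'
#' @param scores A \code{specificity_table}.
#' @param catalog A \code{cancer_catalog} with hallmark labels.
#' @return data.frame with one row per class pair: sizes, W, p value.
#' @export
hallmark_specificity <- function(scores, catalog) {
  classes <- c("oncogene", "tumor_suppressor", "dna_repair")
  members <- lapply(stats::setNames(classes, classes), function(cl) {
    catalog$gene[catalog$hallmark == cl]
  })
  scored <- stats::setNames(scores$score, scores$gene)
  for (cl in classes) {
    if (length(intersect(members[[cl]], names(scored))) < 2) {
      stop("hallmark class '", cl, "' has fewer than 2 scored genes")
    }
  }
  pairs <- utils::combn(classes, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    cmp <- compare_score_groups(scores, setdiff(members[[a]], members[[b]]),
                                setdiff(members[[b]], members[[a]]))
    data.frame(class_a = a, class_b = b, n_a = cmp$n_a, n_b = cmp$n_b,
               statistic = cmp$statistic, p_value = cmp$p_value,
               method = cmp$method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fold enrichment of repair-pathway genes among germline cancer genes
#'
#' Ratio of proportions: the fraction of germline-mutated cancer genes in a
#' repair pathway over the overall fraction of pathway genes in the
#' catalog, reported to one decimal.
#'
#' @param n_pathway_germline Pathway genes that are germline mutated.
#' @param n_germline All germline-mutated genes.
#' @param n_pathway All pathway genes.
#' @param n_total All catalog genes.
#' @return Fold enrichment (one decimal).
#' @examples
#' germline_fold_enrichment(18, 66, 28, 670)  # 6.5
#' @export
germline_fold_enrichment <- function(n_pathway_germline, n_germline,
                                     n_pathway, n_total) {
  stopifnot(n_pathway_germline >= 0, n_germline > 0, n_pathway > 0,
            n_total > 0,
            n_pathway_germline <= min(n_germline, n_pathway))
  round((n_pathway_germline / n_germline) / (n_pathway / n_total), 1)
}

#' Tissue-breadth comparison of germline vs somatic cancer genes
#'
#' Two-sided rank-sum test on the per-gene number of associated tissues,
#' restricted to genes exclusively germline or exclusively somatic (origin
#' \code{both} is excluded, since mixed-origin genes blur the contrast).
#'
#' @param catalog A \code{cancer_catalog}.
#' @return A \code{score_comparison} on tissue counts (germline = group A).
#' @export
breadth_comparison <- function(catalog) {
  keep <- catalog$origin %in% c("germline", "somatic") &
    lengths(catalog$tissues) > 0
  sub <- catalog[keep, , drop = FALSE]
  breadth <- stats::setNames(lengths(sub$tissues), sub$gene)
  g <- sub$gene[sub$origin == "germline"]
  s <- sub$gene[sub$origin == "somatic"]
  compare_score_groups(NULL, g, s, values = breadth)
}

#' PCA of tissues in DNA repair pathway space
#'
#' Column-centered principal component analysis (via singular value
#' decomposition) of the tissue x pathway count matrix. Component signs
#' are fixed so that each loading vector's largest-magnitude entry is
#' positive, making the projection reproducible across platforms.
#'
#' @param counts Matrix from [pathway_tissue_counts()] (>= 3 tissues).
#' @return List with \code{scores} (tissues x first 2 components),
#'   \code{loadings} (pathways x all components) and \code{var_frac}
#'   (variance fractions, all components).
#' @export
pca_tissues <- function(counts) {
  if (nrow(counts) < 3) stop("need at least 3 tissues for the projection")
  centered <- scale(counts, center = TRUE, scale = FALSE)
  if (all(abs(centered) < .Machine$double.eps^0.5)) {
    stop("zero-variance count matrix")
  }
  pc <- stats::prcomp(counts, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE],
       loadings = pc$rotation, var_frac = var_frac)
}
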