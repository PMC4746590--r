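make_repair_ontology <- function(gene_terms) {
  rt <- default_repair_terms()
  terms <- data.frame(id = c("ROOT", "REP", unname(rt)),
                      name = c("root", "repair", names(rt)),
                      namespace = "bp", stringsAsFactors = FALSE)
  parents <- c(list(ROOT = character(), REP = "ROOT"),
               setNames(rep(list("REP"), 3), unname(rt)))
  build_ontology(terms, parents, gene_terms)
}

make_catalog <- function(genes, tissues, origin = "somatic",
                         hallmark = "other") {
  out <- data.frame(gene = genes, origin = origin, hallmark = hallmark,
                    repair_pathway = "none", stringsAsFactors = FALSE)
  out$tissues <- tissues
  class(out) <- c("cancer_catalog", "data.frame")
  out
}

test_that("repair pathway assignment is unique-or-multiple", {
  rt <- default_repair_terms()
  onto <- make_repair_ontology(list(
    g1 = rt[["NER"]],
    g2 = c(rt[["NER"]], rt[["DSBR"]]),
    g3 = "ROOT"))
  cat <- make_catalog(c("g1", "g2", "g3"),
                      list("skin", "breast", "colon"))
  cat <- assign_repair_pathways(cat, onto)
  expect_equal(cat$repair_pathway, c("NER", "multiple", "none"))
  expect_error(assign_repair_pathways(cat, chain_ontology()), "absent")
})

test_that("a 38-gene fixture with 11 multi-annotated yields 27 unique", {
  set.seed(21)
  rt <- default_repair_terms()
  genes <- sprintf("r%02d", 1:38)
  ann <- lapply(seq_along(genes), function(i) {
    if (i <= 11) unname(sample(rt, 2))
    else unname(rt[[sample(3, 1)]])
  })
  onto <- make_repair_ontology(setNames(ann, genes))
  cat <- make_catalog(genes, as.list(rep("skin", 38)))
  cat <- assign_repair_pathways(cat, onto)
  expect_equal(sum(cat$repair_pathway %in% c("NER", "MM", "DSBR")), 27)
  expect_equal(sum(cat$repair_pathway == "multiple"), 11)
})

test_that("tissue counts tally one count per gene-tissue incidence", {
  cat <- make_catalog(c("g1", "g2", "g3"),
                      list(c("skin", "colon"), "skin", "breast"))
  cat$repair_pathway <- c("NER", "MM", "DSBR")
  m <- pathway_tissue_counts(cat)
  expect_equal(m["skin", "NER"], 1L)
  expect_equal(m["colon", "NER"], 1L)   # multi-tissue gene counts per tissue
  expect_equal(sum(m), 4L)
  expect_equal(rowSums(m), c(breast = 1L, colon = 1L, skin = 2L))
})

test_that("pathway-tissue Fisher matches the hypergeometric oracle", {
  cat <- make_catalog(c("g1", "g2", "g3", "g4"),
                      list("skin", "skin", "colon", "colon"))
  cat$repair_pathway <- c("NER", "NER", "MM", "MM")
  m <- pathway_tissue_counts(cat)
  ft <- pathway_tissue_fisher(m, "NER", "skin")
  expect_equal(ft$table, matrix(c(2, 0, 0, 2), 2, byrow = TRUE))
  expect_equal(ft$p_value, 1 / 3)   # point-probability two-sided

  # independence table
  cat2 <- make_catalog(paste0("h", 1:4),
                       list("skin", "colon", "skin", "colon"))
  cat2$repair_pathway <- c("NER", "NER", "MM", "MM")
  ft2 <- pathway_tissue_fisher(pathway_tissue_counts(cat2), "NER", "skin")
  expect_equal(ft2$p_value, 1.0)

  # random tables vs oracle
  set.seed(33)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4) + c(1, 0, 0, 1), 2)
    if (sum(tab) > 40) next
    got <- fisher.test(tab)$p.value
    expect_equal(got, fisher_oracle(tab), tolerance = 1e-9)
  }
})

test_that("germline fold enrichment reproduces the ratio of proportions", {
  expect_equal(germline_fold_enrichment(18, 66, 28, 670), 6.5)
  expect_equal(germline_fold_enrichment(5, 50, 5, 50), 1.0)
  set.seed(14)
  for (i in 1:10) {
    d <- sample(100:1000, 1); c_ <- sample(10:50, 1)
    b <- sample(20:80, 1); a <- sample(seq_len(min(b, c_)), 1)
    expect_equal(germline_fold_enrichment(a, b, c_, d),
                 round((a / b) / (c_ / d), 1))
  }
  expect_error(germline_fold_enrichment(0, 0, 5, 10))
})

test_that("hallmark contrast compares all three class pairs", {
  set.seed(15)
  genes <- sprintf("g%02d", 1:51)
  x <- setNames(seq_along(genes) + rnorm(51, 0, .01), genes)
  st <- scores_from_vector(x)
  cat <- make_catalog(genes, as.list(rep("skin", 51)),
                      hallmark = rep(c("oncogene", "tumor_suppressor",
                                       "dna_repair"), each = 17))
  res <- hallmark_specificity(st, cat)
  expect_equal(nrow(res), 3)
  # repair genes have the largest scores here -> both repair contrasts extreme
  expect_true(all(res$p_value[res$class_b == "dna_repair"] < 0.01))
  # class sizes like the hallmark annotation (8 / 25 / 18) are accepted
  cat2 <- make_catalog(genes, as.list(rep("skin", 51)),
                       hallmark = rep(c("dna_repair", "oncogene",
                                        "tumor_suppressor"), c(8, 25, 18)))
  expect_equal(nrow(hallmark_specificity(st, cat2)), 3)
})

test_that("breadth comparison excludes mixed-origin genes", {
  cat <- make_catalog(paste0("g", 1:7),
                      list("a", "b", "c", c("a", "b", "c", "d", "e"),
                           c("a", "b", "c", "d", "e", "f"),
                           c("a", "b", "c", "d", "e", "f", "g"),
                           c("a", "b")),
                      origin = c("germline", "germline", "germline",
                                 "somatic", "somatic", "somatic", "both"))
  res <- breadth_comparison(cat)
  expect_equal(res$n_a + res$n_b, 6)  # the "both" gene never enters
  expect_equal(res$p_value, 0.1)      # {1,1,1} vs {5,6,7} exact enumeration
})

test_that("tissue PCA conserves variance and is order-invariant", {
  m <- matrix(c(1, 0, 0, 2, 0, 0, 3, 0, 0), 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("NER", "MM", "DSBR")))
  res <- pca_tissues(m)
  expect_equal(res$var_frac[1], 1.0)
  expect_equal(sum(res$var_frac), 1.0)

  set.seed(16)
  m2 <- matrix(rpois(15, 5), 5,
               dimnames = list(paste0("t", 1:5), c("NER", "MM", "DSBR")))
  res2 <- pca_tissues(m2)
  # reconstruction from all components
  centered <- scale(m2, center = TRUE, scale = FALSE)
  k <- sum(res2$var_frac > 1e-12)
  full <- stats::prcomp(m2, center = TRUE)
  rec <- full$x %*% t(full$rotation)
  expect_lt(max(abs(rec - centered)), 1e-10)
  # row-order invariance (up to relabeling)
  perm <- c(3, 1, 5, 2, 4)
  res3 <- pca_tissues(m2[perm, ])
  expect_equal(res3$scores[rownames(m2), ], res2$scores, tolerance = 1e-9)
  expect_error(pca_tissues(matrix(1, 3, 3,
                                  dimnames = list(letters[1:3], 1:3))),
               "zero-variance")
})
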