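chem_net_fixture <- function() {
  edges <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    partner = c("c1", "c1", "c2", "c3", "c3"),
    evidence = c(1L, 3L, 2L, 5L, 2L),
    study_size = c(10L, 40L, 600L, 25L, 700L))
  attrs <- data.frame(partner = c("c1", "c2", "c3"),
                      is_drug = c(FALSE, TRUE, FALSE),
                      is_air_pollutant = c(TRUE, FALSE, FALSE))
  build_network(edges, "chemical", attrs)
}

test_that("network filters drop the stated edges and commute", {
  net <- chem_net_fixture()
  f1 <- filter_network(net, min_evidence = 2)
  expect_false(any(f1$edges$evidence < 2))   # the evidence-1 edge is gone
  f2 <- filter_network(net, min_evidence = 1, exclude_drugs = TRUE)
  expect_false("c2" %in% f2$edges$partner)
  f3 <- filter_network(net, min_evidence = 1, min_study_size = 30)
  expect_true(all(f3$edges$study_size >= 30))

  # order independence
  a <- filter_network(filter_network(net, min_evidence = 2),
                      min_evidence = 0, exclude_drugs = TRUE,
                      min_study_size = 30)
  b <- filter_network(filter_network(net, min_evidence = 0,
                                     exclude_drugs = TRUE,
                                     min_study_size = 30),
                      min_evidence = 2)
  expect_equal(a$edges, b$edges)
  expect_error(filter_network(net, min_evidence = 99), "no edge survives")
})

test_that("a study-size threshold can remove most chemicals", {
  # emulates a medium/large-scale-only re-analysis: most chemicals are
  # reported only by small studies
  set.seed(30)
  chems <- sprintf("c%02d", 1:20)
  small <- seq_len(15)
  edges <- do.call(rbind, lapply(seq_along(chems), function(i) {
    data.frame(gene = paste0("g", sample(50, 3)), partner = chems[i],
               evidence = 2L,
               study_size = if (i %in% small) 10L else 100L)
  }))
  net <- build_network(edges, "chemical")
  filt <- filter_network(net, min_evidence = 1, min_study_size = 30)
  frac_lost <- 1 - length(unique(filt$edges$partner)) / length(chems)
  expect_gte(frac_lost, 0.70)
})

test_that("specific gene sets keep k = 1 genes of large solid types", {
  spec <- synthetic_spec(seed = 17, n_genes = 150)
  mt <- gen_mutation_table(spec)
  st <- rank_genes(mt$table)
  sets <- specific_gene_sets(st, spec$tmap, min_genes = 8)
  expect_setequal(names(sets), spec$specific_types)
  # every member is k = 1 and assigned to its planted type
  truth <- mt$truth
  for (ty in names(sets)) {
    expect_true(all(truth$planted_type[match(sets[[ty]], truth$gene)] == ty))
  }
  # a gene significant in 2 types is excluded
  expect_false(any(unlist(sets) %in% st$gene[st$k != 1]))
  # min_genes above all set sizes errors
  expect_error(specific_gene_sets(st, spec$tmap, min_genes = 500),
               "no cancer type")
})

test_that("chi-squared path matches the closed form; small tables fall back", {
  # [[20,10],[10,20]] -> chi2 = 6.667, p ~ 0.0098
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  orc <- chi2_oracle(tab)
  expect_equal(orc$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(orc$p, 0.009823, tolerance = 1e-4)

  # build sets/net realizing that table: type A 30 genes 20 interacting,
  # background-minus-type 30 genes 10 interacting
  genesA <- sprintf("a%02d", 1:30)
  genesB <- sprintf("b%02d", 1:30)
  inter <- c(genesA[1:20], genesB[1:10])
  edges <- data.frame(gene = inter, partner = "chemX", evidence = 2L,
                      study_size = 100L)
  net <- build_network(edges, "chemical")
  res <- suppressMessages(chemical_enrichment(
    list(A = genesA, B = genesB), net))
  rowA <- res[res$cancer_type == "A" & res$chemical == "chemX", ]
  expect_false(rowA$fisher_fallback)
  expect_equal(rowA$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(rowA$p_value, orc$p, tolerance = 1e-9)
  expect_equal(rowA$coverage, 20 / 30)

  # independence -> chi2 0, p 1
  inter2 <- c(genesA[1:10], genesB[1:10])
  net2 <- build_network(data.frame(gene = inter2, partner = "chemY",
                                   evidence = 2L, study_size = 100L),
                        "chemical")
  res2 <- suppressMessages(chemical_enrichment(
    list(A = genesA, B = genesB), net2))
  expect_equal(res2$statistic[1], 0)
  expect_equal(res2$p_value[1], 1)

  # small expected counts flag the Fisher fallback and match fisher.test
  small_net <- build_network(
    data.frame(gene = c(genesA[1:3], genesB[1]), partner = "chemZ",
               evidence = 2L, study_size = 100L), "chemical")
  res3 <- suppressMessages(chemical_enrichment(
    list(A = genesA[1:8], B = genesB[1:8]), small_net))
  r3 <- res3[res3$cancer_type == "A", ]
  expect_true(r3$fisher_fallback)
  expect_equal(r3$p_value,
               fisher_oracle(matrix(c(3, 5, 1, 7), 2, byrow = TRUE)),
               tolerance = 1e-9)
})

test_that("BH across pairs is input-order invariant", {
  set.seed(31)
  genes <- sprintf("g%02d", 1:40)
  setsA <- list(A = genes[1:20], B = genes[21:40])
  edges <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(gene = sample(genes, 12), partner = paste0("c", i),
               evidence = 2L, study_size = 100L)
  }))
  net1 <- build_network(edges, "chemical")
  net2 <- build_network(edges[rev(seq_len(nrow(edges))), ], "chemical")
  r1 <- suppressMessages(chemical_enrichment(setsA, net1))
  r2 <- suppressMessages(chemical_enrichment(setsA, net2))
  expect_equal(r1, r2)
})

test_that("pollutant fraction and Fisher test against the background", {
  flags <- c(p1 = TRUE, p2 = TRUE, p3 = TRUE, p4 = TRUE, x1 = FALSE)
  bg <- c(names(flags), paste0("b", 1:20))
  res <- pollutant_fraction(names(flags), flags, bg)
  expect_equal(res$fraction, 0.8)
  expect_equal(res$n_pollutant, 4)
  # zero flagged anywhere -> fraction 0, p 1
  res0 <- pollutant_fraction(c("b1", "b2"), c(b1 = FALSE), bg)
  expect_equal(res0$fraction, 0)
  expect_equal(res0$p_value, 1)
  # oracle equivalence on small totals
  flags2 <- setNames(c(rep(TRUE, 3), rep(FALSE, 17)), paste0("q", 1:20))
  res2 <- pollutant_fraction(paste0("q", 1:5), flags2, names(flags2))
  tab <- matrix(c(3, 2, 0, 15), 2, byrow = TRUE)
  expect_equal(res2$p_value, fisher_oracle(tab), tolerance = 1e-9)
})

test_that("virus strain counting uses strains, dedup never changes counts", {
  edges <- data.frame(
    gene = c("g1", "g1", "g1", "g2"),
    partner = c("EBV_s1", "EBV_s2", "EBV_s1", "HPV_s1"),
    evidence = c(2L, 2L, 5L, 2L), study_size = 100L)
  attrs <- data.frame(partner = c("EBV_s1", "EBV_s2", "HPV_s1"),
                      species = c("EBV", "EBV", "HPV16"))
  net <- build_network(edges, "virus_strain", attrs)
  sc <- canspec:::strain_counts(net)
  expect_equal(sc[["g1"]], 2L)  # two strains of one species count as 2
  expect_equal(sc[["g2"]], 1L)
})

test_that("strain-breadth contrast reproduces the exact enumeration", {
  cat <- data.frame(gene = paste0("g", 1:6), origin = "somatic",
                    hallmark = "other", repair_pathway = "none",
                    stringsAsFactors = FALSE)
  cat$tissues <- list("a", "b", "c",
                      c("a", "b", "c", "d", "e"),
                      c("a", "b", "c", "d", "e", "f"),
                      c("a", "b", "c", "d", "e", "f", "g"))
  class(cat) <- c("cancer_catalog", "data.frame")
  # g4..g6 interact with 2 strains; g1..g3 with at most one
  edges <- data.frame(
    gene = rep(c("g4", "g5", "g6", "g1"), c(2, 2, 2, 1)),
    partner = c("v1", "v2", "v1", "v2", "v1", "v2", "v1"),
    evidence = 2L, study_size = 100L)
  attrs <- data.frame(partner = c("v1", "v2"), species = "EBV")
  net <- build_network(edges, "virus_strain", attrs)
  res <- virus_strain_specificity(net, cat)
  expect_equal(res$multi_vs_few$p_value, 0.1)  # {1,1,1} vs {5,6,7}
})

test_that("virus tissue profile normalizes per virus", {
  cat <- data.frame(gene = paste0("g", 1:10), origin = "somatic",
                    hallmark = "other", repair_pathway = "none",
                    stringsAsFactors = FALSE)
  cat$tissues <- c(rep(list("blood"), 4), rep(list("breast"), 6))
  class(cat) <- c("cancer_catalog", "data.frame")
  edges <- data.frame(gene = paste0("g", 1:10), partner = "EBV_s1",
                      evidence = 2L, study_size = 100L)
  net <- build_network(edges, "virus_strain",
                       data.frame(partner = "EBV_s1", species = "EBV"))
  prof <- virus_tissue_profile(net, cat, tmap = default_tissue_map())
  expect_equal(prof["EBV", "hematopoietic"], 0.4)
  expect_equal(prof["EBV", "breast"], 0.6)
})
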