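test_that("set statistic is the median over the scored intersection", {
  st <- scores_from_vector(c(g1 = 1, g2 = 3))
  expect_equal(set_statistic(st, c("g1", "g2")), 2.0)
  expect_equal(set_statistic(st, "g1"), 1.0)
  expect_message(v <- set_statistic(st, c("g1", "g9")), "not in the scored")
  expect_equal(v, 1.0)
  expect_error(set_statistic(st, "g9"), "no set member")
})

test_that("exhaustive permutation p values match the full enumeration", {
  st <- scores_from_vector(c(g1 = 1, g2 = 2, g3 = 3, g4 = 4, g5 = 5))
  pv <- permutation_pvalues(st, c("g1", "g2"), exhaustive = TRUE)
  # all C(5,2) = 10 pair medians: only {g1,g2} itself is <= 1.5
  expect_equal(pv$p_specific, 0.1)
  expect_equal(pv$p_general, 1.0)
  expect_equal(pv$observed_median, 1.5)

  tied <- scores_from_vector(setNames(rep(2, 5), paste0("g", 1:5)))
  pvt <- permutation_pvalues(tied, c("g1", "g2"), exhaustive = TRUE)
  expect_equal(pvt$p_specific, 1.0)
  expect_equal(pvt$p_general, 1.0)
})

test_that("Monte-Carlo p values are deterministic given the seed and add one", {
  set.seed(999)  # outer RNG state must not leak in
  st <- scores_from_vector(setNames(rnorm(30), paste0("g", 1:30)))
  a <- permutation_pvalues(st, paste0("g", 1:5), n_perm = 500, seed = 42)
  set.seed(123)
  b <- permutation_pvalues(st, paste0("g", 1:5), n_perm = 500, seed = 42)
  expect_identical(a, b)
  # add-one: p can never be 0 and never exceeds 1
  expect_gte(a$p_specific, 1 / 501)
  expect_lte(a$p_general, 1)
  expect_error(permutation_pvalues(st, paste0("g", 1:5), n_perm = 50),
               ">= 100")
})

test_that("exhaustive and Monte-Carlo modes agree within 3 SE", {
  set.seed(5)
  st <- scores_from_vector(setNames(rnorm(12), paste0("g", 1:12)))
  for (m in 2:4) {
    members <- paste0("g", 1:m)
    ex <- permutation_pvalues(st, members, exhaustive = TRUE)
    mc <- permutation_pvalues(st, members, n_perm = 2000, seed = 77)
    se <- sqrt(ex$p_specific * (1 - ex$p_specific) / 2000)
    expect_lt(abs(mc$p_specific - ex$p_specific), 3 * se + 1 / 2001)
  }
})

test_that("doubling n_perm moves p by less than 3 binomial SE", {
  set.seed(6)
  st <- scores_from_vector(setNames(rnorm(40), paste0("g", 1:40)))
  members <- paste0("g", sample(40, 8))
  p1 <- permutation_pvalues(st, members, n_perm = 1000, seed = 1)$p_specific
  p2 <- permutation_pvalues(st, members, n_perm = 2000, seed = 2)$p_specific
  expect_lt(abs(p1 - p2), 3 * sqrt(p1 * (1 - p1) / 1000) + 2e-3)
})

test_that("BH adjustment matches the defining formula and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("run_gsea filters by scored set size and sorts by q_specific", {
  set.seed(3)
  st <- scores_from_vector(setNames(rnorm(100), sprintf("g%03d", 1:100)))
  sets <- canspec:::new_gene_sets(list(
    big1 = sprintf("g%03d", 1:20),
    big2 = sprintf("g%03d", 30:45),
    small = sprintf("g%03d", 1:5),
    border = sprintf("g%03d", 1:8)))   # 8 scored members: excluded (> 8 rule)
  res <- run_gsea(st, sets, min_size = 8, n_perm = 200, seed = 9)
  expect_setequal(res$set, c("big1", "big2"))
  expect_true(all(diff(res$q_specific) >= 0))
  expect_true(all(res$q_specific >= res$p_specific - 1e-15))
  expect_error(run_gsea(st, sets, min_size = 50), "no gene set")
})

test_that("a planted low-score set is detected as specific", {
  set.seed(4)
  x <- rnorm(100)
  names(x) <- sprintf("g%03d", 1:100)
  st <- scores_from_vector(x)
  lowest <- st$gene[1:9]
  sets <- canspec:::new_gene_sets(list(planted = lowest))
  res <- run_gsea(st, sets, n_perm = 2000, seed = 10)
  expect_lte(res$p_specific, 0.01)
  expect_equal(res$p_general, 1.0)
})

test_that("results are invariant to gene-set order (per-set streams)", {
  set.seed(12)
  st <- scores_from_vector(setNames(rnorm(60), paste0("g", 1:60)))
  sets1 <- canspec:::new_gene_sets(list(A = paste0("g", 1:12),
                                        B = paste0("g", 20:35)))
  sets2 <- canspec:::new_gene_sets(list(B = paste0("g", 20:35),
                                        A = paste0("g", 1:12)))
  r1 <- run_gsea(st, sets1, n_perm = 300, seed = 5)
  r2 <- run_gsea(st, sets2, n_perm = 300, seed = 5)
  expect_equal(r1[order(r1$set), ], r2[order(r2$set), ], ignore_attr = TRUE)
})
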