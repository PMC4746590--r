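test_that("specificity score matches hand-evaluated cases", {
  expect_equal(compute_specificity(1e-10, 1.0, 1), -9.0, tolerance = 1e-6)
  expect_equal(compute_specificity(1e-2, 1e-12, 8), 18.0, tolerance = 1e-3)
  # equal q values: ratio term vanishes, score = k
  expect_equal(compute_specificity(0.37, 0.37, 1), 1.0, tolerance = 1e-12)
})

test_that("score is monotone in each argument", {
  set.seed(42)
  for (i in 1:50) {
    mq <- runif(1, 1e-12, 0.5); pq <- runif(1, 1e-12, 0.5)
    k <- sample(0:20, 1)
    s0 <- compute_specificity(mq, pq, k)
    expect_gt(compute_specificity(min(1, mq * 10), pq, k), s0)
    expect_lt(compute_specificity(mq, min(1, pq * 10), k), s0)
    expect_gt(compute_specificity(mq, pq, k + 1), s0)
  }
})

test_that("rank_genes orders ascending with the stated tie-break", {
  mt <- tiny_mutsig()
  st <- rank_genes(mt, tau = 0.1)
  expect_equal(st$rank, 1:3)
  expect_equal(st$gene[1], "gA")        # score -9 most specific
  expect_true(all(diff(st$score) >= 0))
  expect_equal(st$k[st$gene == "gB"], 2L)
  expect_equal(st$mostQ[st$gene == "gB"], 1e-3)

  # tie-break: equal scores, smaller panQ (more general) ranked last
  q <- matrix(c(1e-4, 1e-2), 2, 1, dimnames = list(c("g1", "g2"), "T1"))
  tie <- canspec:::new_mutsig(c("g1", "g2"), q,
                              c(g1 = 1e-3, g2 = 1e-1))
  # scores: log10(1e-4/1e-3)+1 = 0 ; log10(1e-2/1e-1)+1 = 0
  ts <- rank_genes(tie)
  expect_equal(ts$gene, c("g2", "g1"))

  # permutation invariance of input rows
  perm <- canspec:::new_mutsig(rev(mt$gene), mt$q_type[3:1, , drop = FALSE],
                               mt$pan_q[3:1])
  expect_equal(rank_genes(perm), st)
})

test_that("study-count filter subsets and re-ranks", {
  st <- rank_genes(tiny_mutsig())
  out <- filter_by_study_count(st, c(gA = 600, gB = 100), max_studies = 500)
  expect_false("gA" %in% out$gene)   # gC absent from counts -> 0, kept
  expect_equal(out$rank, seq_len(nrow(out)))

  expect_equal(filter_by_study_count(st, c(gA = 0))$gene, st$gene)

  # 224 genes, 37 above the threshold -> 187 remain
  q <- matrix(runif(224, 0.2, 1), 224, 1,
              dimnames = list(sprintf("g%03d", 1:224), "T1"))
  big <- canspec:::new_mutsig(rownames(q), q,
                              setNames(runif(224, 0.2, 1), rownames(q)))
  counts <- setNames(rep(10L, 224), rownames(q))
  counts[sample(names(counts), 37)] <- 501L
  expect_equal(nrow(filter_by_study_count(rank_genes(big), counts)), 187)
})

test_that("group comparison matches the exhaustive rank-sum oracle", {
  st <- scores_from_vector(c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6))
  cmp <- compare_score_groups(st, c("a", "b", "c"), c("d", "e", "f"))
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$method, "exact")
  # symmetry in the groups
  cmp2 <- compare_score_groups(st, c("d", "e", "f"), c("a", "b", "c"))
  expect_equal(cmp2$p_value, cmp$p_value)

  set.seed(7)
  for (i in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    x <- sample(100, na + nb)  # distinct -> no ties
    genes <- paste0("g", seq_along(x))
    st <- scores_from_vector(setNames(x, genes))
    cmp <- compare_score_groups(st, genes[1:na], genes[(na + 1):(na + nb)])
    expect_equal(cmp$p_value,
                 ranksum_oracle(x[1:na], x[(na + 1):(na + nb)]),
                 tolerance = 1e-12)
  }
})

test_that("group comparison rejects overlap and degenerate input is p = 1", {
  st <- scores_from_vector(c(a = 1, b = 2, c = 3, d = 4))
  expect_error(compare_score_groups(st, c("a", "b"), c("b", "c")), "overlap")
  st2 <- scores_from_vector(c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(compare_score_groups(st2, c("a", "b"), c("c", "d"))$p_value, 1)
})

test_that("correlation uses the Fisher z transform", {
  r1 <- correlate(c(a = 1, b = 2, c = 3, d = 4), c(a = 2, b = 4, c = 6, d = 8))
  expect_equal(r1$r, 1.0)
  # r = 0.5 at n = 30: z = atanh(0.5) * sqrt(27), p ~ 0.0043
  set.seed(1)
  # construct exact r = 0.5 synthetic pair via known formula check instead:
  z <- atanh(0.5) * sqrt(27)
  expect_equal(2 * pnorm(-abs(z)), 0.004317, tolerance = 1e-3)
  x <- rnorm(30); y <- 0.5 * scale(x)[, 1] + sqrt(0.75) * rnorm(30)
  names(x) <- names(y) <- paste0("g", 1:30)
  res <- correlate(x, y)
  expect_equal(res$p_value, 2 * pnorm(-abs(atanh(res$r) * sqrt(27))))
  expect_error(correlate(c(a = 1, b = 1, c = 1, d = 1),
                         c(a = 1, b = 2, c = 3, d = 4)), "variance")
  expect_error(correlate(c(a = 1, b = 2), c(a = 1, b = 2)), "at least 4")
})

test_that("null correlation is centred at zero over permutations", {
  set.seed(11)
  x <- rnorm(40)
  rs <- replicate(200, cor(x, sample(x)))
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se + 0.02)
})

test_that("planted specific genes rank before planted general genes", {
  for (s in 1:5) {
    spec <- synthetic_spec(seed = s, n_genes = 80)
    mt <- gen_mutation_table(spec)
    st <- rank_genes(mt$table)
    rk <- setNames(st$rank, st$gene)
    expect_lt(max(rk[mt$truth$gene[mt$truth$class == "specific"]]),
              min(rk[mt$truth$gene[mt$truth$class == "general"]]))
  }
})
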