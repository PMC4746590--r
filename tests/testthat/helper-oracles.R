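# Brute-force reference implementations, kept deliberately independent of
# the package's code paths.

# exact two-sided rank-sum p by full enumeration of group assignments
ranksum_oracle <- function(xa, xb) {
  pooled <- c(xa, xb)
  n <- length(pooled); na <- length(xa)
  u_stat <- function(idx) {
    a <- pooled[idx]
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  obs <- u_stat(seq_len(na))
  all_idx <- utils::combn(n, na)
  us <- apply(all_idx, 2, u_stat)
  center <- na * (n - na) / 2
  p <- if (obs > center) 2 * mean(us >= obs) else 2 * mean(us <= obs)
  min(1, p)
}

# two-sided Fisher p by hypergeometric point-probability enumeration
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[, 1]); n_ <- sum(tab[, 2]); k <- sum(tab[1, ])
  xs <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(xs, m, n_, k)
  obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Pearson chi-squared (df = 1, no continuity correction) from the closed form
chi2_oracle <- function(tab) {
  n <- sum(tab)
  num <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2
  den <- prod(rowSums(tab)) * prod(colSums(tab))
  stat <- num / den
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# BH from the defining minimum, in input order
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  vapply(seq_len(n), function(i) {
    ri <- which(ord == i)  # rank position of p[i]
    js <- which(p[ord] >= p[i] - 1e-15)
    min(1, min(p[ord][js] * n / js))
  }, 0)
}

# upper-tail binomial by pmf summation
binom_oracle <- function(k, n, p0) {
  sum(stats::dbinom(k:n, n, p0))
}

# small mutation table fixture: explicit q values, 2 types + pan
tiny_mutsig <- function() {
  q <- matrix(c(1e-10, 0.5,
                1e-2, 1e-3,
                0.5, 0.6),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("T1", "T2")))
  canspec:::new_mutsig(c("gA", "gB", "gC"), q,
                       c(gA = 1.0, gB = 1e-12, gC = 0.9))
}

# chain ontology R <- A <- B with 4 genes; g1..g4 annotation spread chosen
# so IC(A) = 1 bit and IC(B) = 2 bits
chain_ontology <- function() {
  terms <- data.frame(id = c("R", "A", "B"), name = c("root", "mid", "leaf"),
                      namespace = "bp", stringsAsFactors = FALSE)
  parents <- list(R = character(), A = "R", B = "A")
  ann <- list(g1 = "B", g2 = "A", g3 = "R", g4 = "R")
  build_ontology(terms, parents, ann)
}

# specificity table built directly from a named score vector
scores_from_vector <- function(x) {
  ord <- order(x, names(x))
  out <- data.frame(gene = names(x)[ord], mostQ = 0.5, panQ = 0.5,
                    k = 1L, score = unname(x)[ord],
                    rank = seq_along(x), stringsAsFactors = FALSE)
  out$sig_types <- rep(list("T1"), length(x))
  class(out) <- c("specificity_table", "data.frame")
  out
}

adjacent_tissues_x <- function(tmap, tissue) {
  canspec:::adjacent_tissues(tmap, tissue)
}

synthetic_catalog <- function(spec, truth, onto = NULL) {
  tmap <- spec$tmap
  census <- gen_census(spec, truth)
  cat <- suppressMessages(build_ext_catalog(NULL, list(census), tmap))
  if (!is.null(onto)) cat <- assign_repair_pathways(cat, onto)
  cat
}
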