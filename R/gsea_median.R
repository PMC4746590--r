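#' Gene set statistic: median specificity score
#'
#' The set statistic of the enrichment analysis is simply the median of the
#' specificity scores over the genes of the set that are present in the
#' scored table (even cardinality: mean of the two central values).
#'
#' @param scores A \code{specificity_table}.
#' @param members Character vector of gene ids.
#' @return The observed median score.
#' @export
set_statistic <- function(scores, members) {
  vals <- stats::setNames(scores$score, scores$gene)
  hit <- intersect(members, names(vals))
  missing <- setdiff(members, names(vals))
  if (length(missing) > 0) {
    message(length(missing), " set member(s) not in the scored table; ",
            "computed on the intersection")
  }
  if (length(hit) == 0) stop("no set member present in the scored table")
  stats::median(unname(vals[hit]))
}

# deterministic per-set RNG stream: a small string hash folded with the
# global seed, kept below 2^31 so it is a valid R integer seed
derive_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 2654435761) %% 2147483647)
}

#' Permutation p values for one gene set
#'
#' Randomly reassigns the full score vector to genes \code{n_perm} times and
#' compares the permuted set medians with the observed one. Because
#' membership is the only thing that matters for a median, each permutation
#' is equivalent to drawing \code{m} scores without replacement from the
#' score vector.
#'
#' Two one-sided p values are returned: \code{p_specific} is the
#' probability of a permuted median as small or smaller than observed
#' (small scores = tissue-specific genes), \code{p_general} the probability
#' of one as large or larger. Ties count toward both tails. Monte-Carlo p
#' values include the observed statistic in the null
#' (\code{(b + 1) / (n_perm + 1)}), so they are never exactly zero;
#' exhaustive mode enumerates all \code{choose(n, m)} subsets and reports
#' exact fractions without the add-one.
#'
#' @param scores A \code{specificity_table}.
#' @param members Character vector of gene ids.
#' @param n_perm Number of permutations (>= 100 unless exhaustive).
#' @param seed Integer seed; identical inputs and seed give bitwise
#'   identical p values.
#' @param exhaustive Enumerate all subsets instead of sampling. Only
#'   allowed while \code{choose(n, m) <= exhaustive_limit}.
#' @param exhaustive_limit Cap on the number of enumerated subsets
#'   (default 1e5).
#' @return List with \code{p_specific}, \code{p_general},
#'   \code{observed_median}, \code{set_size} and \code{method}.
#' @export
permutation_pvalues <- function(scores, members, n_perm = 1000, seed = 1,
                                exhaustive = FALSE, exhaustive_limit = 1e5) {
  vals <- stats::setNames(scores$score, scores$gene)
  hit <- intersect(members, names(vals))
  if (length(hit) == 0) stop("no set member present in the scored table")
  obs <- stats::median(unname(vals[hit]))
  pool <- unname(vals)
  m <- length(hit); n <- length(pool)
  if (exhaustive) {
    n_comb <- choose(n, m)
    if (n_comb > exhaustive_limit) {
      stop("choose(", n, ", ", m, ") = ", n_comb,
           " exceeds exhaustive_limit ", exhaustive_limit)
    }
    meds <- utils::combn(pool, m, stats::median)
    p_spec <- sum(meds <= obs) / n_comb
    p_gen <- sum(meds >= obs) / n_comb
    method <- "exhaustive"
  } else {
    if (n_perm < 100) stop("n_perm must be >= 100 (or use exhaustive mode)")
    meds <- perm_medians(pool, m, n_perm, seed)
    p_spec <- (sum(meds <= obs) + 1) / (n_perm + 1)
    p_gen <- (sum(meds >= obs) + 1) / (n_perm + 1)
    method <- "monte_carlo"
  }
  list(p_specific = p_spec, p_general = p_gen, observed_median = obs,
       set_size = m, method = method)
}

# n_perm medians of m scores drawn without replacement; isolated RNG
perm_medians <- function(pool, m, n_perm, seed) {
  n <- length(pool)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    code
  }
  withr_seed({
    idx <- matrix(0L, n_perm, m)
    for (i in seq_len(n_perm)) idx[i, ] <- sample.int(n, m)
    x <- matrix(pool[idx], n_perm, m)
    # row medians without per-row function-call overhead:
    # sort each row, take central element(s)
    xs <- t(apply(x, 1, sort))
    if (m %% 2 == 1) {
      xs[, (m + 1) / 2]
    } else {
      (xs[, m / 2] + xs[, m / 2 + 1]) / 2
    }
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validating wrapper around \code{p.adjust(..., method = "BH")}:
#' all p values must lie in (0, 1]; q values are returned in input order.
#'
#' @param pvalues Numeric vector of p values in (0, 1].
#' @return BH-adjusted q values (same order).
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Median-statistic permutation GSEA over a gene set collection
#'
#' For every gene set with strictly more than \code{min_size} scored
#' members, computes the observed median specificity score and
#' label-permutation p values for both directions
#' (see [permutation_pvalues()]), then adjusts each direction separately
#' across the surviving sets with Benjamini-Hochberg. Per-set permutation
#' streams are derived deterministically from the global seed and the set
#' name, so results do not depend on set order and adding a set never
#' perturbs the p values of the others.
#'
#' @param scores A \code{specificity_table}.
#' @param sets A \code{gene_sets} collection.
#' @param min_size Strict lower bound on scored set size (default 8: sets
#'   with at least 9 scored members are kept).
#' @param n_perm Permutations per set (default 1000).
#' @param seed Global seed.
#' @param exhaustive_limit If > 0, sets with \code{choose(n, m)} at or
#'   below this limit are evaluated exhaustively (exact fractions).
#' @return data.frame with one row per surviving set: \code{set},
#'   \code{set_size}, \code{observed_median}, \code{p_specific},
#'   \code{p_general}, \code{q_specific}, \code{q_general}, \code{method};
#'   sorted by \code{q_specific}.
#' @export
run_gsea <- function(scores, sets, min_size = 8, n_perm = 1000, seed = 1,
                     exhaustive_limit = 0) {
  scored <- scores$gene
  sizes <- vapply(sets, function(s) length(intersect(s, scored)), 0L)
  keep <- names(sets)[sizes > min_size]
  if (length(keep) == 0) {
    stop("no gene set with more than ", min_size, " scored members")
  }
  rows <- lapply(keep, function(nm) {
    m <- sizes[[nm]]
    exh <- exhaustive_limit > 0 &&
      choose(length(scored), m) <= exhaustive_limit
    pv <- suppressMessages(permutation_pvalues(
      scores, sets[[nm]], n_perm = n_perm,
      seed = derive_seed(seed, nm), exhaustive = exh,
      exhaustive_limit = exhaustive_limit))
    data.frame(set = nm, set_size = pv$set_size,
               observed_median = pv$observed_median,
               p_specific = pv$p_specific, p_general = pv$p_general,
               method = pv$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # both modes guarantee p > 0: add-one in Monte-Carlo, and the observed
  # subset is itself enumerated in exhaustive mode
  out$q_specific <- bh_adjust(out$p_specific)
  out$q_general <- bh_adjust(out$p_general)
  out <- out[order(out$q_specific, out$p_specific, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
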