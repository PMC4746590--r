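---
title: "Methods: quantifying the tissue specificity of cancer genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the tissue specificity of cancer genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canspec)
```

# The specificity score

The starting point is a per-gene table of multiple-testing corrected
mutation enrichment q values: one per tumor type and one for the pooled
pan-cancer cohort. A gene that is highly significant in a single tumor
type but not pan-cancer is tissue-specific; a gene with strong pan-cancer
significance and many significant types is general. The score

$$S = \log_{10}\frac{mostQ + \varepsilon}{panQ + \varepsilon} + k$$

combines the smallest single-type q value ($mostQ$), the pan-cancer q
value ($panQ$) and the number of significantly mutated types ($k$). It is
strictly increasing in $mostQ$ and $k$ and strictly decreasing in $panQ$,
so the three qualitative requirements above are monotonicity properties
that the test suite sweeps directly.

Tunables, with defaults:

* $\tau = 0.1$ — the per-type threshold defining $k$ (count of types
  with $q < \tau$, strict). Mutation-significance pipelines conventionally
  call q below 0.1 significant; the value is surfaced as an argument
  because the convention is not universal.
* $\varepsilon = 10^{-16}$ — pseudocount guarding exact zeros, which
  published significance tables do contain. It is far below any
  distinguishable q value, so it never reorders genes with
  $q \ge 10^{-12}$.

Ranking is ascending in $S$; ties are broken by placing the gene with the
smaller $panQ$ (more pan-significant, hence more general) later, then by
gene identifier. The tie-break makes the ranking a deterministic total
order independent of input row order and platform.

The study-bias control removes genes linked to more than 500 publications
(configurable) before analyses that could be confounded by annotation
depth, and re-ranks the remainder.

# Median-statistic permutation GSEA

The enrichment analysis uses the median score of a gene set as the set
statistic and a label-permutation null: the score vector is randomly
reassigned to genes, which for a median is equivalent to drawing the
set's size without replacement from the scores. Two one-sided p values
are reported per set: `p_specific`, the probability of a permuted median
as small or smaller than observed, and `p_general`, the mirror image.

One directionality decision deserves a note. Taken literally, one could
attach the "specific" label to the fraction of permuted statistics
*larger* than the observed one; but with the score convention used here
(small score = specific) a set enriched in specific genes has a *small*
median, so the specific p value must count permuted medians at or below
the observed value. This implementation follows the score convention
throughout, and the planted-set tests pin the direction: a set made of
the lowest-scoring genes must come out significant on the specific side.

Numerical choices:

* Monte-Carlo p values are add-one, $(b+1)/(N+1)$, never exactly zero and
  slightly conservative — the standard convention for permutation tests.
  Exhaustive mode (all $\binom{n}{m}$ subsets, feasible below a
  configurable limit) reports exact fractions; the observed subset is
  itself enumerated, so exact p values are also positive.
* Ties between permuted and observed medians count toward both tails
  (conservative).
* Per-set permutation streams are derived from a global seed and the set
  name via a small string hash (kept below $2^{31}$), so results are
  independent of set order and adding a set never perturbs the others.
  Whether the original analysis drew one global or per-set randomization
  sequence is unknowable from the outside; per-set streams were chosen
  for this order-invariance.
* Sets need strictly more than `min_size` (default 8) scored members.
* Benjamini–Hochberg correction (via `p.adjust`) is applied within each
  direction separately across the surviving sets; pooling both directions
  would mix two families of hypotheses with mirrored nulls.

Calibration is verified empirically: with scores shuffled, p values over
1000 random sets at 1000 permutations are within Kolmogorov–Smirnov
distance 0.1 of uniform and the type-I error at 0.05 stays inside its
95% binomial interval.

# Semantic similarity

Term information content is the annotation-frequency form
$IC(t) = -\log_2 p(t)$ with $p(t)$ the fraction of annotated genes
carrying $t$ after true-path propagation; the namespace root has IC 0 and
IC is non-decreasing from parent to child. Term similarity is Lin's
normalization of the most-informative-common-ancestor IC,
$2\,IC(MICA)/(IC(t_1)+IC(t_2))$, bounded in $[0,1]$; the log base cancels.
Lin was chosen over raw Resnik because the group contrast should be
scale-free; over graph-walk measures because frequency-based IC is the
variant the analysis needs and nothing more.

Gene-level similarity is the mean over all ordered pairs of the two
genes' *direct* annotations. Direct, not propagated: averaged over
propagated sets, every pair of genes shares the upper ontology levels and
all similarities degenerate toward 1. A consequence worth stating: the
all-pairs mean of a gene with itself is 1 only when the gene has a single
IC-bearing term; with several terms the self-mean includes cross-term
pairs and drops below 1. This is inherent to the aggregation (a
best-match average would restore self-similarity 1 but was deliberately
not used), and the tests assert the invariant in exactly this form.
Cross-namespace term pairs contribute 0.

The headline contrast takes the `n_top` most specific and most general
scored, annotated genes (default 30, i.e. 435 pairs per group, after the
study-count filter) and compares the two within-group similarity
distributions with a rank-sum test. On synthetic data the planted
general-gene module must give general genes the higher median similarity
in at least 95 of 100 seeds; the direction, not the absolute similarity
level, is the reproducible object.

# DNA repair pathways and tissues

Genes are assigned to nucleotide-excision repair, mismatch repair or
double-strand break repair by propagated ontology annotation; only genes
annotated to exactly one of the three classes enter the tissue counts
(genes in several pathways would blur the contrast; they are labeled
`multiple` and excluded). Multi-tissue genes count once per associated
tissue, without fractional weighting — the tally is of gene–tissue
incidences.

The per-(pathway, tissue) Fisher test uses the 2×2 table "focal pathway
vs the other two" × "focal tissue vs all others" over those incidences;
the analysis only ever announced "Fisher test", so the table construction
is pinned here and in the function documentation. Two-sided p values use
the point-probability rule, and the suite checks them against a
hypergeometric enumeration oracle on all small tables. No multiple-testing
correction is applied across the tissue × pathway grid by default
(nominal p values are what the downstream interpretation uses); BH can be
applied by the caller.

The germline enrichment fold is a plain ratio of proportions,
`(pathway germline / all germline) / (pathway / total)`, reported to one
decimal; with the published catalog counts (18, 66, 28, 670) it evaluates
to 6.5. The breadth comparison between exclusively germline and
exclusively somatic genes excludes mixed-origin genes and rank-sum-tests
the per-gene tissue counts.

The tissue PCA is a column-centered principal component analysis of the
tissue × pathway count matrix via singular value decomposition, with
component signs fixed so each loading's largest-magnitude entry is
positive (reproducible across BLAS implementations).

# Chemical and virus enrichment

The chemical test asks, per (cancer type, chemical), whether the chemical
interacts with more of the type's specific genes (significant in exactly
one type, k = 1) than expected. The background universe is the union of
all investigated types' specific genes — the natural universe given that
the chemical universe itself is defined as "chemicals interacting with at
least one specific cancer gene of any investigated type". Types enter the
analysis with at least eight specific genes, solid tumors only. The
statistic is Pearson's χ² without continuity correction; when any
expected count falls below 5 the exact Fisher test is substituted and the
row flagged (χ² is anti-conservative exactly where the fallback fires).
BH runs across all tested pairs of all types — running it within each
type separately would make q values incomparable between types. A row is
"reportable" when q < 0.01 *and* the chemical covers at least 20% of the
type's specific genes; sub-threshold rows remain in the output.

Bias controls mirror the data realities of curated interaction
databases: edges supported by a single evidence item are dropped, partner
chemicals flagged as approved drugs are excluded (their gene links
reflect treatment, not environmental exposure), and a minimum source
study size can be imposed. The three filters commute.

Virus analyses count distinct interacting *strains* per gene for the
breadth contrast (genes touched by at most one strain vs several,
rank-sum on tumor-tissue counts, plus the none-vs-one control), and group
strains into *species* for the tissue profiles: entry (virus, tissue
group) is the fraction of the virus's cancer-gene interactors associated
with that group, multi-tissue genes counting in each of their groups.

The air-pollutant test contrasts the pollutant flags of a type's
reportable chemicals against the background chemical universe with a
Fisher 2×2 (reportable vs rest × pollutant vs not); the exact universes
were pinned this way because the headline fraction (4 pollutant flags
among 5 reportable lung chemicals, 80%) and the ~3% background frequency
are both defined relative to them.

# Expression agreement

Expression breadth is the number of tissues with abundance strictly above
a detection threshold (default 0). Breadth is correlated with the score
and with raw type counts using Pearson r and the Fisher z-transform
p value, $z = \operatorname{atanh}(r)\sqrt{n-3}$. For genes specific to
one solid tumor type, the tissue of maximal abundance is compared with
the mapped pathology tissue: `direct`, `adjacent` (via a symmetric tissue
adjacency list) or `none`. Ties at the maximum count as a match if any
tied tissue qualifies — generous toward agreement, so a negative finding
cannot be an artifact of tie handling. Significance of the match count
uses an upper-tail binomial test; the chance probability defaults to
(1 + number of adjacent tissues) / number of expression tissues, averaged
over genes, since no canonical null is established for this question.

# Synthetic benchmark conditions

The generators emulate the statistical structure the analyses assume,
with one master seed and independent per-generator substreams (derived by
the same string hash as the GSEA streams), so adding a generator never
changes another's output.

Default conditions, chosen once: 250 genes over 21 tumor types; 40%
planted specific genes (one significant type, $q \sim 10^{U(-12,-8)}$,
pan-cancer q uniform on [0.1, 1]), distributed round-robin over the seven
solid types used in the chemical analysis (about 14 genes per type, the
scale of the published per-type specific gene sets); 20% planted general
genes (pan-cancer $q \sim 10^{U(-12,-8)}$, 8–21 significant types);
background genes with all q uniform on [0.1, 1]. Planted chemicals cover
50% of their target type's specific genes against a 3% background
interaction rate over 40 background chemicals. These effect sizes sit at
the upper end of the published per-chemical coverages (25–50%) and were
fixed by an a-priori power calculation: at ~14 genes per type the exact
Fisher fallback detects 50% coverage against 3% background at q < 0.01
with better than 95% power, while at 8 genes per type no exact test can —
the χ² p values published for such tables are only attainable because χ²
is anti-conservative below expected count 5.

The synthetic ontology is a complete tree (default depth 4, branching 2)
plus the three repair-class terms; planted general genes draw their
annotations from the leaves of one designated subtree ("general module"),
giving them the elevated annotation coherence that the semantic
similarity contrast detects. Planted repair genes (9 NER with skin, 5 MM
with colon, 13 DSBR with breast/blood tissues, 5 multi-pathway, with a
germline-heavy origin mix) feed the repair × tissue analyses. The virus
generator implements tropism directly: every interacting gene draws its
strains from species weighted 20:1 toward species preferring one of the
gene's tissues (EBV-like → blood, HPV16-like → urogenital/breast;
HIV1-like diffuse); general genes are hubs touched by 2–4 strains. The
20:1 odds are the generator's definition of a clear tropism signal —
at mild preference the planted row-maximum property simply is not present
in the generated data, and the generator's purpose is to contain the
signal the detector is specified to find. The expression generator plants
1 direct and 3 adjacent expression/pathology matches among the specific
genes, emulating the near-absence of agreement in real data.

What the generators do *not* emulate: correlated q values across related
tumor types, realistic gene-length or expression covariates of mutation
significance, scale-free interaction network topology, ontology DAGs with
multiple parents, or annotation bias toward well-studied genes beyond the
single study-count multiplier. Passing planted-recovery tests therefore
demonstrates that the statistics detect the signals they target at
realistic effect sizes — not that real curated datasets are free of the
confounders these analyses control for with filters.

# Problem sizes and determinism

The test suite and the acceptance script run at the default conditions:
calibration with 1000 null sets at 1000 permutations each, and
planted-recovery rates over 100 seeds per property (ranking, chemical
power and false positive rate, virus tissue preference,
semantic-similarity direction), with the deeper pipeline determinism
check on a 120-gene bundle. Identical seeds give bitwise-identical
outputs everywhere; all randomness flows from explicit seed arguments and
RNG state is restored after every seeded computation, so library calls
never perturb a caller's stream.

# Known limitations

* The score's functional form is a documented surrogate with the stated
  monotonicity contract; any published variant with the same three
  monotonicities can replace it without interface changes.
* Gene identifiers are opaque case-sensitive strings; symbol
  harmonization across input sources is the caller's responsibility.
* The ontology reader supports the `is_a` subset of OBO 1.2 only; other
  relationship types are counted and ignored.
* Catalog hallmark labels are single-valued; a gene curated both as tumor
  suppressor and repair gene must be duplicated by the caller to appear
  in both classes.
* The tissue grouping and adjacency maps ship with defaults covering the
  21-type vocabulary but are inputs, not inferences — curation decisions
  about tissue vocabularies cannot be recovered from the data.
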