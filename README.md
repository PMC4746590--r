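# canspec

Why do mutations in some genes cause cancer only in particular tissues,
while other genes are found mutated in tumors from almost any site?
`canspec` quantifies this contrast from per-tumor-type mutation
significance tables and relates it to cellular function and environmental
exposure. It is aimed at computational cancer biologists who have
gene-level mutation enrichment q values (one per tumor type plus a pooled
pan-cancer cohort) and want a tested, reproducible implementation of the
downstream specificity analysis.

## The score and the analyses around it

For each gene, let `mostQ` be the smallest single tumor-type mutation
enrichment q value, `panQ` the pan-cancer q value, and `k` the number of
tumor types in which the gene is significantly mutated (q < τ, default
τ = 0.1). The cancer gene specificity score is

    S = log10((mostQ + ε) / (panQ + ε)) + k,        ε = 1e-16

Small S means the gene is strongly tied to a single tumor type
(tissue-specific); large S means broad, pan-cancer relevance (general).
Around the resulting ranking the package implements:

- **Median-statistic permutation GSEA** — for every gene set, the median
  score is compared against a null obtained by randomly reassigning the
  score vector to genes (default 1000 permutations, add-one p values,
  exact subset enumeration available for small sets), with
  Benjamini–Hochberg correction per direction.
- **GO semantic similarity** — information-content (Lin) similarity over
  an `is_a` ontology, aggregated between genes as the all-pairs mean over
  direct annotations, used to contrast functional coherence of the most
  specific vs the most general genes.
- **DNA repair × tissue association** — unique assignment of catalog
  genes to nucleotide-excision repair, mismatch repair or double-strand
  break repair; tissue-by-pathway count matrices, Fisher exact tests,
  germline fold enrichment, and a PCA projection of tissues in repair
  pathway space.
- **Environmental interaction enrichment** — χ²/Fisher enrichment of
  chemical–gene interactions among each cancer type's specific genes
  (with evidence, drug and study-size bias filters), air-pollutant
  fraction tests, virus strain-count vs tumor-type breadth contrasts and
  normalized virus × tissue interaction profiles.
- **Expression agreement** — expression breadth vs specificity
  correlations (Fisher z) and a binomial test of whether specific genes
  are most highly expressed where they cause cancer.
- **Synthetic data generators** — seeded, substream-isolated generators
  for every input (mutation tables, ontology + annotations, chemical and
  virus networks, expression, catalogs, study counts) with planted
  specific/general genes and planted enrichments, so the whole pipeline
  is testable offline.

## Worked example

```r
library(canspec)
spec   <- synthetic_spec(seed = 42)        # planted benchmark conditions
mt     <- gen_mutation_table(spec)
scores <- rank_genes(mt$table)
head(scores[, c("gene", "mostQ", "panQ", "k", "score", "rank")], 3)
#>    gene        mostQ      panQ k     score rank
#> 1 G0019 1.010082e-12 0.8128745 1 -10.90562    1
#> 2 G0039 1.101075e-12 0.7165033 1 -10.81336    2
#> 3 G0023 1.036861e-12 0.4179236 1 -10.60533    3
```

Rank 1 is the most tissue-specific gene: mutation significance q ≈ 1e-12
in exactly one tumor type (`k = 1`) but no pan-cancer signal, giving
S ≈ −10.9. The bottom of the table holds general genes (`k = 20–21`,
strong pan-cancer q, S ≈ +20).

```r
sets <- ontology_gene_sets(gen_ontology(spec, mt$truth)$graph, min_genes = 2)
g <- run_gsea(scores, sets, min_size = 8, n_perm = 1000, seed = 42)
head(g[, c("set", "set_size", "observed_median", "p_specific", "q_specific")], 3)
#>   set set_size observed_median  p_specific q_specific
#> 1  T3      162      -6.5777017 0.000999001 0.03396603
#> 2  T7       93      -6.9538628 0.003996004 0.06793207
#> 3  T6      111      -0.9120619 0.007992008 0.08491508
```

Set `T3`'s median score (−6.58) was matched or undercut by none of the
1000 permuted medians (add-one p = 1/1001 ≈ 0.001); after BH correction
across all surviving sets it remains enriched among specific genes
(q ≈ 0.034).

```r
compare_score_groups(scores,
                     mt$truth$gene[mt$truth$class == "specific"][1:10],
                     mt$truth$gene[mt$truth$class == "general"][1:10])
#> Rank-sum comparison: n = 10 vs 10, W = 0, two-sided p = 0.0001827 (normal_approx)

germline_fold_enrichment(18, 66, 28, 670)
#> [1] 6.5
```

The last call reproduces the catalog-count arithmetic: 18 of 66
exclusively germline cancer genes sit in the three DNA repair pathways,
against 28 of 670 genes overall — a 6.5-fold enrichment.

The full pipeline (`run_all`) chains all stages from a YAML config and
writes one TSV per stage plus a manifest; see `?run_all` and the methods
vignette in `vignettes/`.

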