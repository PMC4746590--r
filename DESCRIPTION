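Package: canspec
Title: Tissue Specificity of Cancer Genes from Mutation Significance Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how tissue-specific cancer driver genes are from
    per-tumor-type mutation significance tables, and relates that
    specificity to cellular function and environmental exposure. Implements
    a per-gene specificity score combining the most significant single
    tumor-type q value, the pan-cancer q value and the number of
    significantly mutated tumor types; a gene set enrichment analysis
    variant using the median score as the set statistic with a
    label-permutation null; information-content based Gene Ontology
    semantic similarity; DNA repair pathway by tissue association tests;
    and enrichment of chemical-gene and virus-host interactions among
    tissue-specific cancer genes. Ships seeded synthetic-data generators
    emulating every input so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
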