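#' Specification of a synthetic benchmark bundle
#'
#' Collects every tunable of the seeded generators in one validated object.
#' The defaults describe the study conditions the pipeline is meant to
#' operate under: a few hundred scored genes over 21 tumor types, planted
#' tissue-specific genes (significant in exactly one type, insignificant
#' pan-cancer), planted general genes (strong pan-cancer signal, many
#' significant types), chemicals covering half of one type's specific
#' genes against a 3 percent background interaction rate, and viruses
#' whose interactors concentrate in one tissue group.
#'
#' @param seed Integer master seed; every generator derives an independent
#'   substream from it, so adding a generator never perturbs the others.
#' @param n_genes Total genes (default 250).
#' @param frac_specific,frac_general Fractions of planted specific /
#'   general genes (defaults 0.4 / 0.2; the rest is background). Planted
#'   counts are floors of the fractions.
#' @param n_types Number of tumor types (default 21, named from
#'   [default_tissue_map()]).
#' @param specific_types Tumor types that receive the planted specific
#'   genes, round-robin (default: the seven solid types used in the
#'   chemical analysis).
#' @param ontology_depth,ontology_branching Shape of the synthetic
#'   ontology tree (defaults 4 and 2: 31 terms).
#' @param chem_coverage Planted chemical coverage of its target type's
#'   specific genes (default 0.5).
#' @param chem_background_rate Bernoulli rate of background chemical-gene
#'   edges (default 0.03).
#' @param n_background_chemicals Number of unplanted chemicals
#'   (default 40).
#' @param n_expression_tissues Number of tissues in the expression matrix
#'   (default: the full tissue vocabulary of the tissue map).
#' @param tmap Tissue map (default [default_tissue_map()]).
#' @return A \code{synth_spec} list.
#' @export
synthetic_spec <- function(seed = 1, n_genes = 250, frac_specific = 0.4,
                           frac_general = 0.2, n_types = 21,
                           specific_types = c("BLCA", "BRCA", "CRC", "UCEC",
                                              "KIRC", "LUAD", "MEL"),
                           ontology_depth = 4, ontology_branching = 2,
                           chem_coverage = 0.5,
                           chem_background_rate = 0.03,
                           n_background_chemicals = 40,
                           n_expression_tissues = NULL,
                           tmap = default_tissue_map()) {
  if (frac_specific + frac_general > 1) {
    stop("frac_specific + frac_general must not exceed 1")
  }
  stopifnot(frac_specific >= 0, frac_general >= 0,
            chem_coverage >= 0, chem_coverage <= 1,
            ontology_depth >= 2)
  types <- names(tmap$cancer_to_tissue)[seq_len(n_types)]
  stopifnot(all(specific_types %in% types))
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 frac_specific = frac_specific, frac_general = frac_general,
                 types = types, specific_types = specific_types,
                 ontology_depth = ontology_depth,
                 ontology_branching = ontology_branching,
                 chem_coverage = chem_coverage,
                 chem_background_rate = chem_background_rate,
                 n_background_chemicals = n_background_chemicals,
                 n_expression_tissues = n_expression_tissues,
                 tmap = tmap),
            class = "synth_spec")
}

with_substream <- function(spec, label, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(spec$seed, label))
  code
}

log_uniform <- function(n, lo_exp, hi_exp) {
  10^stats::runif(n, lo_exp, hi_exp)
}

#' Generate a mutation significance table with planted structure
#'
#' Planted specific genes are significant (q drawn log-uniformly from
#' [1e-12, 1e-8]) in exactly one tumor type, insignificant elsewhere and
#' pan-cancer (q uniform on [0.1, 1]). Planted general genes carry strong
#' pan-cancer significance and 8 or more significant types. Background
#' genes have all q uniform on [0.1, 1]. The accompanying truth table also
#' fixes, per gene, the labels other generators rely on: associated
#' tissues, mutation origin and planted DNA repair class, so the whole
#' bundle stays coherent.
#'
#' @param spec A \code{synth_spec}.
#' @return List with \code{table} (a \code{mutsig}) and \code{truth}
#'   (data.frame: gene, class, planted_type, tissues
#'   (semicolon-separated), origin, repair_class).
#' @export
gen_mutation_table <- function(spec) {
  n <- spec$n_genes
  n_spec <- floor(spec$frac_specific * n)
  n_gen <- floor(spec$frac_general * n)
  genes <- sprintf("G%04d", seq_len(n))
  class <- c(rep("specific", n_spec), rep("general", n_gen),
             rep("background", n - n_spec - n_gen))
  types <- spec$types
  tmap <- spec$tmap
  with_substream(spec, "mutation", {
    q <- matrix(stats::runif(n * length(types), 0.1, 1), n,
                dimnames = list(genes, types))
    pan <- stats::runif(n, 0.1, 1)
    planted_type <- rep(NA_character_, n)
    # specific genes: round-robin over the designated solid types
    if (n_spec > 0) {
      pt <- rep(spec$specific_types, length.out = n_spec)
      for (i in seq_len(n_spec)) {
        q[i, pt[i]] <- log_uniform(1, -12, -8)
      }
      planted_type[seq_len(n_spec)] <- pt
    }
    # general genes: strong pan-cancer signal, >= 8 significant types
    if (n_gen > 0) {
      for (i in n_spec + seq_len(n_gen)) {
        k <- sample(8:length(types), 1)
        sig <- sample(types, k)
        q[i, sig] <- log_uniform(k, -12, -8)
        pan[i] <- log_uniform(1, -12, -8)
      }
    }
    # tissues: specific genes inherit their planted type's tissue;
    # general genes span many tissues; background genes one or two
    all_tissues <- unique(unname(tmap$cancer_to_tissue))
    tissues <- vector("list", n)
    for (i in seq_len(n)) {
      tissues[[i]] <- if (class[i] == "specific") {
        unname(tmap$cancer_to_tissue[[planted_type[i]]])
      } else if (class[i] == "general") {
        sample(all_tissues, sample(4:8, 1))
      } else {
        sample(all_tissues, sample(1:2, 1))
      }
    }
    # planted DNA repair classes live among the background genes, with
    # pathway-characteristic tissues (NER: skin, MM: colon, DSBR:
    # breast / blood) and a germline-heavy mutation origin
    repair_class <- rep("none", n)
    bg_idx <- which(class == "background")
    stopifnot(length(bg_idx) >= 32)
    ner <- bg_idx[1:9]; mm <- bg_idx[10:14]; dsbr <- bg_idx[15:27]
    multi <- bg_idx[28:32]
    repair_class[ner] <- "NER"; repair_class[mm] <- "MM"
    repair_class[dsbr] <- "DSBR"; repair_class[multi] <- "multiple"
    for (i in ner) tissues[[i]] <- "melanoma"
    for (i in mm) tissues[[i]] <- "colon"
    for (i in dsbr) tissues[[i]] <- sample(c("breast", "blood"), 1)
    origin <- ifelse(stats::runif(n) < 0.15, "germline", "somatic")
    uniq <- c(ner, mm, dsbr)
    origin[uniq] <- sample(rep(c("germline", "somatic", "both"),
                               c(17, 5, 5)), length(uniq))
    truth <- data.frame(
      gene = genes, class = class, planted_type = planted_type,
      tissues = vapply(tissues, paste, "", collapse = ";"),
      origin = origin, repair_class = repair_class,
      stringsAsFactors = FALSE)
    list(table = new_mutsig(genes, q, stats::setNames(pan, genes)),
         truth = truth)
  })
}

truth_tissues <- function(truth) {
  stats::setNames(strsplit(truth$tissues, ";", fixed = TRUE), truth$gene)
}

#' Generate a synthetic ontology with a planted general-gene module
#'
#' A complete rooted tree of the requested depth and branching (one
#' namespace), plus the three DNA repair class terms attached under the
#' root. Planted general genes draw their 2-3 leaf annotations from the
#' leaves of one designated depth-1 subtree (the "general module"), giving
#' them elevated annotation clustering; all other genes draw uniformly
#' from all leaves. Genes with a planted repair class are annotated to the
#' corresponding repair term(s).
#'
#' @param spec A \code{synth_spec}.
#' @param truth Truth table from [gen_mutation_table()].
#' @return List with \code{graph} (an \code{ontology}) and
#'   \code{module_terms} (leaf ids of the planted general module).
#' @export
gen_ontology <- function(spec, truth) {
  d <- spec$ontology_depth; b <- spec$ontology_branching
  if (d < 2) stop("ontology depth must be at least 2")
  ids <- "T1"; parents <- list(T1 = character())
  level <- list("T1"); counter <- 1L
  for (depth in seq_len(d)) {
    nxt <- character()
    for (p in level[[depth]]) {
      for (j in seq_len(b)) {
        counter <- counter + 1L
        id <- paste0("T", counter)
        ids <- c(ids, id)
        parents[[id]] <- p
        nxt <- c(nxt, id)
      }
    }
    level[[depth + 1]] <- nxt
  }
  leaves <- level[[d + 1]]
  # general module: leaves under the first depth-1 child
  first_child <- level[[2]][1]
  module_leaves <- leaves[seq_len(length(leaves) / b)]
  repair_terms <- default_repair_terms()
  repair_parent <- "T_repair"
  ids <- c(ids, repair_parent, unname(repair_terms))
  parents[[repair_parent]] <- "T1"
  for (t in repair_terms) parents[[t]] <- repair_parent
  terms <- data.frame(
    id = ids,
    name = ids,
    namespace = "biological_process", stringsAsFactors = FALSE)
  with_substream(spec, "ontology", {
    ann <- lapply(seq_len(nrow(truth)), function(i) {
      n_ann <- sample(2:3, 1)
      pool <- if (truth$class[i] == "general") module_leaves else leaves
      picked <- sample(pool, min(n_ann, length(pool)))
      rc <- truth$repair_class[i]
      extra <- if (rc %in% names(repair_terms)) {
        unname(repair_terms[rc])
      } else if (rc == "multiple") {
        unname(sample(repair_terms, 2))
      } else character()
      c(picked, extra)
    })
    names(ann) <- truth$gene
    list(graph = build_ontology(terms, parents, ann),
         module_terms = module_leaves)
  })
}

#' Generate a synthetic bipartite interaction network
#'
#' Chemical mode: one planted chemical per designated specific cancer
#' type, covering \code{chem_coverage} of that type's planted specific
#' genes with well-evidenced edges (evidence 2-5, large source studies),
#' plus background edges at rate \code{chem_background_rate} between every
#' (gene, chemical) pair, a quarter of them supported by a single evidence
#' item and a mix of small and large source studies (so the evidence and
#' study-size filters have work to do). A few background chemicals are
#' flagged as approved drugs; the planted lung chemical and one background
#' chemical are flagged as hazardous air pollutants.
#'
#' Virus mode: three species (EBV-, HPV16- and HIV1-like, with 5, 3 and 3
#' strains). Planted general genes interact with 2-4 strains; a planted
#' subset of tissue-matched specific genes interacts with exactly one
#' strain of the species preferring their tissue group (EBV: blood, HPV16:
#' endometrium/bladder/breast/ovary, HIV1: diffuse).
#'
#' @param spec A \code{synth_spec}.
#' @param truth Truth table from [gen_mutation_table()].
#' @param kind "chemical" or "virus_strain".
#' @return A \code{bipartite_net}.
#' @export
gen_network <- function(spec, truth, kind = c("chemical", "virus_strain")) {
  kind <- match.arg(kind)
  if (kind == "chemical") gen_chemical_network(spec, truth)
  else gen_virus_network(spec, truth)
}

gen_chemical_network <- function(spec, truth) {
  if (spec$chem_coverage > 1) stop("planted coverage must be <= 1")
  with_substream(spec, "chem_network", {
    spec_genes <- split(truth$gene[truth$class == "specific"],
                        truth$planted_type[truth$class == "specific"])
    planted <- paste0("chem_planted_", names(spec_genes))
    bg_chems <- sprintf("chem_bg_%02d", seq_len(spec$n_background_chemicals))
    edges <- list()
    add_edge <- function(g, p, ev, ss) {
      edges[[length(edges) + 1L]] <<- data.frame(
        gene = g, partner = p, evidence = ev, study_size = ss,
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(spec_genes)) {
      tgt <- spec_genes[[i]]
      n_hit <- round(spec$chem_coverage * length(tgt))
      for (g in sample(tgt, n_hit)) {
        add_edge(g, planted[i], sample(2:5, 1), sample(c(600, 800, 1000), 1))
      }
    }
    all_chems <- c(planted, bg_chems)
    for (ch in all_chems) {
      hit <- truth$gene[stats::runif(nrow(truth)) <
                          spec$chem_background_rate]
      for (g in hit) {
        ev <- if (stats::runif(1) < 0.25) 1L else sample(2:4, 1)
        ss <- sample(c(5, 20, 100, 600), 1)
        add_edge(g, ch, ev, ss)
      }
    }
    attrs <- data.frame(
      partner = all_chems,
      is_drug = c(rep(FALSE, length(planted)),
                  seq_along(bg_chems) <= 5),
      is_air_pollutant = all_chems %in%
        c("chem_planted_LUAD", "chem_bg_10"),
      stringsAsFactors = FALSE)
    build_network(do.call(rbind, edges), "chemical", attrs)
  })
}

gen_virus_network <- function(spec, truth) {
  with_substream(spec, "virus_network", {
    strains <- c(paste0("EBV_s", 1:5), paste0("HPV16_s", 1:3),
                 paste0("HIV1_s", 1:3))
    species <- c(rep("EBV", 5), rep("HPV16", 3), rep("HIV1", 3))
    pref <- list(EBV = c("blood"),
                 HPV16 = c("endometrium", "bladder", "breast", "ovary"),
                 HIV1 = character())
    tiss <- truth_tissues(truth)
    edges <- list()
    add_edge <- function(g, p) {
      edges[[length(edges) + 1L]] <<- data.frame(
        gene = g, partner = p, evidence = sample(2:4, 1),
        study_size = sample(c(100, 600, 900), 1),
        stringsAsFactors = FALSE)
    }
    # tropism: a virus targets genes expressed in its preferred tissues,
    # so each interacting gene draws its strains from species weighted by
    # the overlap between the gene's tissues and the species preference
    species_weights <- function(g) {
      vapply(names(pref), function(sp) {
        liked <- pref[[sp]]
        if (length(liked) == 0) 1.5
        else if (length(intersect(tiss[[g]], liked)) > 0) 20 else 1
      }, 0)
    }
    pick_strains <- function(g, n_slots) {
      w <- species_weights(g)
      sp_pick <- sample(names(pref), n_slots, replace = TRUE, prob = w)
      unique(vapply(sp_pick, function(sp)
        sample(strains[species == sp], 1), ""))
    }
    # general genes are hubs: interactors of several strains each
    for (g in truth$gene[truth$class == "general"]) {
      for (s in pick_strains(g, sample(2:4, 1))) add_edge(g, s)
    }
    # a planted subset of the remaining genes carries one strain each
    cand <- truth$gene[truth$class != "general"]
    for (g in sample(cand, min(75, length(cand)))) {
      add_edge(g, pick_strains(g, 1))
    }
    attrs <- data.frame(partner = strains, species = species,
                        stringsAsFactors = FALSE)
    build_network(do.call(rbind, edges), "virus_strain", attrs)
  })
}

#' Generate a synthetic expression matrix
#'
#' Per-gene expression breadth is drawn uniformly between 1 and the number
#' of tissues; detected tissues get gamma-distributed abundances. One
#' planted specific gene is made maximally abundant in its pathology
#' tissue (a direct match) and three in a tissue adjacent to it, matching
#' the near-absence of expression/pathology agreement the matrix is meant
#' to emulate.
#'
#' @param spec A \code{synth_spec}.
#' @param truth Truth table from [gen_mutation_table()].
#' @return Numeric matrix genes x tissues.
#' @export
gen_expression <- function(spec, truth) {
  tmap <- spec$tmap
  tissue_vocab <- unique(c(unname(tmap$cancer_to_tissue),
                           tmap$adjacency$a, tmap$adjacency$b,
                           c("liver", "spleen", "pancreas", "stomach",
                             "testis", "skin_ref")))
  n_tiss <- spec$n_expression_tissues %||% length(tissue_vocab)
  tissues <- tissue_vocab[seq_len(min(n_tiss, length(tissue_vocab)))]
  with_substream(spec, "expression", {
    n <- nrow(truth)
    m <- matrix(0, n, length(tissues),
                dimnames = list(truth$gene, tissues))
    for (i in seq_len(n)) {
      breadth <- sample.int(length(tissues), 1)
      det <- sample(tissues, breadth)
      m[i, det] <- stats::rgamma(breadth, shape = 2, rate = 0.5)
    }
    # planted agreement: 1 direct + 3 adjacent among the specific genes
    spec_idx <- which(truth$class == "specific")
    mappable <- spec_idx[vapply(spec_idx, function(i) {
      t <- unname(tmap$cancer_to_tissue[[truth$planted_type[i]]])
      t %in% tissues && length(intersect(adjacent_tissues(tmap, t),
                                         tissues)) > 0
    }, TRUE)]
    if (length(mappable) < 4) stop("planted match for unmapped type")
    picks <- sample(mappable, 4)
    tgt <- function(i) unname(tmap$cancer_to_tissue[[truth$planted_type[i]]])
    m[picks[1], tgt(picks[1])] <- max(m[picks[1], ]) + 1
    for (i in picks[2:4]) {
      adj <- intersect(adjacent_tissues(tmap, tgt(i)), tissues)
      m[i, sample(adj, 1)] <- max(m[i, ]) + 1
    }
    m
  })
}

#' Generate a census-style cancer gene catalog table
#'
#' One row per gene-tissue pair with mutation origin and a hallmark label
#' (DNA repair genes labeled \code{dna_repair}; planted general genes are
#' split between \code{oncogene} and \code{tumor_suppressor}; the rest
#' \code{other}), consumable by [build_ext_catalog()].
#'
#' @param spec A \code{synth_spec}.
#' @param truth Truth table from [gen_mutation_table()].
#' @return data.frame with columns gene, tissue, origin, hallmark.
#' @export
gen_census <- function(spec, truth) {
  tiss <- truth_tissues(truth)
  with_substream(spec, "census", {
    hallmark <- rep("other", nrow(truth))
    gen_idx <- which(truth$class == "general")
    hallmark[gen_idx] <- sample(c("oncogene", "tumor_suppressor"),
                                length(gen_idx), replace = TRUE)
    hallmark[truth$repair_class != "none"] <- "dna_repair"
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      data.frame(gene = truth$gene[i], tissue = tiss[[truth$gene[i]]],
                 origin = truth$origin[i], hallmark = hallmark[i],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate per-gene publication counts
#'
#' Log-normally distributed counts, mildly correlated with generality
#' (planted general genes get a 4-fold multiplier), so a study-bias filter
#' at 500 removes a realistic minority of the genes.
#'
#' @param spec A \code{synth_spec}.
#' @param truth Truth table from [gen_mutation_table()].
#' @return Named integer vector gene -> count.
#' @export
gen_study_counts <- function(spec, truth) {
  with_substream(spec, "study_counts", {
    mult <- ifelse(truth$class == "general", 4, 1)
    n <- round(stats::rlnorm(nrow(truth), meanlog = 3.5, sdlog = 1.6) * mult)
    stats::setNames(as.integer(n), truth$gene)
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits every input file of the pipeline in its external format
#' (mutation TSV, ontology OBO + annotation TSV, GMT gene sets, chemical
#' and virus edge/attribute TSVs, expression TSV, study-count TSV,
#' census TSV) plus the truth table, all readable by the package's
#' readers.
#'
#' @param spec A \code{synth_spec}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_synth_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  mt <- gen_mutation_table(spec)
  onto <- gen_ontology(spec, mt$truth)
  chem <- gen_chemical_network(spec, mt$truth)
  virus <- gen_virus_network(spec, mt$truth)
  expr <- gen_expression(spec, mt$truth)
  census <- gen_census(spec, mt$truth)
  counts <- gen_study_counts(spec, mt$truth)

  write_mutation_table(mt$table, p("mutation_table.tsv"))
  utils::write.table(mt$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_obo(onto$graph, p("ontology.obo"))
  ann <- data.frame(
    gene = rep(names(onto$graph$annotations),
               lengths(onto$graph$annotations)),
    term = unlist(onto$graph$annotations))
  utils::write.table(ann, p("annotations.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sets <- ontology_gene_sets(onto$graph, min_genes = 2)
  write_gmt(sets, p("gene_sets.gmt"))
  write_network_files(chem, p("chem_edges.tsv"), p("chem_attributes.tsv"))
  write_network_files(virus, p("virus_edges.tsv"), p("virus_attributes.tsv"))
  expr_df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(expr_df, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(counts), n_studies = counts),
                     p("study_counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(census, p("census.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(
    mutation_table = p("mutation_table.tsv"), truth = p("truth.tsv"),
    obo = p("ontology.obo"), annotations = p("annotations.tsv"),
    gmt = p("gene_sets.gmt"),
    chem_edges = p("chem_edges.tsv"),
    chem_attributes = p("chem_attributes.tsv"),
    virus_edges = p("virus_edges.tsv"),
    virus_attributes = p("virus_attributes.tsv"),
    expression = p("expression.tsv"),
    study_counts = p("study_counts.tsv"), census = p("census.tsv")))
}

#' Write an ontology in the OBO 1.2 subset read by [read_obo_lite()]
#' @param graph An \code{ontology}.
#' @param path Output path.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    ps <- graph$parents[[id]]
    is_a_lines <- if (length(ps) > 0) paste0("is_a: ", ps) else character()
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", graph$terms$name[i]),
                 paste0("namespace: ", graph$terms$namespace[i]),
                 is_a_lines), con)
  }
  invisible(path)
}

write_network_files <- function(net, edges_path, attrs_path) {
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attrs <- net$partners
  names(attrs)[names(attrs) == "kind"] <- "partner_kind"
  utils::write.table(attrs[, setdiff(names(attrs), "partner_kind")],
                     attrs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
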