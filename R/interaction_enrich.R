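#' Apply bias-control filters to a bipartite network
#'
#' Three independent edge/partner filters, applicable in any order with the
#' same result: minimum evidence count per edge (associations supported by
#' a single evidence item are typically removed), exclusion of partners
#' flagged as approved drugs (drug-gene edges reflect treatment, not
#' environmental exposure), and a minimum source-study size (guards against
#' small, hypothesis-driven studies biased toward known cancer genes).
#'
#' @param net A \code{bipartite_net}.
#' @param min_evidence Keep edges with evidence >= this (default 2).
#' @param exclude_drugs Drop all edges of drug-flagged partners.
#' @param min_study_size Keep edges whose largest source study reported at
#'   least this many interactions (default 1 = no filter).
#' @return The filtered \code{bipartite_net}.
#' @export
filter_network <- function(net, min_evidence = 2, exclude_drugs = FALSE,
                           min_study_size = 1) {
  stopifnot(inherits(net, "bipartite_net"),
            min_evidence >= 0, min_study_size >= 0)
  e <- net$edges
  keep <- e$evidence >= min_evidence & e$study_size >= min_study_size
  if (exclude_drugs) {
    drugs <- net$partners$partner[net$partners$is_drug]
    keep <- keep & !e$partner %in% drugs
  }
  e <- e[keep, , drop = FALSE]
  if (nrow(e) == 0) {
    stop("no edge survives the filters (min_evidence = ", min_evidence,
         ", exclude_drugs = ", exclude_drugs, ", min_study_size = ",
         min_study_size, ")")
  }
  rownames(e) <- NULL
  p <- net$partners[net$partners$partner %in% e$partner, , drop = FALSE]
  rownames(p) <- NULL
  structure(list(edges = e, partners = p, kind = net$kind),
            class = "bipartite_net")
}

#' Per-cancer-type sets of specific genes
#'
#' Genes significantly mutated in exactly one tumor type (k = 1), grouped
#' by that type; types with fewer than \code{min_genes} such genes are
#' dropped, and optionally only solid tumor types are kept (solid cancers
#' have an unambiguous tissue of origin).
#'
#' @param scores A \code{specificity_table} (carries each gene's
#'   significant types).
#' @param tmap A \code{tissue_map} (solid flags).
#' @param min_genes Minimum specific genes per retained type (default 8).
#' @param solid_only Keep only solid tumor types (default TRUE).
#' @return Named list cancer type -> character vector of genes.
#' @export
specific_gene_sets <- function(scores, tmap, min_genes = 8,
                               solid_only = TRUE) {
  k1 <- scores$k == 1
  type_of <- vapply(scores$sig_types[k1], `[[`, "", 1)
  sets <- split(scores$gene[k1], type_of)
  if (solid_only) {
    solid <- names(tmap$solid)[tmap$solid]
    sets <- sets[names(sets) %in% solid]
  }
  sets <- sets[lengths(sets) >= min_genes]
  if (length(sets) == 0) {
    stop("no cancer type with at least ", min_genes, " specific genes")
  }
  sets
}

#' Chemical enrichment among type-specific cancer genes
#'
#' For every (cancer type, chemical) pair, tests whether the chemical
#' interacts with more of the type's specific genes than expected from its
#' interaction rate in the background — the union of all investigated
#' types' specific genes. The 2x2 table is (in-type interacting /
#' not-interacting) vs (background-minus-type interacting /
#' not-interacting), tested by Pearson's chi-squared without continuity
#' correction; when any expected count falls below 5 the exact Fisher test
#' is used instead and the row is flagged. p values are BH-adjusted across
#' all tested pairs. A row is "reportable" when q < alpha and the chemical
#' covers at least 20 percent of the type's specific genes.
#'
#' @param sets Named list from [specific_gene_sets()].
#' @param net A filtered chemical \code{bipartite_net}.
#' @param alpha Reportability level on q (default 0.01).
#' @param min_coverage Reportability coverage threshold (default 0.20).
#' @return data.frame with one row per tested pair: \code{cancer_type},
#'   \code{chemical}, \code{n_interacting}, \code{n_specific},
#'   \code{coverage}, \code{statistic}, \code{p_value}, \code{q_value},
#'   \code{fisher_fallback}, \code{reportable}.
#' @export
chemical_enrichment <- function(sets, net, alpha = 0.01,
                                min_coverage = 0.20) {
  stopifnot(net$kind == "chemical")
  background <- unique(unlist(sets))
  edges <- net$edges[net$edges$gene %in% background, , drop = FALSE]
  by_chem <- split(edges$gene, edges$partner)
  by_chem <- lapply(by_chem, unique)
  skipped <- setdiff(unique(net$edges$partner), names(by_chem))
  if (length(skipped) > 0) {
    message(length(skipped),
            " chemical(s) without background interactors skipped")
  }
  rows <- list()
  for (chem in names(by_chem)) {
    interactors <- by_chem[[chem]]
    for (ty in names(sets)) {
      in_type <- sets[[ty]]
      out_type <- setdiff(background, in_type)
      a <- length(intersect(interactors, in_type))
      b <- length(in_type) - a
      c_ <- length(intersect(interactors, out_type))
      d <- length(out_type) - c_
      tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      fallback <- any(expected < 5)
      if (fallback) {
        p <- stats::fisher.test(tab)$p.value
        statistic <- NA_real_
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        p <- ct$p.value
        statistic <- unname(ct$statistic)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cancer_type = ty, chemical = chem, n_interacting = a,
        n_specific = length(in_type), coverage = a / length(in_type),
        statistic = statistic, p_value = p, fisher_fallback = fallback,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cancer_type, out$chemical), , drop = FALSE]
  out$q_value <- bh_adjust(pmin(1, pmax(out$p_value, .Machine$double.xmin)))
  out$reportable <- out$q_value < alpha & out$coverage >= min_coverage
  rownames(out) <- NULL
  out
}

#' Air-pollutant fraction among a type's reportable chemicals
#'
#' The fraction of a cancer type's reportable chemicals flagged as
#' hazardous air pollutants, with a two-sided Fisher test against the
#' pollutant frequency in the background chemical universe (all chemicals
#' interacting with at least one specific cancer gene of any investigated
#' type).
#'
#' @param chemicals Character vector of reportable chemicals for the type.
#' @param pollutant_flags Named logical: chemical -> is air pollutant
#'   (covers at least the union of \code{chemicals} and
#'   \code{background_chemicals}).
#' @param background_chemicals Character vector: the background universe.
#' @return List with \code{fraction}, \code{n_pollutant}, \code{n},
#'   \code{background_fraction}, \code{p_value}.
#' @export
pollutant_fraction <- function(chemicals, pollutant_flags,
                               background_chemicals) {
  if (length(chemicals) < 1) stop("need at least one reportable chemical")
  if (length(background_chemicals) < 1) stop("empty background universe")
  flag <- function(x) {
    f <- pollutant_flags[x]
    f[is.na(f)] <- FALSE
    f
  }
  f_rep <- flag(chemicals)
  rest <- setdiff(background_chemicals, chemicals)
  f_rest <- flag(rest)
  frac <- mean(f_rep)
  bg_frac <- mean(flag(background_chemicals))
  tab <- matrix(c(sum(f_rep), sum(!f_rep), sum(f_rest), sum(!f_rest)),
                2, byrow = TRUE)
  p <- if (any(colSums(tab) == 0)) 1 else stats::fisher.test(tab)$p.value
  list(fraction = frac, n_pollutant = sum(f_rep), n = length(chemicals),
       background_fraction = bg_frac, p_value = p)
}

# distinct virus strains (partner ids) per gene
strain_counts <- function(net) {
  stopifnot(net$kind == "virus_strain")
  counts <- tapply(net$edges$partner, net$edges$gene,
                   function(p) length(unique(p)))
  stats::setNames(as.integer(counts), names(counts))
}

#' Tumor-type breadth vs number of interacting virus strains
#'
#' Partitions catalog genes by the number of distinct virus strains whose
#' proteins they interact with (strains, not species, are the counting
#' unit) and compares the per-gene number of associated tumor tissues
#' between genes touched by at most one strain and genes touched by
#' several. Also reports the control contrast of genes with no viral
#' interaction vs exactly one strain.
#'
#' @param net A virus \code{bipartite_net}.
#' @param catalog A \code{cancer_catalog} (tissue breadth source).
#' @return List with \code{multi_vs_few} (a \code{score_comparison},
#'   group A = <=1 strain, group B = >1), \code{none_vs_one}, and the
#'   per-gene \code{strain_count} vector.
#' @export
virus_strain_specificity <- function(net, catalog) {
  sc <- strain_counts(net)
  keep <- lengths(catalog$tissues) > 0
  genes <- catalog$gene[keep]
  breadth <- stats::setNames(lengths(catalog$tissues[keep]), genes)
  n_strain <- stats::setNames(rep(0L, length(genes)), genes)
  hit <- intersect(genes, names(sc))
  n_strain[hit] <- sc[hit]
  few <- genes[n_strain <= 1]
  multi <- genes[n_strain > 1]
  if (length(few) < 2 || length(multi) < 2) {
    stop("strain-count partition too small (", length(few), " vs ",
         length(multi), " genes)")
  }
  main <- compare_score_groups(NULL, few, multi, values = breadth)
  none <- genes[n_strain == 0]
  one <- genes[n_strain == 1]
  control <- if (length(none) >= 2 && length(one) >= 2) {
    compare_score_groups(NULL, none, one, values = breadth)
  } else NULL
  list(multi_vs_few = main, none_vs_one = control, strain_count = n_strain)
}

#' Normalized virus x tissue-group interaction profile
#'
#' For each virus species, the fraction of its cancer-gene interactors
#' associated with each tissue group:
#' entry(v, t) = interactors of v with tissue-group t / interactors of v
#' with any tissue. Multi-tissue genes count in each of their groups, so
#' rows need not sum to 1. Viruses without any tissue-annotated cancer
#' interactor are dropped with a warning.
#'
#' @param net A virus \code{bipartite_net} (strain partners carry species
#'   attributes).
#' @param catalog A \code{cancer_catalog}.
#' @param viruses Character vector of species to profile (default: all
#'   species in the network).
#' @param tmap A \code{tissue_map}; catalog tissue labels are passed
#'   through its grouping before counting.
#' @return Numeric matrix, virus species x tissue group, entries in [0,1].
#' @export
virus_tissue_profile <- function(net, catalog, viruses = NULL, tmap) {
  stopifnot(net$kind == "virus_strain")
  species_of <- stats::setNames(net$partners$species, net$partners$partner)
  if (is.null(viruses)) viruses <- sort(unique(net$partners$species))
  tiss <- lapply(catalog$tissues, function(ts) unique(group_tissues(tmap, ts)))
  names(tiss) <- catalog$gene
  tiss <- tiss[lengths(tiss) > 0]
  groups <- sort(unique(unlist(tiss)))
  m <- matrix(NA_real_, length(viruses), length(groups),
              dimnames = list(viruses, groups))
  dropped <- character()
  for (v in viruses) {
    strains <- net$partners$partner[net$partners$species == v]
    inter <- unique(net$edges$gene[net$edges$partner %in% strains])
    inter <- intersect(inter, names(tiss))
    if (length(inter) == 0) {
      dropped <- c(dropped, v)
      next
    }
    for (g in groups) {
      m[v, g] <- sum(vapply(tiss[inter], function(ts) g %in% ts, TRUE)) /
        length(inter)
    }
  }
  if (length(dropped) > 0) {
    warning("virus(es) without tissue-annotated cancer interactors ",
            "dropped: ", paste(dropped, collapse = ", "), call. = FALSE)
    m <- m[!rownames(m) %in% dropped, , drop = FALSE]
  }
  m
}
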