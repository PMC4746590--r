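#' Run the full specificity pipeline from a config
#'
#' Orchestrates every stage in order — scoring, gene set enrichment,
#' semantic similarity, DNA repair by tissue, chemical enrichment, virus
#' analyses, expression agreement — reading all inputs from files named in
#' a YAML (or list) config, writing one TSV per stage plus a JSON-like run
#' manifest (inputs with checksums, seed, thresholds, per-stage row
#' counts). All input paths are validated before any stage runs.
#'
#' Config keys (paths): \code{mutation_table}, \code{gmt}, \code{obo},
#' \code{annotations}, \code{chem_edges}, \code{chem_attributes},
#' \code{virus_edges}, \code{virus_attributes}, \code{expression},
#' \code{study_counts}, \code{census}. Scalars: \code{seed},
#' \code{tau}, \code{epsilon}, \code{max_studies}, \code{min_set_size},
#' \code{n_perm}, \code{n_top}, \code{min_evidence}, \code{min_genes},
#' \code{alpha}.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory.
#' @return Invisibly, a named list of stage outputs.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1, tau = 0.1, epsilon = 1e-16, max_studies = 500,
                   min_set_size = 8, n_perm = 1000, n_top = 30,
                   min_evidence = 2, min_genes = 8, alpha = 0.01)
  for (k in names(defaults)) config[[k]] <- config[[k]] %||% defaults[[k]]
  inputs <- c("mutation_table", "gmt", "obo", "annotations", "chem_edges",
              "chem_attributes", "virus_edges", "virus_attributes",
              "expression", "study_counts", "census")
  missing_keys <- inputs[vapply(inputs, function(k)
    is.null(config[[k]]), TRUE)]
  if (length(missing_keys) > 0) {
    stop("config is missing input(s): ", paste(missing_keys, collapse = ", "))
  }
  absent <- inputs[!vapply(inputs, function(k)
    file.exists(config[[k]]), TRUE)]
  if (length(absent) > 0) {
    stop("input file(s) not found: ",
         paste(vapply(absent, function(k) config[[k]], ""), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tmap <- default_tissue_map()
  log_stage <- function(stage, n_in, n_out) {
    message(sprintf("[%s] rows in: %d, rows out: %d", stage, n_in, n_out))
  }
  emit <- function(df, name) {
    flat <- df
    for (col in names(flat)) {
      if (is.list(flat[[col]])) {
        flat[[col]] <- vapply(flat[[col]], paste, "", collapse = ";")
      }
    }
    utils::write.table(flat, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # score
  mt <- read_mutation_table(config$mutation_table)
  scores <- rank_genes(mt, tau = config$tau, epsilon = config$epsilon)
  counts <- read_study_counts(config$study_counts)
  scores_filt <- filter_by_study_count(scores, counts, config$max_studies)
  emit(scores[setdiff(names(scores), "sig_types")], "score")
  log_stage("score", length(mt$gene), nrow(scores_filt))

  # gsea
  sets <- read_gmt(config$gmt)
  gsea <- run_gsea(scores, sets, min_size = config$min_set_size,
                   n_perm = config$n_perm, seed = config$seed)
  emit(gsea, "gsea")
  log_stage("gsea", length(sets), nrow(gsea))

  # semsim
  onto <- read_obo_lite(config$obo, config$annotations)
  ic <- term_ic(onto)
  ext <- compare_extremes(scores_filt, n_top = config$n_top, onto, ic)
  semsim_df <- data.frame(
    group = c("specific", "general"),
    n_pairs = c(length(ext$specific_similarities),
                length(ext$general_similarities)),
    median_similarity = c(ext$median_specific, ext$median_general),
    p_value = ext$comparison$p_value)
  emit(semsim_df, "semsim")
  log_stage("semsim", nrow(scores_filt), nrow(semsim_df))

  # repair
  census <- utils::read.delim(config$census, stringsAsFactors = FALSE)
  catalog <- suppressMessages(
    build_ext_catalog(scores, list(census), tmap))
  catalog <- assign_repair_pathways(catalog, onto)
  counts_tp <- pathway_tissue_counts(catalog)
  fisher_rows <- do.call(rbind, lapply(rownames(counts_tp), function(ti) {
    do.call(rbind, lapply(colnames(counts_tp), function(pw) {
      ft <- suppressMessages(pathway_tissue_fisher(counts_tp, pw, ti))
      data.frame(tissue = ti, pathway = pw, odds_ratio = ft$odds_ratio,
                 p_value = ft$p_value)
    }))
  }))
  emit(as.data.frame(counts_tp), "repair_counts")
  emit(fisher_rows, "repair_fisher")
  pca <- pca_tissues(counts_tp)
  emit(data.frame(tissue = rownames(pca$scores), pca$scores), "repair_pca")
  log_stage("repair", nrow(catalog), nrow(fisher_rows))

  # chem
  chem_net <- read_network(config$chem_edges, "chemical",
                           config$chem_attributes)
  chem_filt <- filter_network(chem_net, min_evidence = config$min_evidence,
                              exclude_drugs = TRUE)
  sets_by_type <- specific_gene_sets(scores, tmap,
                                     min_genes = config$min_genes)
  chem <- suppressMessages(
    chemical_enrichment(sets_by_type, chem_filt, alpha = config$alpha))
  emit(chem, "chem")
  log_stage("chem", nrow(chem_net$edges), nrow(chem))

  # virus
  virus_net <- read_network(config$virus_edges, "virus_strain",
                            config$virus_attributes)
  virus_filt <- filter_network(virus_net,
                               min_evidence = config$min_evidence)
  vss <- virus_strain_specificity(virus_filt, catalog)
  profile <- suppressWarnings(
    virus_tissue_profile(virus_filt, catalog, tmap = tmap))
  emit(data.frame(virus = rownames(profile), profile, check.names = FALSE),
       "virus_profile")
  emit(data.frame(
    comparison = c("le1_vs_multi",
                   if (!is.null(vss$none_vs_one)) "none_vs_one"),
    p_value = c(vss$multi_vs_few$p_value,
                if (!is.null(vss$none_vs_one)) vss$none_vs_one$p_value)),
    "virus_specificity")
  log_stage("virus", nrow(virus_net$edges), nrow(profile))

  # expr
  expr <- read_expression(config$expression)
  breadth <- tissue_breadth(expr)
  corr <- breadth_specificity_correlation(breadth, scores)
  k1 <- scores$k == 1
  solid <- names(tmap$solid)[tmap$solid]
  spec_types <- stats::setNames(
    vapply(scores$sig_types[k1], `[[`, "", 1), scores$gene[k1])
  spec_types <- spec_types[spec_types %in% solid]
  match <- suppressMessages(top_tissue_match(spec_types, expr, tmap))
  p0 <- match_null_probability(spec_types, expr, tmap)
  n_match <- sum(match$counts[c("direct", "adjacent")])
  expr_df <- data.frame(
    metric = c("r_score", "p_score", "r_raw_k", "n_direct", "n_adjacent",
               "n_none", "binomial_p"),
    value = c(corr$score$r, corr$score$p_value, corr$raw_k$r,
              match$counts["direct"], match$counts["adjacent"],
              match$counts["none"],
              binomial_match_test(n_match, length(match$match), p0)))
  emit(expr_df, "expr")
  log_stage("expr", nrow(expr), nrow(expr_df))

  manifest <- list(
    inputs = lapply(stats::setNames(inputs, inputs), function(k) {
      list(path = config[[k]],
           md5 = unname(tools::md5sum(config[[k]])))
    }),
    parameters = config[names(defaults)],
    r_version = as.character(getRversion()))
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  invisible(list(scores = scores, gsea = gsea, semsim = semsim_df,
                 repair_counts = counts_tp, chem = chem,
                 virus_profile = profile, expr = expr_df))
}
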