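#' Read a per-gene mutation significance table
#'
#' Parses a tab-separated table of multiple-testing corrected mutation
#' enrichment q values, one row per gene, with one column per tumor type and
#' a pan-cancer column (the pooled cohort). These tables are the starting
#' point of the specificity analysis: from them the per-gene \code{mostQ}
#' (smallest single-type q), \code{panQ} (pan-cancer q) and \code{k}
#' (number of significantly mutated types) are derived.
#'
#' Column roles are declared, never sniffed: a silently mis-mapped q column
#' is the worst possible failure mode for everything downstream.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect A list with elements \code{gene_col} (name of the gene
#'   identifier column), \code{pan_col} (name of the pan-cancer q column)
#'   and optionally \code{type_cols} (character vector of tumor-type q
#'   columns; default: every remaining column).
#' @return An object of class \code{mutsig}: a list with \code{gene}
#'   (character), \code{q_type} (numeric matrix, genes x tumor types, row
#'   names = genes) and \code{pan_q} (named numeric).
#' @details Missing or empty q cells are treated as 1.0 (least significant),
#'   with a warning naming the count; this is conservative for specificity
#'   calls. q values outside [0, 1] and non-numeric cells are hard errors
#'   reporting the offending row.
#' @export
read_mutation_table <- function(path, dialect = list(gene_col = "gene",
                                                     pan_col = "pan")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  gene_col <- dialect$gene_col %||% "gene"
  pan_col <- dialect$pan_col %||% "pan"
  for (col in c(gene_col, pan_col)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path)
    }
  }
  type_cols <- dialect$type_cols %||% setdiff(names(df), c(gene_col, pan_col))
  if (length(type_cols) < 1) {
    stop("mutation table needs at least one tumor-type q column")
  }
  genes <- df[[gene_col]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    stop("duplicate gene_id in mutation table: ",
         paste(unique(dup), collapse = ", "))
  }
  parse_q <- function(x, col) {
    blank <- is.na(x) | !nzchar(trimws(x))
    q <- suppressWarnings(as.numeric(x))
    bad <- !blank & is.na(q)
    if (any(bad)) {
      stop("non-numeric q value in column '", col, "' at row ",
           which(bad)[1], ": '", x[which(bad)[1]], "'")
    }
    out_of_range <- !is.na(q) & (q < 0 | q > 1)
    if (any(out_of_range)) {
      stop("q value outside [0,1] in column '", col, "' at row ",
           which(out_of_range)[1], ": ", q[which(out_of_range)[1]])
    }
    n_missing <- sum(blank)
    if (n_missing > 0) {
      warning(n_missing, " missing q value(s) in column '", col,
              "' set to 1.0", call. = FALSE)
      q[blank] <- 1.0
    }
    q
  }
  q_type <- sapply(type_cols, function(col) parse_q(df[[col]], col))
  q_type <- matrix(q_type, nrow = length(genes),
                   dimnames = list(genes, type_cols))
  pan_q <- parse_q(df[[pan_col]], pan_col)
  names(pan_q) <- genes
  new_mutsig(genes, q_type, pan_q)
}

new_mutsig <- function(gene, q_type, pan_q) {
  structure(list(gene = gene, q_type = q_type, pan_q = pan_q),
            class = "mutsig")
}

#' Write a mutation significance table to TSV
#'
#' Inverse of [read_mutation_table()] (round-trip identity on valid data).
#'
#' @param x A \code{mutsig} object.
#' @param path Output path.
#' @param dialect Column naming, as in [read_mutation_table()].
#' @export
write_mutation_table <- function(x, path, dialect = list(gene_col = "gene",
                                                         pan_col = "pan")) {
  stopifnot(inherits(x, "mutsig"))
  df <- data.frame(gene = x$gene, x$q_type, pan = x$pan_q,
                   check.names = FALSE, row.names = NULL)
  names(df)[1] <- dialect$gene_col %||% "gene"
  names(df)[ncol(df)] <- dialect$pan_col %||% "pan"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.mutsig <- function(x, ...) {
  cat("Mutation significance table:", length(x$gene), "genes x",
      ncol(x$q_type), "tumor types (+ pan-cancer)\n")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, \code{name TAB description TAB member...}.
#'
#' @param path Path to a GMT file.
#' @return A \code{gene_sets} object: a named list of character vectors with
#'   a \code{descriptions} attribute (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    stop("GMT line ", which(short)[1], " has fewer than 3 fields")
  }
  names_ <- vapply(fields, `[[`, "", 1)
  dup <- names_[duplicated(names_)]
  if (length(dup) > 0) {
    stop("duplicate gene set name(s) in GMT: ",
         paste(unique(dup), collapse = ", "))
  }
  desc <- vapply(fields, `[[`, "", 2)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  empty <- lengths(members) == 0
  if (any(empty)) stop("GMT set '", names_[which(empty)[1]], "' has no members")
  sets <- stats::setNames(members, names_)
  new_gene_sets(sets, stats::setNames(desc, names_))
}

new_gene_sets <- function(sets, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions, class = "gene_sets")
}

#' Write gene sets in GMT format
#' @param sets A \code{gene_sets} object or named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an ontology (OBO 1.2 subset) plus gene annotations
#'
#' Parses \code{[Term]} stanzas keeping only \code{id}, \code{name},
#' \code{namespace} and \code{is_a}, then joins a two-column gene-to-term
#' annotation TSV and propagates annotations to all ancestors (the
#' true-path rule: a gene annotated to a term is implicitly annotated to
#' every ancestor of that term).
#'
#' @param path_obo Path to the OBO file.
#' @param path_annotations Path to a TSV with columns \code{gene} and
#'   \code{term} (header row).
#' @return An \code{ontology} object: list with \code{terms} (data.frame
#'   id/name/namespace), \code{parents} (named list, term -> is_a parents),
#'   \code{ancestors} (named list, term -> all ancestors including self),
#'   \code{annotations} (named list, gene -> direct terms) and
#'   \code{annotations_prop} (gene -> propagated terms).
#' @details Cyclic \code{is_a} structure is rejected naming one edge on a
#'   cycle; so is an annotation to an unknown term. Every namespace must
#'   have exactly one root (a term with no outgoing \code{is_a}).
#'   Relationship lines other than \code{is_a} are ignored with a logged
#'   count.
#' @export
read_obo_lite <- function(path_obo, path_annotations) {
  lines <- readLines(path_obo, warn = FALSE)
  in_term <- FALSE
  ids <- character(); nms <- character(); nss <- character()
  parent_list <- list()
  cur <- NULL
  n_other_rel <- 0L
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) {
      ids[[length(ids) + 1L]] <<- cur$id
      nms[[length(nms) + 1L]] <<- cur$name %||% cur$id
      nss[[length(nss) + 1L]] <<- cur$namespace %||% "default"
      parent_list[[cur$id]] <<- cur$parents
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); cur <- list(parents = character()); in_term <- TRUE; next
    }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "namespace:")) {
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, tgt)
    } else if (startsWith(ln, "relationship:")) {
      n_other_rel <- n_other_rel + 1L
    }
  }
  flush()
  if (n_other_rel > 0) {
    message("ignored ", n_other_rel, " non-is_a relationship line(s)")
  }
  if (length(ids) == 0) stop("no [Term] stanzas found in ", path_obo)
  if (anyDuplicated(ids)) {
    stop("duplicate term id: ", ids[duplicated(ids)][1])
  }
  unknown_parent <- setdiff(unlist(parent_list), ids)
  if (length(unknown_parent) > 0) {
    stop("is_a target(s) not defined as terms: ",
         paste(unknown_parent, collapse = ", "))
  }
  terms <- data.frame(id = ids, name = nms, namespace = nss,
                      stringsAsFactors = FALSE)
  parents <- lapply(stats::setNames(ids, ids),
                    function(i) parent_list[[i]] %||% character())

  ann <- utils::read.delim(path_annotations, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("gene", "term") %in% names(ann))) {
    stop("annotation file needs columns 'gene' and 'term'")
  }
  build_ontology(terms, parents,
                 annotations = split(ann$term, ann$gene))
}

#' Construct an ontology object from in-memory pieces
#'
#' Used by [read_obo_lite()] and by the synthetic ontology generator.
#' Validates acyclicity and per-namespace single roots, and propagates
#' annotations along \code{is_a} edges (true-path rule).
#'
#' @param terms data.frame with columns id, name, namespace.
#' @param parents Named list term -> character vector of is_a parents.
#' @param annotations Named list gene -> character vector of term ids
#'   (direct annotations).
#' @return An \code{ontology} object; see [read_obo_lite()].
#' @export
build_ontology <- function(terms, parents, annotations) {
  ids <- terms$id
  edges <- do.call(rbind, lapply(ids, function(i) {
    ps <- parents[[i]]
    if (length(ps) == 0) return(NULL)
    cbind(i, ps)
  }))
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(ids)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(as.matrix(data.frame(edges))))
  }
  if (!igraph::is_dag(g)) {
    # name one edge participating in a cycle for the error message
    fb <- igraph::feedback_arc_set(g)
    e <- igraph::ends(g, fb[1])
    stop("is_a graph contains a cycle (e.g. edge ", e[1], " -> ", e[2], ")")
  }
  # per-namespace root check: root = no outgoing is_a
  is_root <- lengths(parents[ids]) == 0
  for (ns in unique(terms$namespace)) {
    n_roots <- sum(is_root & terms$namespace == ns)
    if (n_roots != 1) {
      stop("namespace '", ns, "' has ", n_roots, " roots; expected exactly 1")
    }
  }
  # ancestor closure (including self), child -> parent edges = mode "out"
  anc <- lapply(stats::setNames(ids, ids), function(i) {
    igraph::subcomponent(g, i, mode = "out")$name
  })
  unknown <- setdiff(unlist(annotations), ids)
  if (length(unknown) > 0) {
    stop("annotation(s) to unknown term(s): ", paste(unknown, collapse = ", "))
  }
  annotations <- lapply(annotations, unique)
  prop <- lapply(annotations, function(ts) unique(unlist(anc[ts])))
  structure(list(terms = terms, parents = parents, ancestors = anc,
                 annotations = annotations, annotations_prop = prop,
                 graph = g),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat("Ontology:", nrow(x$terms), "terms,",
      length(unique(x$terms$namespace)), "namespace(s),",
      length(x$annotations), "annotated genes\n")
  invisible(x)
}

#' Derive gene sets from ontology terms
#'
#' One gene set per term, containing the genes annotated (after true-path
#' propagation) to the term. The usual way to supply ontology classes to
#' [run_gsea()].
#'
#' @param graph An \code{ontology} object.
#' @param min_genes Keep terms annotating at least this many genes.
#' @return A \code{gene_sets} object keyed by term id.
#' @export
ontology_gene_sets <- function(graph, min_genes = 1) {
  stopifnot(inherits(graph, "ontology"))
  genes <- names(graph$annotations_prop)
  by_term <- list()
  for (g in genes) {
    for (t in graph$annotations_prop[[g]]) {
      by_term[[t]] <- c(by_term[[t]], g)
    }
  }
  by_term <- by_term[lengths(by_term) >= min_genes]
  desc <- stats::setNames(
    graph$terms$name[match(names(by_term), graph$terms$id)], names(by_term))
  new_gene_sets(by_term, desc)
}

#' Read a bipartite interaction network (chemical-gene or virus-host)
#'
#' Edge-list TSV with columns \code{gene}, \code{partner}, \code{evidence}
#' (number of supporting evidence items) and \code{study_size} (size of the
#' largest source study reporting the edge). Duplicate (gene, partner) rows
#' are collapsed by summing evidence and taking the maximal study size.
#'
#' @param path Path to the edge TSV.
#' @param partner_kind Either \code{"chemical"} or \code{"virus_strain"}.
#' @param attribute_table Optional data.frame (or TSV path) of partner
#'   attributes: columns \code{partner}, and for chemicals \code{is_drug},
#'   \code{is_air_pollutant} (logical/0-1), for viruses \code{species}.
#'   Chemical partners absent from the table get default (FALSE) flags with
#'   a log message; virus partners without a species are an error, since
#'   strain-to-species grouping is required downstream.
#' @return A \code{bipartite_net} object: list with \code{edges}
#'   (data.frame gene/partner/evidence/study_size) and \code{partners}
#'   (data.frame partner/kind/is_drug/is_air_pollutant/species).
#' @export
read_network <- function(path, partner_kind = c("chemical", "virus_strain"),
                         attribute_table = NULL) {
  partner_kind <- match.arg(partner_kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "partner", "evidence", "study_size")
  if (!all(need %in% names(df))) {
    stop("network file needs columns: ", paste(need, collapse = ", "))
  }
  if (is.character(attribute_table)) {
    attribute_table <- utils::read.delim(attribute_table, header = TRUE,
                                         sep = "\t", stringsAsFactors = FALSE)
  }
  build_network(df, partner_kind, attribute_table)
}

#' Construct a bipartite network from an in-memory edge table
#'
#' @inheritParams read_network
#' @param edges data.frame with columns gene, partner, evidence, study_size.
#' @export
build_network <- function(edges, partner_kind = c("chemical", "virus_strain"),
                          attribute_table = NULL) {
  partner_kind <- match.arg(partner_kind)
  if (any(edges$evidence < 1)) {
    stop("evidence_count < 1 at edge row ", which(edges$evidence < 1)[1])
  }
  if (any(edges$study_size < 1)) {
    stop("study_size < 1 at edge row ", which(edges$study_size < 1)[1])
  }
  key <- paste(edges$gene, edges$partner, sep = "\r")
  ev <- tapply(edges$evidence, key, sum)
  ss <- tapply(edges$study_size, key, max)
  parts <- strsplit(names(ev), "\r", fixed = TRUE)
  dedup <- data.frame(gene = vapply(parts, `[[`, "", 1),
                      partner = vapply(parts, `[[`, "", 2),
                      evidence = as.integer(ev),
                      study_size = as.integer(ss),
                      stringsAsFactors = FALSE, row.names = NULL)
  dedup <- dedup[order(dedup$gene, dedup$partner), , drop = FALSE]
  rownames(dedup) <- NULL
  partner_ids <- sort(unique(dedup$partner))
  partners <- data.frame(partner = partner_ids, kind = partner_kind,
                         is_drug = FALSE, is_air_pollutant = FALSE,
                         species = "", stringsAsFactors = FALSE)
  if (!is.null(attribute_table)) {
    idx <- match(partners$partner, attribute_table$partner)
    known <- !is.na(idx)
    if ("is_drug" %in% names(attribute_table)) {
      partners$is_drug[known] <-
        as.logical(attribute_table$is_drug[idx[known]])
    }
    if ("is_air_pollutant" %in% names(attribute_table)) {
      partners$is_air_pollutant[known] <-
        as.logical(attribute_table$is_air_pollutant[idx[known]])
    }
    if ("species" %in% names(attribute_table)) {
      sp <- attribute_table$species[idx[known]]
      sp[is.na(sp)] <- ""
      partners$species[known] <- sp
    }
    if (any(!known)) {
      message(sum(!known), " partner(s) without attributes; default flags used")
    }
  }
  if (partner_kind == "virus_strain" &&
      any(!nzchar(partners$species))) {
    stop("virus partner(s) without species: ",
         paste(partners$partner[!nzchar(partners$species)], collapse = ", "))
  }
  if (partner_kind == "chemical" && any(nzchar(partners$species))) {
    stop("chemical partner(s) carry a virus species")
  }
  structure(list(edges = dedup, partners = partners, kind = partner_kind),
            class = "bipartite_net")
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat("Bipartite network (", x$kind, "): ", nrow(x$edges), " edges, ",
      length(unique(x$edges$gene)), " genes, ",
      nrow(x$partners), " partners\n", sep = "")
  invisible(x)
}

#' Default tumor-type to tissue map
#'
#' Ships a mapping covering 21 tumor types of the pan-cancer mutation
#' significance cohort: each cancer type's tissue of origin, a fine-to-group
#' tissue grouping (e.g. the three skin cancer labels join into "skin";
#' hematological malignancies join into "hematopoietic"), a symmetric
#' tissue adjacency list used when matching expression maxima to pathology
#' sites, and a solid/non-solid flag per cancer type. All components are
#' user-overridable via [tissue_map()].
#'
#' @return A \code{tissue_map} object.
#' @export
default_tissue_map <- function() {
  cancer_to_tissue <- c(
    BLCA = "bladder", BRCA = "breast", CRC = "colon", ESO = "esophagus",
    GBM = "brain", HNSC = "head_neck", KIRC = "kidney", LAML = "blood",
    LUAD = "lung", LUSC = "lung", MED = "brain", MEL = "melanoma",
    MM = "blood", NB = "adrenal", OV = "ovary", PRAD = "prostate",
    RHAB = "muscle", THCA = "thyroid", UCEC = "endometrium",
    DLBCL = "blood", CLL = "blood")
  grouping <- c(
    melanoma = "skin", skin_basal_cell = "skin", skin_squamous_cell = "skin",
    blood = "hematopoietic", lymph = "hematopoietic",
    endometrium = "uterus", myometrium = "uterus", cervix = "uterus",
    colon = "colon", ileum = "colon")
  adjacency <- data.frame(
    a = c("endometrium", "colon", "ovary", "lung", "kidney"),
    b = c("myometrium", "ileum", "endometrium", "bronchus", "adrenal"),
    stringsAsFactors = FALSE)
  solid <- !names(cancer_to_tissue) %in% c("LAML", "MM", "DLBCL", "CLL")
  names(solid) <- names(cancer_to_tissue)
  tissue_map(cancer_to_tissue, grouping, adjacency, solid)
}

#' Construct a tissue map
#'
#' @param cancer_to_tissue Named character: cancer type -> tissue label.
#' @param grouping Named character: fine tissue label -> group label.
#'   Labels absent from the map pass through unchanged.
#' @param adjacency data.frame with columns \code{a}, \code{b}; stored
#'   symmetric and irreflexive.
#' @param solid Named logical: cancer type -> is a solid tumor.
#' @return A \code{tissue_map} object.
#' @export
tissue_map <- function(cancer_to_tissue, grouping = character(),
                       adjacency = data.frame(a = character(),
                                              b = character()),
                       solid = NULL) {
  if (any(adjacency$a == adjacency$b)) {
    stop("tissue adjacency must be irreflexive")
  }
  adj <- unique(rbind(adjacency,
                      data.frame(a = adjacency$b, b = adjacency$a)))
  rownames(adj) <- NULL
  if (is.null(solid)) {
    solid <- stats::setNames(rep(TRUE, length(cancer_to_tissue)),
                             names(cancer_to_tissue))
  }
  structure(list(cancer_to_tissue = cancer_to_tissue, grouping = grouping,
                 adjacency = adj, solid = solid),
            class = "tissue_map")
}

#' Apply tissue grouping to labels
#' @param tmap A \code{tissue_map}.
#' @param tissues Character vector of fine tissue labels.
#' @return Group labels (labels without a grouping entry pass through).
#' @export
group_tissues <- function(tmap, tissues) {
  out <- tmap$grouping[tissues]
  out[is.na(out)] <- tissues[is.na(out)]
  unname(out)
}

adjacent_tissues <- function(tmap, tissue) {
  unique(tmap$adjacency$b[tmap$adjacency$a == tissue])
}

#' Read a per-gene publication count table
#'
#' Two-column TSV \code{gene}, \code{n_studies}; a proxy for how heavily a
#' gene has been studied, used to control study bias.
#'
#' @param path Path to the TSV.
#' @return Named integer vector.
#' @export
read_study_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "n_studies") %in% names(df))) {
    stop("study count file needs columns 'gene' and 'n_studies'")
  }
  n <- as.integer(df$n_studies)
  if (any(is.na(n) | n < 0)) stop("study counts must be non-negative integers")
  stats::setNames(n, df$gene)
}

#' Read an expression matrix (genes x tissues)
#'
#' TSV with a \code{gene} column and one abundance column per tissue.
#' Negative abundances and duplicate tissue labels are rejected.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with gene row names and tissue column names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop("expression file needs a 'gene' column")
  if (anyDuplicated(setdiff(names(df), "gene"))) {
    stop("duplicate tissue labels in expression matrix")
  }
  m <- as.matrix(df[setdiff(names(df), "gene")])
  mode(m) <- "numeric"
  rownames(m) <- df$gene
  if (any(is.na(m))) stop("non-numeric abundance in expression matrix")
  if (any(m < 0)) stop("negative abundance in expression matrix")
  m
}

#' Merge a scored core set with literature cancer-gene catalogs
#'
#' Builds the extended cancer gene catalog: the union of the
#' specificity-scored core genes and one or more census-style tables carrying
#' per-gene tissue and mutation-origin labels. Core genes contribute the
#' tissues of the tumor types in which they are significantly mutated
#' (mapped through the tissue map); census rows contribute their curated
#' tissue labels. All tissue labels pass through the fine-to-group map, so
#' clinically diverse cancer types from the same tissue collapse to one
#' label. When sources disagree on germline vs somatic origin the gene is
#' labeled \code{both}.
#'
#' @param core A specificity table from [rank_genes()], or NULL.
#' @param census_tables List of data.frames with columns \code{gene},
#'   \code{tissue} (one row per gene-tissue pair), \code{origin}
#'   (germline/somatic/both) and optionally \code{hallmark}
#'   (oncogene/tumor_suppressor/dna_repair/other).
#' @param tmap A \code{tissue_map}.
#' @return A \code{cancer_catalog}: data.frame with columns \code{gene},
#'   \code{tissues} (list column of group labels), \code{origin},
#'   \code{hallmark}, \code{repair_pathway} (initially "none"; see
#'   [assign_repair_pathways()]).
#' @details Genes with no tissue in any source are retained with empty
#'   tissues and logged; tissue-based analyses skip them.
#' @export
build_ext_catalog <- function(core = NULL, census_tables = list(), tmap) {
  rows <- list()   # gene -> list(tissues, origins, hallmark)
  add <- function(gene, tissues, origin = NA_character_,
                  hallmark = NA_character_) {
    r <- rows[[gene]] %||% list(tissues = character(), origins = character(),
                                hallmark = character())
    r$tissues <- union(r$tissues, tissues)
    if (!is.na(origin)) r$origins <- union(r$origins, origin)
    if (!is.na(hallmark)) r$hallmark <- union(r$hallmark, hallmark)
    rows[[gene]] <<- r
  }
  if (!is.null(core)) {
    sig_types <- core$sig_types
    for (i in seq_len(nrow(core))) {
      tiss <- group_tissues(tmap, unname(
        tmap$cancer_to_tissue[sig_types[[i]]]))
      add(core$gene[i], tiss[!is.na(tiss)], origin = "somatic")
    }
  }
  for (tab in census_tables) {
    if (!all(c("gene", "tissue", "origin") %in% names(tab))) {
      stop("census table needs columns gene, tissue, origin")
    }
    for (i in seq_len(nrow(tab))) {
      tiss <- tab$tissue[i]
      tiss <- if (is.na(tiss) || !nzchar(tiss)) character() else
        group_tissues(tmap, tiss)
      hm <- if ("hallmark" %in% names(tab)) tab$hallmark[i] else NA_character_
      add(tab$gene[i], tiss, origin = tab$origin[i], hallmark = hm)
    }
  }
  genes <- sort(names(rows))
  origin <- vapply(genes, function(g) {
    o <- setdiff(rows[[g]]$origins, NA)
    if (length(o) == 0) return(NA_character_)
    if ("both" %in% o || all(c("germline", "somatic") %in% o)) return("both")
    o[1]
  }, "")
  hallmark <- vapply(genes, function(g) {
    h <- rows[[g]]$hallmark
    h <- h[!is.na(h) & nzchar(h)]
    if (length(h) == 0) "other" else h[1]
  }, "")
  tissues <- lapply(genes, function(g) sort(rows[[g]]$tissues))
  n_empty <- sum(lengths(tissues) == 0)
  if (n_empty > 0) {
    message(n_empty, " gene(s) with no tissue label; ",
            "excluded from tissue analyses")
  }
  out <- data.frame(gene = genes, origin = origin, hallmark = hallmark,
                    repair_pathway = "none", stringsAsFactors = FALSE,
                    row.names = NULL)
  out$tissues <- tissues
  class(out) <- c("cancer_catalog", "data.frame")
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
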