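# GO annotation handling: OBO parsing, ancestor closure, family-level
# annotation with the >= 30%-of-members rule, and Fisher's exact
# over/under-representation tests between gene sets.

#' Load an ontology from an OBO file
#'
#' Parses `[Term]` stanzas (id, name, `is_a` and `relationship: part_of`
#' parents, obsolescence). Obsolete terms are dropped with a warning; a
#' cyclic parent graph is a format error.
#'
#' @param path Path to a plain-text OBO file.
#' @return List of class `ontology`: `terms` (tibble `id`, `name`), `graph`
#'   (igraph DAG, edges child -> parent), `ancestors` (named list of
#'   ancestor id vectors, closed and excluding the term itself).
#' @export
load_ontology <- function(path) {
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0) abort_("no [Term] stanzas found")
  bounds <- c(term_starts, length(lines) + 1L)
  terms <- list(); edges <- list(); obsolete <- character(0)
  for (s in seq_along(term_starts)) {
    block <- lines[term_starts[s]:(bounds[s + 1] - 1L)]
    get1 <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      if (length(v) == 0) return(NA_character_)
      sub("\\s*!.*$", "", sub(paste0("^", key, ": "), "", v[1]))
    }
    id <- get1("id")
    if (is.na(id)) next
    if (identical(get1("is_obsolete"), "true")) {
      obsolete <- c(obsolete, id)
      next
    }
    isa <- block[startsWith(block, "is_a: ")]
    isa <- sub("\\s*!.*$", "", sub("^is_a: ", "", isa))
    po <- block[startsWith(block, "relationship: part_of ")]
    po <- sub("\\s*!.*$", "", sub("^relationship: part_of ", "", po))
    parents <- trimws(c(isa, po))
    terms[[id]] <- get1("name")
    if (length(parents) > 0) {
      edges[[id]] <- tibble(from = id, to = parents)
    }
  }
  if (length(obsolete) > 0) {
    rlang::warn(sprintf("dropped %d obsolete term(s)", length(obsolete)))
  }
  term_tbl <- tibble(id = names(terms),
                     name = unname(unlist(terms, use.names = FALSE)))
  edge_tbl <- bind_rows(edges)
  edge_tbl <- filter(edge_tbl, .data$to %in% term_tbl$id)
  g <- igraph::graph_from_data_frame(edge_tbl, directed = TRUE,
                                     vertices = term_tbl$id)
  if (!igraph::is_dag(g)) {
    abort_("ontology graph contains a cycle", class = "duplidate_format_error")
  }
  anc <- lapply(term_tbl$id, function(t) {
    setdiff(names(igraph::subcomponent(g, t, mode = "out")), t)
  })
  names(anc) <- term_tbl$id
  structure(list(terms = term_tbl, graph = g, ancestors = anc,
                 obsolete = obsolete),
            class = "ontology")
}

#' Ancestors of an ontology term
#'
#' @param ontology An `ontology` from [load_ontology()].
#' @param term Term id.
#' @return Character vector of ancestor ids (excluding the term).
#' @export
term_ancestors <- function(ontology, term) {
  ontology$ancestors[[term]] %||% abort_(sprintf("unknown term %s", term))
}

#' Annotate genes with ancestor closure
#'
#' Expands a gene-to-term table so that a gene annotated to a term is also
#' annotated to every ancestor of that term. Terms absent from the ontology
#' (including obsolete ones) are skipped with a warning. The operation is
#' idempotent.
#'
#' @param gene_terms Tibble with columns `gene`, `term` (one pair per row;
#'   extra columns, e.g. GAF evidence codes, are ignored).
#' @param ontology An `ontology`.
#' @return Tibble `gene`, `term`, deduplicated and closed.
#' @export
annotate_genes <- function(gene_terms, ontology) {
  known <- gene_terms$term %in% ontology$terms$id
  if (any(!known)) {
    rlang::warn(sprintf("skipped %d annotation(s) to unknown or obsolete terms",
                        sum(!known)))
    gene_terms <- gene_terms[known, , drop = FALSE]
  }
  if (nrow(gene_terms) == 0) {
    return(tibble(gene = character(), term = character()))
  }
  closed <- purrr::map2_dfr(gene_terms$gene, gene_terms$term, function(g, t) {
    tibble(gene = g, term = c(t, ontology$ancestors[[t]]))
  })
  distinct(closed, .data$gene, .data$term)
}

#' Annotate a gene family by member vote
#'
#' A family is annotated with a term when at least `threshold` of its
#' members carry that term (after ancestor closure); the boundary is
#' inclusive.
#'
#' @param members Character vector of the family's gene ids.
#' @param annotations Closed gene-term tibble from [annotate_genes()].
#' @param threshold Minimum annotated-member proportion (default 0.30).
#' @return Character vector of assigned term ids.
#' @export
annotate_family <- function(members, annotations, threshold = 0.30) {
  sub <- filter(annotations, .data$gene %in% members)
  if (nrow(sub) == 0) return(character(0))
  counts <- sub |>
    distinct(.data$gene, .data$term) |>
    dplyr::count(.data$term)
  counts$term[counts$n / length(members) >= threshold]
}

#' Annotate every family
#'
#' @param clustering Result of [cluster_families()].
#' @param annotations Closed gene-term tibble.
#' @param threshold Family annotation threshold (default 0.30).
#' @return Tibble `family_id`, `term`.
#' @export
annotate_all_families <- function(clustering, annotations,
                                  threshold = 0.30) {
  fams <- split(clustering$membership$gene,
                clustering$membership$family_id)
  purrr::imap_dfr(fams, function(members, fid) {
    terms <- annotate_family(members, annotations, threshold)
    if (length(terms) == 0) return(NULL)
    tibble(family_id = fid, term = terms)
  })
}

#' Fisher's exact enrichment between two annotated sets
#'
#' For each term annotated in at least one of the two sets, builds the 2x2
#' table (in-set annotated / not, out-set annotated / not) and applies the
#' two-sided Fisher exact test. Direction is the sign of the log odds
#' ratio. Units are whatever the ids denote (genes, or families each
#' counting once).
#'
#' @param test_set,background_set Character vectors of unit ids; the
#'   background is the comparison group (disjoint from the test set).
#' @param annotations Tibble with columns naming the unit (`gene` or
#'   `family_id`, autodetected) and `term`.
#' @param alpha Significance level on the raw p-value (default 0.01).
#' @param adjust If `TRUE`, add a Benjamini-Hochberg adjusted p-value
#'   column.
#' @return Tibble `term`, `a`, `b`, `c`, `d`, `odds_direction`, `p_value`,
#'   `significant`, sorted by p-value.
#' @export
fisher_enrichment <- function(test_set, background_set, annotations,
                              alpha = 0.01, adjust = FALSE) {
  unit_col <- intersect(c("gene", "family_id", "id"), names(annotations))[1]
  if (is.na(unit_col)) abort_("annotations need a gene/family_id column")
  ann <- annotations |>
    rename(unit = dplyr::all_of(unit_col)) |>
    distinct(.data$unit, .data$term)
  in_test <- filter(ann, .data$unit %in% test_set)
  in_bg <- filter(ann, .data$unit %in% background_set)
  terms <- union(in_test$term, in_bg$term)
  if (length(terms) == 0) {
    return(tibble(term = character(), a = integer(), b = integer(),
                  c = integer(), d = integer(),
                  odds_direction = character(), p_value = numeric(),
                  significant = logical()))
  }
  n_test <- length(test_set)
  n_bg <- length(background_set)
  res <- purrr::map_dfr(terms, function(t) {
    a <- sum(in_test$term == t)
    c_ <- sum(in_bg$term == t)
    b <- n_test - a
    d <- n_bg - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                     alternative = "two.sided")$p.value
    dir <- if (a / max(n_test, 1) >= c_ / max(n_bg, 1)) "over" else "under"
    tibble(term = t, a = a, b = b, c = c_, d = d,
           odds_direction = dir, p_value = p)
  })
  res <- mutate(res, significant = .data$p_value < alpha)
  if (adjust) {
    res <- mutate(res, p_adjusted = p.adjust(.data$p_value, "BH"))
  }
  arrange(res, .data$p_value)
}
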