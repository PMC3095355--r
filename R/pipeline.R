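# End-to-end orchestration: a resolved configuration, staged execution over
# plain TSV/JSON intermediates, and summary reporting.

#' Pipeline configuration
#'
#' Collects every filter threshold with its standard default: minimum coding
#' length 300 nt, paralog call at >= 100 aligned aa and > 30% identity, Ks
#' eligibility at >= 60% identity, Ks saturation cutoff 2.0, young-paralog
#' cutoff 0.4, family annotation threshold 0.30, enrichment alpha 0.01,
#' co-expression alpha 0.05, >= 3 ESTs per gene, 10,000 null pairs, 5
#' likelihood restarts, up to 3 normal mixture components.
#'
#' @param seed Master seed.
#' @param ... Named overrides of any default.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    min_cds_nt = 300, min_aln_aa = 100, min_pct_id = 30, ks_pct_id = 60,
    ks_max = 2.0, young_cutoff = 0.4, family_annot_frac = 0.30,
    enrich_alpha = 0.01, coexpr_alpha = 0.05, min_ests = 3,
    n_null_pairs = 10000, n_restarts = 5, max_normals = 3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort_(sprintf("unknown config field(s): %s",
                   paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the duplication-dating pipeline on a dataset
#'
#' Executes pairs -> Ks -> zero-Ks dedup -> families -> node dating ->
#' young subset -> mixture selection -> expression divergence on an
#' in-memory dataset (e.g. from [simulate_dataset()]), returning all stage
#' outputs plus a run report of per-stage record counts.
#'
#' @param dataset List with `genes` (tibble `id`, `cds`, `protein`,
#'   optionally with minimum-length filtering still to apply) and
#'   optionally `expression` (as produced by [simulate_expression()]) and a
#'   `config` element; a `sim_dataset` works directly.
#' @param config A [run_config()].
#' @param hits Optional precomputed hit table (see [load_hits()]); computed
#'   with [align_all_vs_all()] when absent.
#' @param tissue_map Optional tibble `library`, `tissue`.
#' @param annotations Optional gene-to-term tibble (`gene`, `term`); with
#'   `ontology`, enables the family-annotation and enrichment stage.
#' @param ontology Optional `ontology` from [load_ontology()].
#' @return List of class `run_result` with stage outputs (`pairs`,
#'   `singlets`, `ks`, `clustering`, `nodes`, `young`, `mixture_fit`,
#'   `go`, `expression_divergence`) and `report` (named list of counts).
#' @export
run_pipeline <- function(dataset, config = run_config(), hits = NULL,
                         tissue_map = NULL, annotations = NULL,
                         ontology = NULL) {
  genes <- dataset$genes
  if (!"protein" %in% names(genes)) genes$protein <- translate_cds(genes$cds)
  genes <- filter(genes, nchar(.data$cds) >= config$min_cds_nt)
  report <- list(genes_in = nrow(genes))

  if (is.null(hits)) hits <- align_all_vs_all(genes)
  called <- call_paralogs(hits, gene_ids = genes$id,
                          min_aln_aa = config$min_aln_aa,
                          min_pct_id = config$min_pct_id,
                          ks_pct_id = config$ks_pct_id)
  report$pairs_called <- nrow(called$pairs)
  report$singlets <- length(called$singlets)

  ks_raw <- estimate_ks(called$pairs, genes,
                        n_restarts = config$n_restarts, seed = config$seed)
  ks_kept <- filter_ks(ks_raw, ks_max = config$ks_max)
  dedup <- dedupe_zero_ks(ks_kept)
  ks_final <- filter(dedup$kept, .data$ks > 0)
  report$ks_estimated <- nrow(ks_raw)
  report$ks_retained <- nrow(ks_final)
  report$zero_ks_removed <- length(dedup$removed_genes)

  pair_universe <- filter(called$pairs,
                          !.data$gene_a %in% dedup$removed_genes,
                          !.data$gene_b %in% dedup$removed_genes)
  clustering <- cluster_families(pair_universe)
  report$families <- nrow(clustering$families)
  report$genes_in_families <- nrow(clustering$membership)

  nodes <- date_all_families(clustering, ks_final)
  report$duplication_nodes <- nrow(nodes)
  young <- young_subset(ks_final, nodes, cutoff = config$young_cutoff)
  report$young_duplications <- sum(young$d_young$d_young)

  mixture_fit <- NULL
  ages <- nodes$age_ks[nodes$age_ks > 0 & nodes$age_ks <= config$ks_max]
  if (length(ages) >= 50) {
    mixture_fit <- select_model(ages, max_normals = config$max_normals,
                                seed = config$seed)
    report$mixture_normals <- mixture_fit$n_normals
  }

  go <- NULL
  if (!is.null(annotations) && !is.null(ontology)) {
    closed <- annotate_genes(annotations, ontology)
    fam_terms <- annotate_all_families(clustering, closed,
                                       threshold = config$family_annot_frac)
    if (nrow(fam_terms) == 0) {
      fam_terms <- tibble(family_id = character(), term = character())
    }
    combined <- bind_rows(
      rename(fam_terms, gene = "family_id"),
      filter(closed, .data$gene %in% called$singlets)
    )
    enrichment <- fisher_enrichment(
      unique(fam_terms$family_id), called$singlets, combined,
      alpha = config$enrich_alpha
    )
    go <- list(gene_terms = closed, family_terms = fam_terms,
               enrichment = enrichment)
    report$families_annotated <- dplyr::n_distinct(fam_terms$family_id)
    report$terms_enriched <- sum(enrichment$significant)
  }

  expression_divergence <- NULL
  if (!is.null(dataset$expression)) {
    prof <- expression_profiles(dataset$expression$counts,
                                min_total = config$min_ests)
    pr <- pearson_divergence(ks_final, prof)
    rstar <- null_threshold(prof, exclude_pairs = pair_universe,
                            n_random_pairs = config$n_null_pairs,
                            alpha = config$coexpr_alpha, seed = config$seed)
    fr <- divergent_fractions(mutate(pr, ks = .data$ks), rstar,
                              ks_cutoff = config$young_cutoff)
    expression_divergence <- list(pairs = pr, r_star = as.numeric(rstar),
                                  fractions = fr)
    report$r_star <- as.numeric(rstar)
    report$divergent_overall <- fr$overall
  }

  structure(
    list(pairs = called$pairs, singlets = called$singlets, ks = ks_final,
         clustering = clustering, nodes = nodes, young = young,
         mixture_fit = mixture_fit, go = go,
         expression_divergence = expression_divergence,
         report = report, config = config),
    class = "run_result"
  )
}

#' Summary statistics block for a run
#'
#' Produces the headline statistics a duplication study reports: total
#' protein-coding genes, genes in families and their share, number of
#' families and mean family size (1 decimal), singlet count and share, the
#' selected mixture parameters, and expression-divergence fractions.
#' Supplying printed counts directly also works, which makes the arithmetic
#' reusable for published tables.
#'
#' @param total_genes Number of protein-coding genes.
#' @param genes_in_families Genes with at least one paralog.
#' @param n_families Number of families.
#' @param singlets Single-copy gene count.
#' @param annotated_singlets Optional count of GO-annotated singlets.
#' @return Tibble with the derived statistics: `mean_family_size` (1
#'   decimal), `pct_in_families` and `pct_singlets` (rounded percent),
#'   `singlet_annotation_rate` (rounded percent, `NA` if not supplied).
#' @export
family_statistics <- function(total_genes, genes_in_families, n_families,
                              singlets, annotated_singlets = NULL) {
  tibble(
    total_genes = total_genes,
    genes_in_families = genes_in_families,
    n_families = n_families,
    singlets = singlets,
    mean_family_size = round(genes_in_families / n_families, 1),
    pct_in_families = round(100 * genes_in_families / total_genes, 1),
    pct_singlets = round(100 * singlets / total_genes, 1),
    singlet_annotation_rate = if (is.null(annotated_singlets)) NA_real_ else
      round(100 * annotated_singlets / singlets, 1)
  )
}

#' Summarize a pipeline run
#'
#' @param result A `run_result` from [run_pipeline()].
#' @return List with `text` (printable lines) and `stats` (JSON-ready list).
#' @export
summarize_run <- function(result) {
  rep <- result$report
  if (rep$genes_in == 0) {
    return(list(text = "no data: empty gene set", stats = list(empty = TRUE)))
  }
  fs <- family_statistics(rep$genes_in, rep$genes_in_families,
                          max(rep$families, 1L), rep$singlets)
  lines <- c(
    sprintf("Protein-coding genes: %d", rep$genes_in),
    sprintf("Genes in families: %d (~%.0f%%)", rep$genes_in_families,
            fs$pct_in_families),
    sprintf("Gene families: %d (mean size %.1f)", rep$families,
            fs$mean_family_size),
    sprintf("Single-copy genes: %d (~%.0f%%)", rep$singlets,
            fs$pct_singlets),
    sprintf("Duplication nodes dated: %d (young: %d)",
            rep$duplication_nodes, rep$young_duplications)
  )
  if (!is.null(result$mixture_fit)) {
    f <- result$mixture_fit
    lines <- c(lines, sprintf(
      "Age mixture: death rate %.3f + %d normal(s)%s",
      f$death_rate, f$n_normals,
      if (f$n_normals > 0) {
        paste0(" at Ks ", paste(sprintf("%.3f", f$components$mean),
                                collapse = ", "))
      } else ""
    ))
  }
  if (!is.null(result$expression_divergence)) {
    fr <- result$expression_divergence$fractions
    lines <- c(lines, sprintf(
      "Expression divergence: r* = %.2f; divergent overall %.0f%% (young %.0f%%, old %.0f%%)",
      result$expression_divergence$r_star, 100 * fr$overall,
      100 * fr$young, 100 * fr$old))
  }
  stats <- c(as.list(fs), rep[setdiff(names(rep), names(fs))])
  list(text = lines, stats = stats)
}

#' Write a machine-readable run report
#'
#' Serializes the per-stage counts and summary statistics of a run to
#' JSON.
#'
#' @param result A `run_result`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_run_report <- function(result, path) {
  payload <- list(stats = summarize_run(result)$stats,
                  config = unclass(result$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.run_result <- function(x, ...) {
  cat(paste(summarize_run(x)$text, collapse = "\n"), "\n")
  invisible(x)
}
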