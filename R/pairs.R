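# Paralog identification from protein similarity: BLAST-tabular parsing,
# a built-in local aligner for synthetic datasets, the length/identity
# selection filters, and Ks = 0 redundancy cleanup.

blast_cols <- c("query", "subject", "pct_identity", "aln_length",
                "mismatches", "gap_opens", "qstart", "qend", "sstart",
                "send", "evalue", "bitscore")

#' Load an all-vs-all protein similarity hit table
#'
#' Parses 12-column BLAST-tabular (`-outfmt 6`) rows, removes self-hits, and
#' collapses reciprocal duplicates keeping the hit with the lowest e-value
#' (ties broken by bitscore). Coordinates are 1-based inclusive.
#'
#' @param path Path to a tab-separated hit file (no header; `#` comments
#'   allowed).
#' @return Tibble of hits with canonical unordered gene pairs
#'   (`gene_a < gene_b` lexicographically).
#' @export
load_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  pct_identity = numeric(), aln_length = integer(),
                  evalue = numeric(), bitscore = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0) {
    abort_(sprintf("malformed hit row at line %d: expected 12 tab-separated columns, found %d",
                   bad[1], lengths(fields)[bad[1]]), class = "duplidate_parse_error")
  }
  mat <- do.call(rbind, fields)
  colnames(mat) <- blast_cols
  num <- suppressWarnings(apply(mat[, 3:12, drop = FALSE], 2, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1, dimnames = list(NULL, blast_cols[3:12]))
  bad <- which(apply(num, 1, anyNA))
  if (length(bad) > 0) {
    abort_(sprintf("malformed hit row at line %d: non-numeric value in numeric column",
                   bad[1]), class = "duplidate_parse_error")
  }
  hits <- tibble(
    query = mat[, "query"], subject = mat[, "subject"],
    pct_identity = num[, "pct_identity"],
    aln_length = as.integer(num[, "aln_length"]),
    evalue = num[, "evalue"], bitscore = num[, "bitscore"]
  )
  hits |>
    filter(.data$query != .data$subject) |>
    mutate(gene_a = pmin(.data$query, .data$subject),
           gene_b = pmax(.data$query, .data$subject)) |>
    arrange(.data$gene_a, .data$gene_b, .data$evalue, dplyr::desc(.data$bitscore)) |>
    distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
    select("gene_a", "gene_b", "pct_identity", "aln_length", "evalue",
           "bitscore")
}

#' All-vs-all local protein alignment
#'
#' Built-in Smith-Waterman-style search so that small or synthetic datasets
#' need no external similarity tool. Each unordered protein pair is aligned
#' locally (BLOSUM62, affine gaps) and converted to the same hit-record shape
#' as [load_hits()]; the e-value column is a Karlin-Altschul-style surrogate
#' derived from the alignment score.
#'
#' @param genes Tibble with columns `id` and `protein`.
#' @param gap_opening,gap_extension Affine gap penalties (positive costs;
#'   the BLASTP defaults).
#' @param evalue_max Surrogate e-value cutoff above which a pair is not
#'   reported (default 1e-10, the conventional significance cutoff for
#'   protein searches).
#' @return Tibble of hits (canonical unordered pairs). Percent identity is
#'   computed over aligned columns excluding gap columns; `aln_length`
#'   includes gap columns (BLAST convention).
#' @export
align_all_vs_all <- function(genes, gap_opening = 11, gap_extension = 1,
                             evalue_max = 1e-10) {
  stopifnot(all(c("id", "protein") %in% names(genes)))
  prot <- Biostrings::AAStringSet(setNames(genes$protein, genes$id))
  n <- length(prot)
  res <- list()
  k <- 0L
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  for (i in seq_len(n - 1)) {
    alns <- Biostrings::pairwiseAlignment(
      prot[(i + 1):n], prot[[i]], type = "local",
      substitutionMatrix = mat,
      gapOpening = gap_opening, gapExtension = gap_extension
    )
    score <- Biostrings::score(alns)
    # Karlin-Altschul surrogate: bits = (lambda*S - ln K)/ln 2 with the
    # ungapped BLOSUM62 constants, E = m*n*2^-bits
    bits <- (0.267 * score - log(0.041)) / log(2)
    m_len <- nchar(genes$protein[i])
    n_len <- nchar(genes$protein[(i + 1):n])
    evalue <- m_len * n_len * 2^(-bits)
    keep <- which(evalue <= evalue_max)
    if (length(keep) == 0) next
    for (w in keep) {
      k <- k + 1L
      a <- alns[w]
      width <- Biostrings::nchar(a)
      pid2 <- Biostrings::pid(a, type = "PID2")
      res[[k]] <- tibble(
        query = genes$id[i], subject = genes$id[i + w],
        pct_identity = pid2, aln_length = as.integer(width),
        evalue = evalue[w], bitscore = bits[w]
      )
    }
  }
  if (k == 0L) {
    return(tibble(gene_a = character(), gene_b = character(),
                  pct_identity = numeric(), aln_length = integer(),
                  evalue = numeric(), bitscore = numeric()))
  }
  bind_rows(res) |>
    mutate(gene_a = pmin(.data$query, .data$subject),
           gene_b = pmax(.data$query, .data$subject)) |>
    arrange(.data$gene_a, .data$gene_b, .data$evalue) |>
    distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
    select("gene_a", "gene_b", "pct_identity", "aln_length", "evalue",
           "bitscore")
}

#' Call paralogous pairs from similarity hits
#'
#' Applies the paralog selection filters: a pair is paralogous when its best
#' hit aligns over at least `min_aln_aa` amino acids with identity strictly
#' above `min_pct_id`; it is eligible for Ks estimation when identity is at
#' least `ks_pct_id`. Genes with no surviving pair are reported as
#' single-copy (singlets).
#'
#' @param hits Hit tibble from [load_hits()] or [align_all_vs_all()].
#' @param gene_ids Character vector of all genes in the dataset (the universe
#'   from which singlets are determined); defaults to genes present in
#'   `hits`.
#' @param min_aln_aa Minimum aligned length in amino acids (default 100).
#' @param min_pct_id Identity threshold, strict (default 30; pairs must
#'   exceed it).
#' @param ks_pct_id Identity threshold for Ks eligibility, inclusive
#'   (default 60).
#' @param blacklist Optional character vector of gene ids (e.g.
#'   transposon-like genes) removed before pairing.
#' @return List with `pairs` (tibble with `ks_eligible` flag) and `singlets`
#'   (character vector).
#' @export
call_paralogs <- function(hits, gene_ids = NULL, min_aln_aa = 100,
                          min_pct_id = 30, ks_pct_id = 60,
                          blacklist = NULL) {
  gene_ids <- gene_ids %||% sort(unique(c(hits$gene_a, hits$gene_b)))
  if (!is.null(blacklist)) {
    gene_ids <- setdiff(gene_ids, blacklist)
    hits <- filter(hits, !.data$gene_a %in% blacklist,
                   !.data$gene_b %in% blacklist)
  }
  pairs <- hits |>
    filter(.data$aln_length >= min_aln_aa,
           .data$pct_identity > min_pct_id) |>
    mutate(ks_eligible = .data$pct_identity >= ks_pct_id)
  in_pairs <- unique(c(pairs$gene_a, pairs$gene_b))
  list(
    pairs = pairs,
    singlets = sort(setdiff(gene_ids, in_pairs))
  )
}

#' Remove redundant genes connected by Ks = 0 pairs
#'
#' Paralog pairs with no synonymous substitutions are most likely multiple
#' entries of one gene (e.g. splice variants). For each connected component
#' of Ks = 0 edges, exactly one representative is retained (the
#' lexicographically smallest id); every pair touching a removed gene is
#' dropped.
#'
#' @param ks_tbl Tibble with columns `gene_a`, `gene_b`, `ks`.
#' @return List with `kept` (the reduced Ks table), `removed_genes`, and
#'   `representatives` (one per zero-Ks component).
#' @export
dedupe_zero_ks <- function(ks_tbl) {
  zero <- filter(ks_tbl, .data$ks == 0)
  if (nrow(zero) == 0) {
    return(list(kept = ks_tbl, removed_genes = character(),
                representatives = character()))
  }
  g <- igraph::graph_from_data_frame(zero[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  reps <- vapply(members, function(m) min(m), "")
  removed <- setdiff(unlist(members), reps)
  kept <- filter(ks_tbl, !.data$gene_a %in% removed,
                 !.data$gene_b %in% removed)
  list(kept = kept, removed_genes = sort(removed),
       representatives = sort(unname(reps)))
}
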