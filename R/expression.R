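# Digital expression divergence between paralogs: per-library EST frequency
# profiles, Pearson correlation, a resampled null threshold for calling
# co-regulation, and per-tissue-class Fisher tests for expression shifts.

#' Build expression profiles from an EST count matrix
#'
#' Normalizes counts per library to frequencies per 10,000 library ESTs and
#' applies the minimum-representation filter: only genes with at least
#' `min_total` ESTs over the whole dataset are retained for correlation
#' analysis.
#'
#' @param counts Tibble with a `gene` column and one numeric column per
#'   library.
#' @param min_total Minimum total EST count per gene (default 3).
#' @return List of class `expression_profiles`: `freq` (matrix genes x
#'   libraries of frequencies), `counts` (matrix of raw counts, all genes),
#'   `libraries`, `kept` (gene ids passing the filter).
#' @export
expression_profiles <- function(counts, min_total = 3) {
  stopifnot("gene" %in% names(counts))
  mat <- as.matrix(counts[, setdiff(names(counts), "gene"), drop = FALSE])
  rownames(mat) <- counts$gene
  if (any(mat < 0)) abort_("EST counts must be non-negative")
  lib_tot <- colSums(mat)
  freq <- sweep(mat, 2, pmax(lib_tot, 1), "/") * 1e4
  kept <- rownames(mat)[rowSums(mat) >= min_total]
  structure(
    list(freq = freq[kept, , drop = FALSE], counts = mat,
         libraries = colnames(mat), kept = kept),
    class = "expression_profiles"
  )
}

#' Pearson expression correlation for paralog pairs
#'
#' Computes the Pearson correlation between the per-library frequency
#' vectors of each pair. Pairs where either gene fails the EST filter or
#' has a constant profile are flagged and excluded from the correlation
#' (`r` is `NA`).
#'
#' @param pairs Tibble with `gene_a`, `gene_b`.
#' @param profiles An `expression_profiles` object.
#' @return `pairs` with added columns `r` and `flag` (`"ok"`,
#'   `"low_count"`, or `"constant_profile"`).
#' @export
pearson_divergence <- function(pairs, profiles) {
  f <- profiles$freq
  kept <- rownames(f)
  sds <- apply(f, 1, stats::sd)
  res <- purrr::pmap_dfr(pairs[, c("gene_a", "gene_b")],
                         function(gene_a, gene_b) {
    if (!(gene_a %in% kept) || !(gene_b %in% kept)) {
      return(tibble(gene_a = gene_a, gene_b = gene_b, r = NA_real_,
                    flag = "low_count"))
    }
    if (sds[gene_a] == 0 || sds[gene_b] == 0) {
      return(tibble(gene_a = gene_a, gene_b = gene_b, r = NA_real_,
                    flag = "constant_profile"))
    }
    tibble(gene_a = gene_a, gene_b = gene_b,
           r = cor(f[gene_a, ], f[gene_b, ]), flag = "ok")
  })
  left_join(pairs, res, by = c("gene_a", "gene_b"))
}

#' Null co-regulation threshold from random gene pairs
#'
#' Samples unordered pairs of distinct, non-paralogous genes uniformly,
#' computes their expression correlation, and returns the empirical
#' `1 - alpha` quantile: the correlation below which `1 - alpha` of
#' unrelated gene pairs fall. Constant-profile pairs are excluded, matching
#' their exclusion from the observed distribution.
#'
#' @param profiles An `expression_profiles` object.
#' @param exclude_pairs Optional tibble `gene_a`, `gene_b` of known paralog
#'   pairs to exclude from the null.
#' @param n_random_pairs Number of random pairs (default 10000).
#' @param alpha Tail probability (default 0.05); `alpha = 0` returns the
#'   null maximum.
#' @param seed Integer seed (recorded in the output attributes).
#' @return The threshold `r_star` (numeric scalar) with attributes `null_r`
#'   (the sampled correlations) and `seed`.
#' @export
null_threshold <- function(profiles, exclude_pairs = NULL,
                           n_random_pairs = 10000, alpha = 0.05, seed = 1L) {
  f <- profiles$freq
  genes <- rownames(f)
  sds <- apply(f, 1, stats::sd)
  genes <- genes[sds > 0]
  if (length(genes) < 10) abort_("too few variable genes for a null")
  f <- f[genes, , drop = FALSE]
  excl <- character(0)
  if (!is.null(exclude_pairs) && nrow(exclude_pairs) > 0) {
    excl <- paste(pmin(exclude_pairs$gene_a, exclude_pairs$gene_b),
                  pmax(exclude_pairs$gene_a, exclude_pairs$gene_b))
  }
  rs <- with_seed_(seed, {
    out <- numeric(0)
    # standardize rows once; the pair correlation is then a dot product
    z <- t(scale(t(f)))
    m <- ncol(f)
    while (length(out) < n_random_pairs) {
      todo <- n_random_pairs - length(out)
      i <- sample.int(length(genes), todo * 1.2 + 10, replace = TRUE)
      j <- sample.int(length(genes), todo * 1.2 + 10, replace = TRUE)
      ok <- i != j &
        !(paste(pmin(genes[i], genes[j]), pmax(genes[i], genes[j])) %in% excl)
      i <- i[ok]; j <- j[ok]
      r <- rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE]) / (m - 1)
      out <- c(out, r)
    }
    out[seq_len(n_random_pairs)]
  })
  r_star <- if (alpha == 0) max(rs) else unname(quantile(rs, 1 - alpha))
  attr(r_star, "null_r") <- rs
  attr(r_star, "seed") <- seed
  r_star
}

#' Divergent-expression fractions overall and by age
#'
#' Proportion of paralog pairs whose expression correlation falls below the
#' null threshold (divergent expression), overall and stratified into young
#' (Ks <= cutoff) and old (Ks > cutoff) pairs, plus the correlation between
#' `r` and Ks.
#'
#' @param pair_r Tibble with columns `r` and `ks` (one row per pair; `NA`
#'   correlations are dropped).
#' @param r_star Null threshold from [null_threshold()].
#' @param ks_cutoff Young/old stratification cutoff (default 0.4).
#' @return Tibble with one row: `overall`, `young`, `old` (proportions,
#'   `NA` when a stratum is empty), `r_ks_correlation`, `n_pairs`.
#' @export
divergent_fractions <- function(pair_r, r_star, ks_cutoff = 0.4) {
  d <- filter(pair_r, !is.na(.data$r))
  frac <- function(x) if (length(x) == 0) NA_real_ else mean(x < r_star)
  young <- d$r[d$ks <= ks_cutoff]
  old <- d$r[d$ks > ks_cutoff]
  tibble(
    overall = frac(d$r),
    young = frac(young),
    old = frac(old),
    r_ks_correlation = if (nrow(d) >= 3 && stats::sd(d$r) > 0 &&
                             stats::sd(d$ks) > 0) {
      cor(d$r, d$ks)
    } else {
      NA_real_
    },
    n_pairs = nrow(d)
  )
}

#' Tissue-specificity test for a paralog pair
#'
#' Aggregates each gene's EST counts into tissue classes and, for every
#' class, tests the 2x2 table (rows: the two genes; columns: the class
#' versus all other classes) with the two-sided Fisher exact test. A pair
#' is tissue-shifted when any class is significant after Holm correction
#' across the classes (set `correct = "none"` for the uncorrected rule).
#' The test is skipped with a low-count flag when both genes have fewer
#' than `min_total` ESTs.
#'
#' @param gene_a,gene_b Gene ids.
#' @param profiles An `expression_profiles` object (raw counts are used).
#' @param tissue_map Tibble `library`, `tissue` mapping library columns to
#'   tissue classes.
#' @param alpha Significance level (default 0.05).
#' @param correct `"holm"` (default) or `"none"`.
#' @param min_total Minimum EST total for testing (default 5).
#' @return Tibble with one row per tissue class: `tissue`, counts, `p_value`,
#'   `p_adjusted`, `direction` (which gene is relatively enriched),
#'   `significant`; with attribute `shifted` (logical) and `flag`.
#' @export
tissue_specificity <- function(gene_a, gene_b, profiles, tissue_map,
                               alpha = 0.05, correct = c("holm", "none"),
                               min_total = 5) {
  correct <- match.arg(correct)
  cm <- profiles$counts
  if (!(gene_a %in% rownames(cm)) || !(gene_b %in% rownames(cm))) {
    abort_("gene missing from count matrix")
  }
  map <- setNames(tissue_map$tissue, tissue_map$library)
  libs <- intersect(colnames(cm), names(map))
  classes <- unique(unname(map[libs]))
  agg <- function(g) {
    vapply(classes, function(cl) {
      sum(cm[g, libs[map[libs] == cl]])
    }, numeric(1))
  }
  ca <- agg(gene_a); cb <- agg(gene_b)
  if (sum(ca) < min_total && sum(cb) < min_total) {
    out <- tibble(tissue = classes, a_in = ca, b_in = cb,
                  a_out = sum(ca) - ca, b_out = sum(cb) - cb,
                  p_value = NA_real_, p_adjusted = NA_real_,
                  direction = NA_character_, significant = NA)
    attr(out, "shifted") <- NA
    attr(out, "flag") <- "low_count"
    return(out)
  }
  res <- purrr::map_dfr(seq_along(classes), function(k) {
    tab <- matrix(c(ca[k], sum(ca) - ca[k],
                    cb[k], sum(cb) - cb[k]), 2, byrow = TRUE)
    p <- fisher.test(tab, alternative = "two.sided")$p.value
    prop_a <- ca[k] / max(sum(ca), 1)
    prop_b <- cb[k] / max(sum(cb), 1)
    tibble(tissue = classes[k], a_in = ca[k], b_in = cb[k],
           a_out = sum(ca) - ca[k], b_out = sum(cb) - cb[k],
           p_value = p,
           direction = dplyr::case_when(
             prop_a > prop_b ~ gene_a,
             prop_b > prop_a ~ gene_b,
             TRUE ~ NA_character_
           ))
  })
  res$p_adjusted <- if (correct == "holm") {
    p.adjust(res$p_value, "holm")
  } else {
    res$p_value
  }
  res$significant <- res$p_adjusted < alpha
  attr(res, "shifted") <- any(res$significant)
  attr(res, "flag") <- "ok"
  res
}
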