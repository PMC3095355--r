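# Gene families: single-linkage clustering of the paralog graph, dating of
# duplication nodes on the within-family Ks dendrogram, young-paralog
# subsets, amplification ratios, and the family-size power law.

#' Cluster paralog pairs into gene families
#'
#' Single-linkage clustering: families are the connected components of the
#' paralog-pair graph. Singleton genes are not families.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @return List with `membership` (tibble `gene`, `family_id`) and
#'   `families` (tibble `family_id`, `n`), family ids ordered by decreasing
#'   size then lexicographically smallest member.
#' @export
cluster_families <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(list(membership = tibble(gene = character(),
                                    family_id = character()),
                families = tibble(family_id = character(), n = integer())))
  }
  g <- igraph::graph_from_data_frame(pairs[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  ord <- order(-lengths(members),
               vapply(members, function(m) min(m), ""))
  members <- members[ord]
  ids <- sprintf("FAM%05d", seq_along(members))
  membership <- tibble(
    gene = unlist(members, use.names = FALSE),
    family_id = rep(ids, lengths(members))
  )
  list(
    membership = membership,
    families = tibble(family_id = ids, n = unname(lengths(members)))
  )
}

#' Date duplication nodes within a family
#'
#' Builds the within-family dendrogram by average-linkage (UPGMA)
#' agglomeration on the pairwise Ks matrix. Each merge is one duplication
#' event; its age is the arithmetic mean of the observed cross-cluster
#' pairwise Ks values, which deduplicates the redundant pairwise ages of a
#' single event. Member pairs lacking a Ks estimate are imputed with the
#' family's maximum observed Ks for linkage purposes only and never
#' contribute to node age means.
#'
#' @param members Character vector of the family's gene ids (>= 2).
#' @param ks_tbl Tibble `gene_a`, `gene_b`, `ks` covering the family's
#'   estimated pairs.
#' @return Tibble with one row per duplication node: `age_ks`,
#'   `n_left`, `n_right`, `age_observed` (FALSE when every cross-cluster Ks
#'   was imputed, in which case `age_ks` is the imputed mean).
#' @export
date_duplications <- function(members, ks_tbl) {
  n <- length(members)
  if (n < 2) abort_("a family needs >= 2 members")
  obs <- matrix(NA_real_, n, n, dimnames = list(members, members))
  sub <- filter(ks_tbl, .data$gene_a %in% members,
                .data$gene_b %in% members)
  if (nrow(sub) > 0) {
    obs[cbind(sub$gene_a, sub$gene_b)] <- sub$ks
    obs[cbind(sub$gene_b, sub$gene_a)] <- sub$ks
  }
  if (all(is.na(obs[upper.tri(obs)]))) {
    abort_("no Ks estimates available for this family")
  }
  impute <- max(obs, na.rm = TRUE)
  filled <- obs
  filled[is.na(filled)] <- impute
  diag(filled) <- 0
  hc <- hclust(as.dist(filled), method = "average")
  # walk the merge table, tracking leaf sets, and average observed Ks across
  # each merge's two clusters
  leafsets <- vector("list", n - 1L)
  out <- vector("list", n - 1L)
  get_set <- function(idx) {
    if (idx < 0) members[-idx] else leafsets[[idx]]
  }
  for (e in seq_len(n - 1L)) {
    left <- get_set(hc$merge[e, 1])
    right <- get_set(hc$merge[e, 2])
    leafsets[[e]] <- c(left, right)
    cross <- obs[left, right, drop = FALSE]
    observed <- any(!is.na(cross))
    age <- if (observed) mean(cross, na.rm = TRUE) else hc$height[e]
    out[[e]] <- tibble(age_ks = age, n_left = length(left),
                       n_right = length(right), age_observed = observed)
  }
  bind_rows(out)
}

#' Date duplication nodes for every family
#'
#' @param clustering Result of [cluster_families()].
#' @param ks_tbl Tibble `gene_a`, `gene_b`, `ks`.
#' @return Tibble `family_id` plus the [date_duplications()] columns.
#' @export
date_all_families <- function(clustering, ks_tbl) {
  fams <- split(clustering$membership$gene,
                clustering$membership$family_id)
  purrr::imap_dfr(fams, function(members, fid) {
    nodes <- tryCatch(date_duplications(members, ks_tbl),
                      duplidate_error = function(e) NULL)
    if (is.null(nodes)) return(NULL)
    bind_cols(tibble(family_id = fid), nodes)
  })
}

#' Recluster young paralogs and count young duplications
#'
#' Selects the pairs with Ks strictly below `cutoff`, reclusters them into
#' young families with the same single-linkage approach, and counts, for
#' each whole-dataset family, the duplication nodes younger than the cutoff.
#'
#' @param ks_tbl Tibble `gene_a`, `gene_b`, `ks` (whole dataset).
#' @param nodes Tibble from [date_all_families()].
#' @param cutoff Young-paralog Ks cutoff, strict (default 0.4).
#' @return List with `young_clustering` (as [cluster_families()]) and
#'   `d_young` (tibble `family_id`, `d_young`).
#' @export
young_subset <- function(ks_tbl, nodes, cutoff = 0.4) {
  young_pairs <- filter(ks_tbl, .data$ks < cutoff)
  d_young <- nodes |>
    group_by(.data$family_id) |>
    summarise(d_young = sum(.data$age_ks < cutoff), .groups = "drop")
  list(
    young_clustering = cluster_families(young_pairs),
    d_young = d_young
  )
}

#' Gene-family amplification ratio
#'
#' The current copy number divided by the inferred ancestral copy number
#' (current minus young duplication events): a family of `n_total` genes
#' with `d_young` duplication nodes younger than the cutoff descends from
#' `n_total - d_young` ancestral copies.
#'
#' @param n_total Current copy number(s).
#' @param d_young Number of young duplication nodes (must be < `n_total`).
#' @return Tibble `n_total`, `d_young`, `n_ancestral`, `ratio` (rounded to
#'   2 decimals).
#' @export
amplification_ratio <- function(n_total, d_young) {
  if (any(d_young >= n_total)) {
    abort_("d_young must be smaller than n_total (>= 1 ancestral copy)")
  }
  if (any(d_young < 0) || any(n_total < 1)) {
    abort_("copy numbers must be non-negative, n_total >= 1")
  }
  tibble(
    n_total = n_total, d_young = d_young,
    n_ancestral = n_total - d_young,
    ratio = round(n_total / (n_total - d_young), 2)
  )
}

#' Fit a power law to the family-size distribution
#'
#' Estimates the exponent of `f(x) = a * x^-b` over the occupied size
#' classes. The default is the discrete truncated maximum-likelihood
#' estimator, which weights every family equally; `method = "ols"` gives
#' the classical log-log least-squares curve fit instead. The least-squares
#' fit treats each size class as one point, so the long sparse tail of
#' unit-frequency classes dominates and flattens the slope badly on
#' realistic samples (bias near -0.8 at 2,000 families); it is kept for
#' presentation (its `a` and R-squared describe the plotted curve), not
#' estimation.
#'
#' @param sizes Integer vector of family sizes, or a data frame with
#'   columns `size` and `frequency` (a prebuilt size-class histogram).
#' @param method `"mle"` (default) or `"ols"`.
#' @return Object of class `powerlaw_fit`: list with `a`, `b`, `r_squared`,
#'   `method`, and the size-class table.
#' @export
fit_powerlaw <- function(sizes, method = c("mle", "ols")) {
  method <- match.arg(method)
  if (is.data.frame(sizes)) {
    stopifnot(all(c("size", "frequency") %in% names(sizes)))
    classes <- as_tibble(sizes[, c("size", "frequency")])
    n_total <- sum(classes$frequency)
  } else {
    tab <- table(sizes)
    classes <- tibble(size = as.integer(names(tab)),
                      frequency = as.integer(tab))
    n_total <- length(sizes)
  }
  if (nrow(classes) < 2) {
    abort_("power-law fit is under-determined with a single size class")
  }
  if (method == "ols") {
    fit <- lm(log(frequency) ~ log(size), data = classes)
    a <- exp(coef(fit)[[1]])
    b <- -coef(fit)[[2]]
    obs <- log(classes$frequency)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((obs - mean(obs))^2)
  } else {
    xmin <- min(classes$size); xmax <- max(classes$size)
    nll <- function(b) {
      z <- sum((xmin:xmax)^(-b))
      -sum(classes$frequency * (-b * log(classes$size) - log(z)))
    }
    b <- optimize(nll, c(1.0001, 10))$minimum
    a <- n_total / sum((xmin:xmax)^(-b))
    # pseudo-R2 on the log-log class frequencies for comparability
    pred <- log(a) - b * log(classes$size)
    obs <- log(classes$frequency)
    r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
  structure(
    list(a = a, b = b, r_squared = r2, method = method, classes = classes),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s): f(x) = %.0f * x^-%.2f  (R^2 = %.2f)\n",
              x$method, x$a, x$b, x$r_squared))
  invisible(x)
}

#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, r_squared = x$r_squared,
         n_classes = nrow(x$classes), method = x$method)
}

#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  ggplot2::ggplot(object$classes,
                  ggplot2::aes(x = .data$size, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::geom_function(
      fun = function(x) object$a * x^(-object$b), colour = "grey40"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "family size", y = "number of families",
                  title = sprintf("f(x) = %.0f x^-%.2f (R² = %.2f)",
                                  object$a, object$b, object$r_squared))
}

#' Compare family sizes against a reference species
#'
#' Inner-joins two family-size tables on the family name and reports the
#' Pearson correlation of copy numbers and the families larger than the
#' reference.
#'
#' @param sizes,reference Tibbles with columns `family` and `n`.
#' @return List with `joined` (tibble `family`, `n`, `n_ref`, `larger`),
#'   `correlation`, and `larger` (character vector).
#' @export
compare_sizes <- function(sizes, reference) {
  stopifnot(all(c("family", "n") %in% names(sizes)),
            all(c("family", "n") %in% names(reference)))
  joined <- inner_join(sizes, rename(reference, n_ref = "n"),
                       by = "family") |>
    mutate(larger = .data$n > .data$n_ref)
  r <- if (nrow(joined) >= 3) cor(joined$n, joined$n_ref) else NA_real_
  list(joined = joined, correlation = r,
       larger = joined$family[joined$larger])
}

#' Printed copy numbers of the amplified apple gene families
#'
#' Loads the bundled table of 17 amplified gene families with copy numbers
#' in apple, Arabidopsis and poplar, the copy number among young (Ks < 0.4)
#' paralogs, and the young-duplication count used for amplification ratios.
#'
#' @return Tibble with columns `family`, `apple`, `arabidopsis`, `poplar`,
#'   `n_young_ks`, `d_young`.
#' @export
amplified_families <- function() {
  readr::read_tsv(
    system.file("extdata", "amplified_families.tsv", package = "duplidate"),
    show_col_types = FALSE
  )
}
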