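# Synthetic-data generator: codon sequence pairs at known Ks, duplication
# ages from an exponential + Gaussian mixture, power-law family sizes, and
# multinomial EST count profiles with controllable paralog co-regulation.
# Every generator is deterministic given its seed.

#' Simulation configuration
#'
#' Bundles the ground-truth parameters used by [simulate_dataset()]. The
#' defaults emulate an EST study of a polyploid woody plant: a continuous
#' exponential decay of small-scale duplications (death rate 1.892 per Ks
#' unit), a sharp recent polyploidy peak (mean Ks 0.185), a broad ancient
#' triplication peak (mean Ks 1.65, variance 0.31), family sizes following a
#' discrete power law with exponent 2.35, and 14 non-normalized EST libraries
#' mapped to four tissue classes.
#'
#' @param seed Master seed; identical configurations generate byte-identical
#'   datasets.
#' @param n_families Number of gene families to simulate.
#' @param death_rate Exponential rate of the small-scale-duplication age
#'   component, per Ks unit (> 0).
#' @param components Data frame with columns `mean`, `variance`, `weight`
#'   describing 0-3 normal age components (Ks, Ks^2, proportion).
#' @param w_exp Weight of the exponential component; `w_exp` plus the normal
#'   weights must sum to 1.
#' @param powerlaw_exponent Exponent of the discrete power law for family
#'   sizes (> 1).
#' @param size_range Integer vector `c(min, max)` of admissible family sizes.
#' @param n_libraries Number of EST libraries.
#' @param library_sizes ESTs sequenced per library (recycled to
#'   `n_libraries`).
#' @param tissue_map Character vector of length `n_libraries` assigning each
#'   library to a tissue class.
#' @param ks_upper Truncation point of the age distribution (ages are
#'   conditioned on (0, ks_upper]).
#' @param n_codons Codon length of simulated coding sequences.
#' @param kappa,omega Codon-model parameters used to evolve sequences.
#' @param coregulated_fraction Proportion of paralog pairs sharing an
#'   expression profile.
#' @param tissue_shifted_fraction Proportion of paralog pairs with
#'   disjoint-tissue-class profiles (subfunctionalization-like).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 200L,
                       death_rate = 1.892,
                       components = tibble(
                         mean = c(0.185, 1.650),
                         variance = c(0.08^2, 0.31),
                         weight = c(0.35, 0.20)
                       ),
                       w_exp = 0.45,
                       powerlaw_exponent = 2.35,
                       size_range = c(2L, 50L),
                       n_libraries = 14L,
                       library_sizes = 5000L,
                       tissue_map = rep(c("fruit", "vegetative",
                                          "reproductive", "vascular"),
                                        length.out = n_libraries),
                       ks_upper = 2,
                       n_codons = 300L,
                       kappa = 2,
                       omega = 0.3,
                       coregulated_fraction = 0.2,
                       tissue_shifted_fraction = 0.1) {
  components <- as_tibble(components)
  w_all <- c(w_exp, components$weight)
  if (any(w_all < 0) || abs(sum(w_all) - 1) > 1e-8) {
    abort_("mixture weights must be >= 0 and sum to 1 (exponential + normals)")
  }
  if (death_rate <= 0) abort_("death_rate must be > 0")
  if (nrow(components) > 0 && any(components$variance <= 0)) {
    abort_("all normal-component variances must be > 0")
  }
  if (powerlaw_exponent <= 1) abort_("powerlaw_exponent must be > 1")
  if (length(tissue_map) != n_libraries) {
    abort_("tissue_map must name one class per library")
  }
  structure(
    list(
      seed = as.integer(seed), n_families = as.integer(n_families),
      death_rate = death_rate, components = components, w_exp = w_exp,
      powerlaw_exponent = powerlaw_exponent,
      size_range = as.integer(size_range),
      n_libraries = as.integer(n_libraries),
      library_sizes = rep(as.integer(library_sizes),
                          length.out = n_libraries),
      tissue_map = tissue_map, ks_upper = ks_upper,
      n_codons = as.integer(n_codons), kappa = kappa, omega = omega,
      coregulated_fraction = coregulated_fraction,
      tissue_shifted_fraction = tissue_shifted_fraction
    ),
    class = "sim_config"
  )
}

#' Simulate a codon sequence pair at a target Ks
#'
#' Draws an ancestral sense-codon sequence from F3x4 equilibrium frequencies
#' and evolves two descendants under the GY94 model, each for half of the
#' total divergence `t` at which the model-expected synonymous divergence
#' equals `ks_target`. Per-site substitution is sampled from the exact
#' matrix-exponential transition probabilities, so the simulation matches the
#' estimator's model class exactly.
#'
#' @param n_codons Number of codons (>= 10).
#' @param ks_target Target synonymous divergence between the two descendants
#'   (>= 0).
#' @param kappa,omega Codon-model parameters.
#' @param seed Integer seed.
#' @param pi Optional 61-codon equilibrium frequencies; defaults to the
#'   uniform F3x4 profile.
#' @return Tibble with one row per gene (`id`, `cds`) plus attributes
#'   `t_total` (divergence used) and `ks_target`.
#' @export
simulate_codon_pair <- function(n_codons, ks_target, kappa = 2, omega = 0.3,
                                seed = 1L, pi = NULL) {
  if (n_codons < 10) abort_("n_codons must be >= 10")
  if (ks_target < 0) abort_("ks_target must be >= 0")
  pi <- pi %||% f3x4_frequencies()
  t_total <- gy94_t_for_ks(ks_target, pi, kappa, omega)
  model <- gy94_model(pi, kappa, omega)
  eig <- gy94_eigen(model)
  uni <- codon_universe()
  with_seed_(seed, {
    anc <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
    if (t_total == 0) {
      a <- b <- anc
    } else {
      P <- gy94_pmat(model, t_total / 2, eig)
      a <- evolve_codons_(anc, P)
      b <- evolve_codons_(anc, P)
    }
    out <- tibble(
      id = c("sim_a", "sim_b"),
      cds = c(paste(uni$codons[a], collapse = ""),
              paste(uni$codons[b], collapse = ""))
    )
    attr(out, "t_total") <- t_total
    attr(out, "ks_target") <- ks_target
    out
  })
}

# sample descendant codon states; sites grouped by ancestral codon so each
# group is one multinomial draw from the corresponding row of P
evolve_codons_ <- function(states, P) {
  out <- integer(length(states))
  for (s in unique(states)) {
    idx <- which(states == s)
    out[idx] <- sample.int(61L, length(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Simulate duplication ages from an exponential + normal mixture
#'
#' Draws i.i.d. ages from the weighted mixture of one exponential and 0-3
#' normal components, rejection-truncated to `(0, upper]`. Component labels
#' are retained in the `component` column (0 = exponential).
#'
#' @param n Number of ages (>= 1).
#' @param config A [sim_config()] supplying `death_rate`, `components` and
#'   `w_exp`.
#' @param upper Truncation point (> 0); defaults to the config's `ks_upper`.
#' @param seed Integer seed.
#' @return Tibble with columns `age` and `component`.
#' @export
simulate_age_sample <- function(n, config = sim_config(), upper = NULL,
                                seed = 1L) {
  if (n < 1) abort_("n must be >= 1")
  upper <- upper %||% config$ks_upper
  if (upper <= 0) abort_("upper must be > 0")
  comp <- config$components
  weights <- c(config$w_exp, comp$weight)
  with_seed_(seed, {
    lab <- sample.int(length(weights), n, replace = TRUE,
                      prob = weights) - 1L
    age <- numeric(n)
    todo <- seq_len(n)
    while (length(todo) > 0) {
      k <- lab[todo]
      draw <- numeric(length(todo))
      is_exp <- k == 0L
      if (any(is_exp)) draw[is_exp] <- rexp(sum(is_exp), config$death_rate)
      for (ci in seq_len(nrow(comp))) {
        sel <- k == ci
        if (any(sel)) {
          draw[sel] <- rnorm(sum(sel), comp$mean[ci], sqrt(comp$variance[ci]))
        }
      }
      age[todo] <- draw
      todo <- todo[draw <= 0 | draw > upper]
    }
    tibble(age = age, component = lab)
  })
}

#' Simulate gene-family sizes from a discrete power law
#'
#' Sizes are drawn from `P(x) proportional to x^-exponent` on the integer
#' range `[min_size, max_size]`.
#'
#' @param n_families Number of families (>= 1).
#' @param exponent Power-law exponent (> 1).
#' @param min_size,max_size Integer size range.
#' @param seed Integer seed.
#' @return Integer vector of family sizes.
#' @export
simulate_family_sizes <- function(n_families, exponent = 2.35, min_size = 2L,
                                  max_size = 250L, seed = 1L) {
  if (n_families < 1) abort_("n_families must be >= 1")
  if (exponent <= 1) abort_("exponent must be > 1")
  if (min_size < 1 || max_size < min_size) abort_("invalid size range")
  if (min_size == max_size) return(rep(as.integer(min_size), n_families))
  sizes <- min_size:max_size
  with_seed_(seed, {
    sample(sizes, n_families, replace = TRUE, prob = sizes^(-exponent))
  })
}

#' Simulate EST count profiles for genes with planted co-regulation
#'
#' Each gene receives a latent expression profile over the libraries. Paralog
#' pairs flagged `coregulated` share one profile; `divergent` pairs get
#' independent profiles; `tissue-shifted` pairs get profiles with disjoint
#' tissue-class support. Observed counts are multinomial draws per library
#' (genes competing for the library's sequencing depth), mimicking
#' non-normalized EST sampling.
#'
#' @param genes Character vector of gene ids, or a tibble with an `id`
#'   column. Genes are grouped into families via `family` (optional column /
#'   attribute); ungrouped genes are treated as single-copy.
#' @param pairs Optional tibble (`gene_a`, `gene_b`) of paralog pairs used to
#'   plant co-regulation classes; pairs must lie within one family when
#'   families are given.
#' @param config A [sim_config()] supplying library structure and the
#'   co-regulation fractions.
#' @param seed Integer seed.
#' @return List with `counts` (tibble gene x library, one column per library
#'   id), `truth` (tibble `gene_a`, `gene_b`, `class`), and `profiles` (the
#'   latent per-gene expected frequencies).
#' @export
simulate_expression <- function(genes, pairs = NULL, config = sim_config(),
                                seed = 1L) {
  ids <- if (is.data.frame(genes)) genes$id else genes
  fam <- if (is.data.frame(genes) && "family" %in% names(genes)) {
    genes$family
  } else {
    # genes without family structure: every gene its own group
    paste0("g", seq_along(ids))
  }
  n_lib <- config$n_libraries
  classes <- config$tissue_map
  class_levels <- unique(classes)
  with_seed_(seed, {
    # latent per-family base profile and per-gene abundance
    base_profile <- function() {
      p <- rgamma(n_lib, shape = 0.5)
      p / sum(p)
    }
    profiles <- matrix(0, length(ids), n_lib,
                       dimnames = list(ids, paste0("lib", seq_len(n_lib))))
    fam_base <- list()
    pair_class <- character(0)
    if (!is.null(pairs) && nrow(pairs) > 0) {
      u <- runif(nrow(pairs))
      pair_class <- ifelse(
        u < config$coregulated_fraction, "coregulated",
        ifelse(u < config$coregulated_fraction +
                 config$tissue_shifted_fraction, "tissue-shifted", "divergent")
      )
    }
    # decide each gene's profile: genes named in a coregulated pair share the
    # family base; tissue-shifted partners get complementary class supports
    assigned <- setNames(vector("list", length(ids)), ids)
    for (f in unique(fam)) fam_base[[f]] <- base_profile()
    gene_fam <- setNames(fam, ids)
    if (!is.null(pairs) && nrow(pairs) > 0) {
      for (k in seq_len(nrow(pairs))) {
        ga <- pairs$gene_a[k]; gb <- pairs$gene_b[k]
        cls <- pair_class[k]
        if (cls == "coregulated") {
          bp <- fam_base[[gene_fam[[ga]]]]
          assigned[[ga]] <- assigned[[ga]] %||% bp
          assigned[[gb]] <- assigned[[gb]] %||% bp
        } else if (cls == "tissue-shifted") {
          half <- sample(class_levels, ceiling(length(class_levels) / 2))
          pa <- base_profile(); pb <- base_profile()
          pa[!(classes %in% half)] <- 0
          pb[classes %in% half] <- 0
          if (sum(pa) == 0 || sum(pb) == 0) { pa <- base_profile(); pb <- base_profile() }
          assigned[[ga]] <- assigned[[ga]] %||% (pa / sum(pa))
          assigned[[gb]] <- assigned[[gb]] %||% (pb / sum(pb))
        }
      }
    }
    for (g in ids) {
      if (is.null(assigned[[g]])) assigned[[g]] <- base_profile()
      profiles[g, ] <- assigned[[g]]
    }
    abundance <- stats::rlnorm(length(ids), meanlog = 0, sdlog = 1)
    expected <- profiles * abundance
    counts <- matrix(0L, length(ids), n_lib, dimnames = dimnames(profiles))
    for (l in seq_len(n_lib)) {
      p <- expected[, l]
      if (sum(p) == 0) next
      counts[, l] <- rmultinom(1, config$library_sizes[l], p)[, 1]
    }
    truth <- if (!is.null(pairs) && nrow(pairs) > 0) {
      tibble(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             class = pair_class)
    } else {
      tibble(gene_a = character(), gene_b = character(),
             class = character())
    }
    list(
      counts = as_tibble(counts, rownames = "gene"),
      truth = truth,
      profiles = as_tibble(profiles, rownames = "gene")
    )
  })
}

#' Simulate a complete dataset with known ground truth
#'
#' Generates gene families (power-law sizes), a random ultrametric
#' duplication history per family with node ages drawn from the age mixture,
#' coding sequences evolved along that history under the GY94 model, and EST
#' count profiles with planted co-regulation classes.
#'
#' @param config A [sim_config()].
#' @param sequences If `FALSE`, skip sequence evolution (fast mode for tests
#'   of clustering/dating machinery; `cds` columns are then absent).
#' @return List of class `sim_dataset` with elements `genes` (tibble: `id`,
#'   `family`, and `cds`/`protein` when simulated), `true_pair_ks` (tibble
#'   `gene_a`, `gene_b`, `ks`), `true_ages` (per-family duplication node
#'   ages), `expression` (see [simulate_expression()]) and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), sequences = TRUE) {
  seed <- config$seed
  sizes <- simulate_family_sizes(
    config$n_families, config$powerlaw_exponent,
    config$size_range[1], config$size_range[2], seed = seed
  )
  n_events <- sum(sizes - 1L)
  ages <- simulate_age_sample(max(n_events, 1L), config, seed = seed + 1L)$age
  uni <- codon_universe()
  pi <- f3x4_frequencies()
  model <- gy94_model(pi, config$kappa, config$omega)
  eig <- gy94_eigen(model)
  ks_unit <- gy94_ks_ka(1, pi, config$kappa, config$omega)$ks

  genes <- list(); pair_ks <- list(); age_tbl <- list()
  ev_at <- 0L
  with_seed_(seed + 2L, {
    for (f in seq_along(sizes)) {
      n <- sizes[f]
      fam_id <- sprintf("F%04d", f)
      node_ages <- sort(ages[ev_at + seq_len(n - 1L)])
      ev_at <- ev_at + n - 1L
      ids <- sprintf("%s_g%02d", fam_id, seq_len(n))
      # random coalescent-style ultrametric topology: merge two random
      # clusters at each node age (ascending); pairwise Ks = MRCA height
      ks_mat <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
      clusters <- as.list(seq_len(n))
      merges <- list()
      for (e in seq_len(n - 1L)) {
        pick <- sample.int(length(clusters), 2L)
        ca <- clusters[[pick[1]]]; cb <- clusters[[pick[2]]]
        ks_mat[ca, cb] <- node_ages[e]
        ks_mat[cb, ca] <- node_ages[e]
        clusters[[pick[1]]] <- c(ca, cb)
        clusters <- clusters[-pick[2]]
        merges[[e]] <- list(a = ca, b = cb, h = node_ages[e])
      }
      if (sequences) {
        cds <- evolve_family_(n, merges, model, eig, pi, ks_unit,
                              config$n_codons, uni)
      } else {
        cds <- NULL
      }
      genes[[f]] <- tibble(id = ids, family = fam_id,
                           cds = if (is.null(cds)) NA_character_ else cds)
      idx <- which(upper.tri(ks_mat), arr.ind = TRUE)
      pair_ks[[f]] <- tibble(
        gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
        ks = ks_mat[idx]
      )
      age_tbl[[f]] <- tibble(family = fam_id, age = node_ages)
    }
  })
  genes <- bind_rows(genes)
  if (sequences) {
    genes$protein <- translate_cds(genes$cds)
  } else {
    genes$cds <- NULL
  }
  pair_ks <- bind_rows(pair_ks)
  expr <- simulate_expression(genes, pairs = pair_ks[, c("gene_a", "gene_b")],
                              config = config, seed = seed + 3L)
  structure(
    list(genes = genes, true_pair_ks = pair_ks,
         true_ages = bind_rows(age_tbl), expression = expr,
         config = config),
    class = "sim_dataset"
  )
}

# Evolve codon sequences down a recorded merge history. Heights are pairwise
# Ks at each node; a lineage spanning from height h1 down to h0 evolves for
# t = (h1 - h0)/2 * 3 * rho1 / rho (i.e. Ks-to-t conversion of half the
# height difference, divergence being shared by two lineages).
evolve_family_ <- function(n, merges, model, eig, pi, ks_unit, n_codons, uni) {
  heights <- numeric(n) # current height of each leaf's ancestor (0 at leaf)
  root_h <- merges[[length(merges)]]$h
  root <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  seqs <- rep(list(root), n)
  # walk merges from root downwards: before the final merge everything shares
  # the root state; at each node the two child clusters diverge independently
  # for the height gap down to their next (lower) node or leaf.
  state_h <- rep(root_h, n)
  for (e in rev(seq_along(merges))) {
    m <- merges[[e]]
    for (side in list(m$a, m$b)) {
      # children of this node sit at height m$h; they will next split at the
      # highest merge strictly below within `side`, or reach the leaves
      sub <- Filter(function(x) all(x$a %in% side) && all(x$b %in% side) &&
                      x$h < m$h, merges[seq_len(e - 1)])
      next_h <- if (length(sub) > 0) max(vapply(sub, `[[`, 0, "h")) else 0
      dt <- (m$h - next_h) / 2 / ks_unit
      if (dt > 0) {
        P <- gy94_pmat(model, dt, eig)
        evolved <- evolve_codons_(seqs[[side[1]]], P)
        for (g in side) seqs[[g]] <- evolved
      }
    }
  }
  # the loop above evolves whole clusters jointly at each level; finish by
  # evolving each leaf independently from its last shared state... handled by
  # construction since clusters of size 1 are reached with next_h = 0.
  vapply(seqs, function(s) paste(uni$codons[s], collapse = ""), "")
}

#' Translate coding sequences
#'
#' Standard-code translation of in-frame CDS strings; ambiguous codons
#' translate to `X`.
#'
#' @param cds Character vector of nucleotide sequences (length multiple of 3).
#' @return Character vector of protein sequences.
#' @export
translate_cds <- function(cds) {
  vapply(cds, function(s) {
    if (is.na(s)) return(NA_character_)
    as.character(Biostrings::translate(
      Biostrings::DNAString(s), if.fuzzy.codon = "X"
    ))
  }, "", USE.NAMES = FALSE)
}

#' Write a simulated dataset to plain-text pipeline inputs
#'
#' Writes CDS and protein FASTA, the EST count matrix (genes x libraries,
#' header row of library ids), the library-to-tissue map, and the truth
#' tables.
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  g <- dataset$genes
  if ("cds" %in% names(g)) {
    cds_path <- file.path(dir, "cds.fasta")
    writeLines(paste0(">", g$id, "\n", g$cds), cds_path)
    prot_path <- file.path(dir, "protein.fasta")
    writeLines(paste0(">", g$id, "\n", g$protein), prot_path)
    files <- c(files, cds_path, prot_path)
  }
  counts_path <- file.path(dir, "est_counts.tsv")
  readr::write_tsv(dataset$expression$counts, counts_path)
  tissue_path <- file.path(dir, "tissue_map.tsv")
  readr::write_tsv(
    tibble(library = paste0("lib", seq_along(dataset$config$tissue_map)),
           tissue = dataset$config$tissue_map),
    tissue_path
  )
  truth_ks <- file.path(dir, "true_pair_ks.tsv")
  readr::write_tsv(dataset$true_pair_ks, truth_ks)
  truth_fam <- file.path(dir, "true_families.tsv")
  readr::write_tsv(dataset$genes[, c("id", "family")], truth_fam)
  invisible(c(files, counts_path, tissue_path, truth_ks, truth_fam))
}
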