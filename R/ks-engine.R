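# Pairwise synonymous-divergence estimation: protein-guided codon alignment,
# maximum likelihood under GY94/F3x4 with randomized restarts, and a
# Nei-Gojobori (1986) counting estimator kept as an independent cross-check.

#' Protein-guided codon alignment of a gene pair
#'
#' Globally aligns the two proteins (BLOSUM62, affine gaps), back-translates
#' the alignment to codons using each gene's CDS, and removes every codon
#' column containing a gap, an ambiguous base, or a stop codon.
#'
#' @param cds_a,cds_b In-frame coding sequences (length divisible by 3).
#' @param protein_a,protein_b Optional proteins; derived by translation when
#'   absent. A mismatch between a supplied protein and its CDS translation
#'   (over non-ambiguous codons) is a data error.
#' @return Tibble with columns `codon_a`, `codon_b`, one row per retained
#'   codon column.
#' @export
codon_align <- function(cds_a, cds_b, protein_a = NULL, protein_b = NULL) {
  if (nchar(cds_a) %% 3 != 0 || nchar(cds_b) %% 3 != 0) {
    abort_("CDS length must be divisible by 3", class = "duplidate_data_error")
  }
  ta <- translate_cds(cds_a)
  tb <- translate_cds(cds_b)
  check_prot <- function(given, derived, label) {
    if (is.null(given)) return(derived)
    if (nchar(given) != nchar(derived)) {
      abort_(sprintf("protein/CDS length mismatch for %s", label),
             class = "duplidate_data_error")
    }
    g <- strsplit(given, "")[[1]]
    d <- strsplit(derived, "")[[1]]
    ok <- g == d | d == "X" | g == "X"
    if (!all(ok)) {
      abort_(sprintf("protein does not match CDS translation for %s", label),
             class = "duplidate_data_error")
    }
    given
  }
  pa <- check_prot(protein_a, ta, "sequence A")
  pb <- check_prot(protein_b, tb, "sequence B")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  # X (ambiguous-codon translation) is absent from BLOSUM62's letters here;
  # align on X-masked copies scored as neutral by substituting a rare residue
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(gsub("[*]", "X", pa)),
    Biostrings::AAString(gsub("[*]", "X", pb)),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 0.5
  )
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  codons_a <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  codons_b <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  ia <- 0L; ib <- 0L
  keep_a <- character(0); keep_b <- character(0)
  stops <- c("TAA", "TAG", "TGA")
  for (col in seq_along(ap)) {
    ga <- ap[col] == "-"; gb <- as_[col] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) next
    ca <- toupper(codons_a[ia]); cb <- toupper(codons_b[ib])
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (ca %in% stops || cb %in% stops) next
    keep_a <- c(keep_a, ca); keep_b <- c(keep_b, cb)
  }
  tibble(codon_a = keep_a, codon_b = keep_b)
}

#' Maximum-likelihood Ks/Ka for an aligned codon pair
#'
#' Maximizes the pairwise likelihood `sum_sites log(pi_x P(x -> y | t))`
#' under the GY94 model over `(t, kappa, omega)`, with F3x4 frequencies
#' estimated empirically from the pooled codons of the pair. The optimizer
#' is a derivative-free simplex on log-transformed parameters with box
#' bounds `t in [1e-6, 20]`, `kappa in [0.1, 20]`, `omega in [1e-4, 10]`;
#' `n_restarts` randomized initializations are run and the best
#' log-likelihood is retained. Ks is the synonymous substitution flux per
#' synonymous site (sites defined with omega fixed to 1), Ka its
#' nonsynonymous counterpart.
#'
#' @param alignment Tibble from [codon_align()] (>= 10 retained columns).
#' @param n_restarts Number of randomized restarts (default 5).
#' @param pair_id Optional string used to seed the restart jitter
#'   reproducibly (e.g. `"geneA|geneB"`).
#' @param seed Base seed combined with `pair_id`.
#' @return One-row tibble: `t`, `kappa`, `omega`, `ks`, `ka`, `loglik`,
#'   `n_codons_used`, `converged`.
#' @export
fit_pair_ml <- function(alignment, n_restarts = 5, pair_id = "pair",
                        seed = 1L) {
  n_cod <- nrow(alignment)
  if (n_cod < 10) abort_("need >= 10 retained codon columns")
  pi <- f3x4_frequencies(c(alignment$codon_a, alignment$codon_b))
  uni <- codon_universe()
  ia <- match(alignment$codon_a, uni$codons)
  ib <- match(alignment$codon_b, uni$codons)
  if (anyNA(ia) || anyNA(ib)) abort_("alignment contains non-sense codons")
  # collapse to pattern counts: likelihood depends only on (x, y) counts
  pat <- paste(ia, ib)
  cnt <- table(pat)
  px <- as.integer(sub(" .*", "", names(cnt)))
  py <- as.integer(sub(".* ", "", names(cnt)))
  nw <- as.numeric(cnt)

  if (all(px == py)) {
    # identical sequences: the likelihood is maximized at the t -> 0
    # boundary, where Ks and Ka are exactly zero
    ll <- sum(nw * log(pi[px]))
    return(tibble(t = 0, kappa = NA_real_, omega = NA_real_, ks = 0, ka = 0,
                  loglik = ll, n_codons_used = n_cod, converged = TRUE))
  }

  lo <- log(c(1e-6, 0.1, 1e-4))
  hi <- log(c(20, 20, 10))
  negll <- function(par) {
    pen <- sum(pmax(par - hi, 0)^2 + pmax(lo - par, 0)^2) * 1e4
    par <- pmin(pmax(par, lo), hi)
    th <- exp(par)
    m <- gy94_model(pi, th[2], th[3])
    P <- gy94_pmat(m, th[1])
    p <- pi[px] * P[cbind(px, py)]
    if (any(p <= 0)) return(1e10)
    -sum(nw * log(p)) + pen
  }
  t_inits <- c(0.05, 0.2, 0.5, 1, 2)
  best <- NULL
  rs <- with_seed_(string_seed_(pair_id, base = seed), {
    lapply(seq_len(n_restarts), function(r) {
      t0 <- t_inits[(r - 1) %% length(t_inits) + 1] * runif(1, 0.8, 1.2)
      k0 <- 2
      w0 <- 0.3 * runif(1, 0.8, 1.2)
      opt <- optim(log(c(t0, k0, w0)), negll, method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 2000))
      opt
    })
  })
  vals <- vapply(rs, `[[`, 0, "value")
  best <- rs[[which.min(vals)]]
  conv <- any(vapply(rs, function(o) o$convergence == 0, TRUE))
  th <- exp(pmin(pmax(best$par, lo), hi))
  kk <- gy94_ks_ka(th[1], pi, th[2], th[3])
  tibble(t = th[1], kappa = th[2], omega = th[3],
         ks = kk$ks, ka = kk$ka, loglik = -best$value,
         n_codons_used = n_cod, converged = conv)
}

# cached per-codon NG86 site counts and codon pair difference counts
ng86_sites_ <- function() {
  if (!is.null(.codon_env$ng86_sites)) return(.codon_env$ng86_sites)
  uni <- codon_universe()
  gc_tab <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  s <- numeric(61)
  for (i in seq_len(61)) {
    cod <- strsplit(uni$codons[i], "")[[1]]
    for (p in 1:3) {
      for (nt in setdiff(nts, cod[p])) {
        alt <- cod; alt[p] <- nt
        alt_c <- paste(alt, collapse = "")
        aa_alt <- gc_tab[[alt_c]]
        # changes to stop codons counted as nonsynonymous
        if (aa_alt != "*" && aa_alt == uni$aa[i]) s[i] <- s[i] + 1 / 3
      }
    }
  }
  .codon_env$ng86_sites <- setNames(s, uni$codons)
  .codon_env$ng86_sites
}

# pathway-averaged synonymous/nonsynonymous difference counts between two
# codons; pathways through stop codons are excluded unless all are blocked
ng86_diffs_ <- function(ca, cb) {
  if (ca == cb) return(c(0, 0))
  gc_tab <- Biostrings::GENETIC_CODE
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  paths <- if (length(pos) == 1) list(pos) else
    lapply(asplit(permutations_(pos), 1), as.integer)
  count_path <- function(order) {
    cur <- a; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- gc_tab[[paste(cur, collapse = "")]]
      aa2 <- gc_tab[[paste(nxt, collapse = "")]]
      if (aa2 == "*" || aa1 == "*") return(NULL)
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  counted <- Filter(Negate(is.null), lapply(paths, count_path))
  if (length(counted) == 0) {
    # all pathways pass through a stop; fall back to counting through them
    counted <- lapply(paths, function(order) {
      cur <- a; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- b[p]
        aa1 <- gc_tab[[paste(cur, collapse = "")]]
        aa2 <- gc_tab[[paste(nxt, collapse = "")]]
        if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
  }
  Reduce(`+`, counted) / length(counted)
}

permutations_ <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- permutations_(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Nei-Gojobori (1986) counting estimate of Ks and Ka
#'
#' Pathway-counting estimator with Jukes-Cantor correction, used as an
#' independent oracle for the likelihood estimator. Synonymous sites per
#' codon are the fraction of single-nucleotide changes that are synonymous
#' (changes to stop codons counted as nonsynonymous); differences between
#' codons are averaged over all mutational pathways avoiding stop codons.
#'
#' @param alignment Tibble from [codon_align()].
#' @return One-row tibble: `ks`, `ka`, `p_s`, `p_n`, `s_sites`, `n_sites`,
#'   `saturated`. `ks`/`ka` are `NaN` with `saturated = TRUE` when the
#'   corrected proportion reaches the Jukes-Cantor singularity (p >= 3/4).
#' @export
ng86_ks <- function(alignment) {
  s_tab <- ng86_sites_()
  sa <- s_tab[alignment$codon_a]
  sb <- s_tab[alignment$codon_b]
  S <- sum((sa + sb) / 2)
  N <- 3 * nrow(alignment) - S
  key <- paste(alignment$codon_a, alignment$codon_b)
  diffs <- vapply(unique(key), function(k) {
    parts <- strsplit(k, " ")[[1]]
    ng86_diffs_(parts[1], parts[2])
  }, numeric(2))
  counts <- diffs[, match(key, unique(key)), drop = FALSE]
  Sd <- sum(counts[1, ])
  Nd <- sum(counts[2, ])
  p_s <- Sd / S
  p_n <- Nd / N
  jc <- function(p) {
    if (p >= 3 / 4) return(NaN)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  ks <- jc(p_s); ka <- jc(p_n)
  tibble(ks = ks, ka = ka, p_s = p_s, p_n = p_n, s_sites = S, n_sites = N,
         saturated = is.nan(ks) || is.nan(ka))
}

#' Filter Ks estimates for downstream dating
#'
#' Drops estimates with Ks above `ks_max` (saturation) and estimates that
#' failed to converge; flags Ks = 0 pairs for redundancy cleanup
#' (see [dedupe_zero_ks()]). The Ks = `ks_max` boundary is retained
#' (strictly greater values are discarded).
#'
#' @param estimates Tibble with at least `ks` and (optionally) `converged`.
#' @param ks_max Saturation cutoff (default 2).
#' @return The retained rows with an added `zero_ks` flag.
#' @export
filter_ks <- function(estimates, ks_max = 2) {
  out <- estimates
  if ("converged" %in% names(out)) out <- filter(out, .data$converged)
  out |>
    filter(.data$ks <= ks_max) |>
    mutate(zero_ks = .data$ks == 0)
}

#' Estimate Ks for every eligible paralog pair
#'
#' Driver over a pair table: aligns each Ks-eligible pair and fits the
#' likelihood model.
#'
#' @param pairs Tibble with `gene_a`, `gene_b` and optionally `ks_eligible`.
#' @param genes Tibble with `id`, `cds` (and optionally `protein`).
#' @param n_restarts Restarts per pair (default 5).
#' @param seed Base seed for restart jitter.
#' @return Tibble: pair ids plus the [fit_pair_ml()] columns.
#' @export
estimate_ks <- function(pairs, genes, n_restarts = 5, seed = 1L) {
  if ("ks_eligible" %in% names(pairs)) {
    pairs <- filter(pairs, .data$ks_eligible)
  }
  cds <- setNames(genes$cds, genes$id)
  purrr::pmap_dfr(pairs[, c("gene_a", "gene_b")], function(gene_a, gene_b) {
    aln <- codon_align(cds[[gene_a]], cds[[gene_b]])
    if (nrow(aln) < 10) {
      return(tibble(gene_a = gene_a, gene_b = gene_b, t = NA_real_,
                    kappa = NA_real_, omega = NA_real_, ks = NA_real_,
                    ka = NA_real_, loglik = NA_real_,
                    n_codons_used = nrow(aln), converged = FALSE))
    }
    est <- fit_pair_ml(aln, n_restarts = n_restarts,
                       pair_id = paste0(gene_a, "|", gene_b), seed = seed)
    bind_cols(tibble(gene_a = gene_a, gene_b = gene_b), est)
  })
}
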