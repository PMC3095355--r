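# Goldman-Yang codon substitution model (GY94) with F3x4 equilibrium
# frequencies. The 61 sense codons of the standard genetic code are the state
# space; stop codons are excluded throughout.

.codon_env <- new.env(parent = emptyenv())

# Cached structural description of the sense-codon state space: which codon
# pairs differ at a single position, whether that change is a transition and
# whether it is synonymous.
codon_universe <- function() {
  if (!is.null(.codon_env$universe)) {
    return(.codon_env$universe)
  }
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)[gc_tab != "*"]
  aa <- unname(gc_tab[codons])
  nt_mat <- do.call(rbind, strsplit(codons, ""))
  n <- length(codons)
  stopifnot(n == 61L)

  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ndiff <- rowSums(nt_mat[idx[, 1], , drop = FALSE] !=
                     nt_mat[idx[, 2], , drop = FALSE])
  one <- idx[ndiff == 1L, , drop = FALSE]
  pos <- apply(nt_mat[one[, 1], , drop = FALSE] !=
                 nt_mat[one[, 2], , drop = FALSE], 1, which)
  from_nt <- nt_mat[cbind(one[, 1], pos)]
  to_nt <- nt_mat[cbind(one[, 2], pos)]
  is_ts <- (from_nt == "A" & to_nt == "G") | (from_nt == "G" & to_nt == "A") |
    (from_nt == "C" & to_nt == "T") | (from_nt == "T" & to_nt == "C")
  is_syn <- aa[one[, 1]] == aa[one[, 2]]

  .codon_env$universe <- list(
    codons = codons, aa = aa, nt_mat = nt_mat,
    i = one[, 1], j = one[, 2], pos = pos,
    is_ts = is_ts, is_syn = is_syn
  )
  .codon_env$universe
}

#' F3x4 codon equilibrium frequencies
#'
#' Builds sense-codon equilibrium frequencies from position-specific
#' nucleotide frequencies (the F3x4 parameterization): the frequency of a
#' codon is proportional to the product of its three nucleotide frequencies,
#' each taken from the frequency profile of the corresponding codon position,
#' renormalized over the 61 sense codons.
#'
#' @param codons Character vector of codons (e.g. pooled over the two
#'   sequences of an alignment) from which position-specific nucleotide
#'   frequencies are estimated, or `NULL` for the uniform profile.
#' @param floor Lower bound applied to each positional nucleotide frequency
#'   before renormalization, guarding against zero frequencies in short
#'   alignments.
#' @return Numeric vector of 61 frequencies summing to 1, named by codon.
#' @export
f3x4_frequencies <- function(codons = NULL, floor = 1e-4) {
  uni <- codon_universe()
  if (is.null(codons)) {
    pos_freq <- matrix(0.25, nrow = 3, ncol = 4,
                       dimnames = list(NULL, c("A", "C", "G", "T")))
  } else {
    mat <- do.call(rbind, strsplit(toupper(codons), ""))
    if (ncol(mat) != 3L) abort_("codons must be length-3 strings")
    pos_freq <- t(apply(mat, 2, function(col) {
      tab <- table(factor(col, levels = c("A", "C", "G", "T")))
      f <- as.numeric(tab) / max(sum(tab), 1L)
      f <- pmax(f, floor)
      f / sum(f)
    }))
    colnames(pos_freq) <- c("A", "C", "G", "T")
  }
  pi <- pos_freq[1, uni$nt_mat[, 1]] *
    pos_freq[2, uni$nt_mat[, 2]] *
    pos_freq[3, uni$nt_mat[, 3]]
  pi <- pi / sum(pi)
  names(pi) <- uni$codons
  pi
}

#' Goldman-Yang codon model
#'
#' Constructs the GY94 instantaneous rate matrix over the 61 sense codons.
#' Off-diagonal rates are non-zero only between codons differing at a single
#' nucleotide: the rate to codon j is proportional to `pi[j]`, multiplied by
#' `kappa` for transitions and by `omega` for nonsynonymous changes. The
#' matrix is scaled so that the expected number of substitutions per codon
#' per unit time equals one.
#'
#' @param pi Equilibrium frequencies over the 61 sense codons
#'   (see [f3x4_frequencies()]).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (> 0).
#' @return An object of class `gy94_model`: list with the scaled rate matrix
#'   `Q`, `pi`, `kappa`, `omega`, and `rho_syn`, the synonymous fraction of
#'   the total substitution flux at equilibrium.
#' @export
gy94_model <- function(pi = f3x4_frequencies(), kappa = 2, omega = 0.3) {
  if (kappa <= 0 || omega <= 0) abort_("kappa and omega must be > 0")
  if (length(pi) != 61L || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    abort_("pi must be 61 non-negative frequencies summing to 1")
  }
  uni <- codon_universe()
  n <- 61L
  Q <- matrix(0, n, n, dimnames = list(uni$codons, uni$codons))
  rate <- pi[uni$j] * ifelse(uni$is_ts, kappa, 1) *
    ifelse(uni$is_syn, 1, omega)
  Q[cbind(uni$i, uni$j)] <- rate
  # reversibility: q_ji = pi_i * (same kappa/omega factor)
  Q[cbind(uni$j, uni$i)] <- pi[uni$i] * ifelse(uni$is_ts, kappa, 1) *
    ifelse(uni$is_syn, 1, omega)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) abort_("degenerate rate matrix (zero flux)")
  Q <- Q / scale
  flux <- pi[uni$i] * Q[cbind(uni$i, uni$j)] + pi[uni$j] * Q[cbind(uni$j, uni$i)]
  rho_syn <- sum(flux[uni$is_syn])
  structure(
    list(Q = Q, pi = pi, kappa = kappa, omega = omega, rho_syn = rho_syn),
    class = "gy94_model"
  )
}

# Spectral decomposition of the reversible Q via the symmetrized form
# S = D^{1/2} Q D^{-1/2}; cached on the model for repeated P(t) evaluation.
gy94_eigen <- function(model) {
  pi <- pmax(model$pi, 1e-12)
  d <- sqrt(pi)
  S <- model$Q * outer(d, 1 / d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, d = d)
}

#' Codon transition probabilities
#'
#' Computes `P(t) = exp(Qt)` for a [gy94_model()] by spectral decomposition
#' of the reversible rate matrix.
#'
#' @param model A `gy94_model`.
#' @param t Divergence in expected substitutions per codon (>= 0).
#' @param eig Optional precomputed decomposition from an internal cache.
#' @return 61 x 61 row-stochastic matrix of transition probabilities.
#' @export
gy94_pmat <- function(model, t, eig = NULL) {
  if (t < 0) abort_("t must be >= 0")
  if (is.null(eig)) eig <- gy94_eigen(model)
  inner <- eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))
  P <- (1 / eig$d) * inner * rep(eig$d, each = length(eig$d))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(model$Q)
  P
}

# Ks and Ka implied by total divergence t under the model: Ks is the
# synonymous substitution count per codon (t * rho_syn) divided by the number
# of synonymous sites per codon, defined as 3 times the synonymous flux
# fraction of the neutral (omega = 1) model with the same pi and kappa.
gy94_ks_ka <- function(t, pi, kappa, omega) {
  m <- gy94_model(pi, kappa, omega)
  m1 <- gy94_model(pi, kappa, 1)
  rho <- m$rho_syn
  rho1 <- m1$rho_syn
  list(
    ks = t * rho / (3 * rho1),
    ka = t * (1 - rho) / (3 * (1 - rho1))
  )
}

# Total divergence t that yields a model-expected Ks of ks_target.
gy94_t_for_ks <- function(ks_target, pi, kappa, omega) {
  if (ks_target < 0) abort_("ks_target must be >= 0")
  unit <- gy94_ks_ka(1, pi, kappa, omega)$ks
  if (unit <= 0) abort_("model has no synonymous flux; ks_target unattainable")
  ks_target / unit
}
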