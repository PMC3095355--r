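test_that("zero divergence yields identical stop-free in-frame sequences", {
  p <- simulate_codon_pair(50, 0, seed = 7)
  expect_identical(p$cds[1], p$cds[2])
  for (s in p$cds) {
    expect_equal(nchar(s) %% 3, 0)
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("simulated pairs carry the target synonymous divergence", {
  # counting oracle on one simulated pair
  p <- simulate_codon_pair(500, 0.5, kappa = 2, omega = 0.2, seed = 1)
  aln <- codon_align(p$cds[1], p$cds[2])
  ds <- ng86_ks(aln)$ks
  expect_gt(ds, 0.35)
  expect_lt(ds, 0.65)
  # deeper calibration: the downstream ML estimate is unbiased on average
  est <- vapply(1:20, function(s) {
    q <- simulate_codon_pair(300, 0.185, seed = s)
    a <- codon_align(q$cds[1], q$cds[2])
    fit_pair_ml(a, n_restarts = 2, pair_id = paste0("cal", s))$ks
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.185), 0.08)
})

test_that("simulation is deterministic in the seed and errors on bad input", {
  a <- simulate_codon_pair(30, 0.4, seed = 11)
  b <- simulate_codon_pair(30, 0.4, seed = 11)
  expect_identical(a, b)
  expect_error(simulate_codon_pair(5, 0.1), "n_codons")
  expect_error(simulate_codon_pair(50, -1), "ks_target")
})

test_that("age samples match their truncated-mixture moments", {
  cfg_exp <- sim_config(
    seed = 1, w_exp = 1,
    components = tibble::tibble(mean = numeric(), variance = numeric(),
                                weight = numeric())
  )
  x <- simulate_age_sample(1e5, cfg_exp, seed = 3)
  m_expect <- truncated_exp_mean(1.892, 2)
  expect_lt(abs(mean(x$age) - m_expect) / m_expect, 0.01)
  expect_true(all(x$age > 0 & x$age <= 2))

  cfg_norm <- sim_config(
    seed = 1, w_exp = 0,
    components = tibble::tibble(mean = 0.185, variance = 0.08^2, weight = 1)
  )
  y <- simulate_age_sample(1e5, cfg_norm, seed = 4)
  expect_lt(abs(median(y$age) - 0.185), 0.01)

  expect_error(simulate_age_sample(0, sim_config()), "n must be")
})

test_that("mixture component labels follow the configured weights", {
  cfg <- sim_config(seed = 1)
  p <- c(cfg$w_exp, cfg$components$weight)
  # labels are assigned before in-component truncation, so raw weights
  # apply; the chi-square check has a 1% false-rejection rate per sample,
  # so require agreement on at least 4 of 5 independent samples
  rejected <- vapply(1:5, function(s) {
    x <- simulate_age_sample(1e5, cfg, seed = s)
    obs <- table(factor(x$component, levels = 0:2))
    stats::chisq.test(obs, p = p)$p.value < 0.01
  }, logical(1))
  expect_lte(sum(rejected), 1)
})

test_that("family sizes follow the discrete power law", {
  s1 <- simulate_family_sizes(1, 2.35, 2, 250, seed = 1)
  expect_length(s1, 1)
  expect_true(s1 >= 2 && s1 <= 250)
  # near-infinite exponent concentrates all mass at the minimum size
  s_inf <- simulate_family_sizes(200, 50, 2, 250, seed = 2)
  expect_true(all(s_inf == 2))
  sizes <- simulate_family_sizes(2000, 2.35, 2, 250, seed = 3)
  fit <- fit_powerlaw(sizes)
  expect_lt(abs(fit$b - 2.35), 0.15)
})

test_that("expression counts encode the planted co-regulation classes", {
  genes <- tibble::tibble(
    id = sprintf("F%03d_g%d", rep(1:30, each = 2), rep(1:2, 30)),
    family = sprintf("F%03d", rep(1:30, each = 2))
  )
  pairs <- tibble::tibble(
    gene_a = genes$id[seq(1, 60, 2)],
    gene_b = genes$id[seq(2, 60, 2)]
  )
  cfg <- sim_config(seed = 1, coregulated_fraction = 0.5,
                    tissue_shifted_fraction = 0.2,
                    library_sizes = 50000L)
  sim <- simulate_expression(genes, pairs, cfg, seed = 9)
  expect_setequal(sim$truth$class,
                  c("coregulated", "divergent", "tissue-shifted"))
  prof <- expression_profiles(sim$counts, min_total = 3)
  pr <- pearson_divergence(pairs, prof)
  joined <- dplyr::inner_join(pr, sim$truth, by = c("gene_a", "gene_b"))
  co <- joined$r[joined$class == "coregulated" & !is.na(joined$r)]
  # shared latent profile at deep sampling: correlation near 1
  expect_gt(median(co), 0.9)
  shifted <- joined$r[joined$class == "tissue-shifted" & !is.na(joined$r)]
  expect_lt(median(shifted), 0.3)
})

test_that("a full simulated dataset is internally consistent", {
  cfg <- sim_config(seed = 2, n_families = 25, n_codons = 60,
                    size_range = c(2L, 6L))
  ds <- simulate_dataset(cfg)
  # every gene in the pair truth exists in the gene table
  expect_true(all(c(ds$true_pair_ks$gene_a, ds$true_pair_ks$gene_b) %in%
                    ds$genes$id))
  # family labels agree with pair-truth connectivity
  fam_of <- setNames(ds$genes$family, ds$genes$id)
  expect_true(all(fam_of[ds$true_pair_ks$gene_a] ==
                    fam_of[ds$true_pair_ks$gene_b]))
  # sequences are in frame and stop-free
  codons <- unlist(lapply(ds$genes$cds, function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  # byte-identical regeneration from the same config
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$genes, ds2$genes)
  expect_identical(ds$true_pair_ks, ds2$true_pair_ks)
  expect_identical(ds$expression$counts, ds2$expression$counts)
})

test_that("dataset sequences carry the ultrametric Ks truth", {
  ds <- simulate_dataset(sim_config(seed = 31, n_families = 6,
                                    n_codons = 400, size_range = c(2L, 4L)))
  pairs <- dplyr::filter(ds$true_pair_ks, ks <= 1.2)
  pairs <- utils::head(pairs, 6)
  est <- estimate_ks(dplyr::mutate(pairs, ks_eligible = TRUE), ds$genes,
                     n_restarts = 2, seed = 1)
  cmp <- dplyr::inner_join(pairs, est, by = c("gene_a", "gene_b"),
                           suffix = c("_true", "_ml"))
  expect_gt(cor(cmp$ks_true, cmp$ks_ml), 0.9)
  expect_lt(abs(mean(cmp$ks_ml - cmp$ks_true)), 0.1)
})

test_that("dataset writer produces the plain-text pipeline inputs", {
  cfg <- sim_config(seed = 3, n_families = 5, n_codons = 40,
                    size_range = c(2L, 3L))
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  files <- write_dataset(ds, dir)
  expect_true(all(file.exists(files)))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "cds.fasta"))
  expect_setequal(names(fa), ds$genes$id)
  counts <- readr::read_tsv(file.path(dir, "est_counts.tsv"),
                            show_col_types = FALSE)
  expect_equal(nrow(counts), nrow(ds$genes))
})
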