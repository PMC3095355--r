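toy_counts <- function() {
  tibble::tibble(
    gene = c("gA", "gB", "gC", "gD", "gE"),
    !!!setNames(as.data.frame(rbind(
      c(5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),   # gA single-library
      c(0, 7, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),   # gB disjoint support
      c(2, 4, 6, 8, 2, 4, 6, 8, 2, 4, 6, 8, 2, 4),   # gC
      c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2, 3, 4, 1, 2),   # gD proportional to gC
      c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)    # gE below the filter
    )), paste0("lib", 1:14))
  )
}

test_that("profiles are frequency-normalized and filtered at 3 ESTs", {
  prof <- expression_profiles(toy_counts())
  expect_setequal(prof$kept, c("gA", "gB", "gC", "gD"))
  # per-library normalization: frequencies are counts per 10,000 library ESTs
  expect_equal(unname(prof$freq["gA", "lib1"]), 5 / 9 * 1e4)
})

test_that("pair correlations match closed forms on indicator profiles", {
  prof <- expression_profiles(toy_counts())
  pairs <- tibble::tibble(gene_a = c("gA", "gC", "gA"),
                          gene_b = c("gB", "gD", "gE"))
  pr <- pearson_divergence(pairs, prof)
  # disjoint single-library supports over 14 libraries: r = -1/13
  expect_equal(pr$r[1], -1 / 13, tolerance = 1e-10)
  # proportional profiles: r = 1
  expect_equal(pr$r[2], 1, tolerance = 1e-10)
  # gE fails the EST filter
  expect_equal(pr$flag[3], "low_count")
  expect_true(is.na(pr$r[3]))
})

test_that("the null threshold matches the analytic 14-point percentile", {
  # i.i.d. standard-normal profiles: the Pearson r of two independent
  # 14-vectors has r*sqrt(12/(1-r^2)) ~ t(12); 95th percentile ~ 0.458
  counts <- withr::with_seed(11, {
    m <- matrix(abs(rnorm(400 * 14, mean = 6)), 400, 14)
    tibble::as_tibble(as.data.frame(m)) |>
      setNames(paste0("lib", 1:14)) |>
      dplyr::mutate(gene = paste0("n", 1:400), .before = 1)
  })
  prof <- expression_profiles(counts, min_total = 0)
  r_star <- null_threshold(prof, n_random_pairs = 2e4, seed = 12)
  t95 <- stats::qt(0.95, 12)
  analytic <- t95 / sqrt(12 + t95^2)
  expect_lt(abs(as.numeric(r_star) - analytic), 0.03)
  # alpha = 0 returns the maximum of the null sample
  r_max <- null_threshold(prof, n_random_pairs = 1000, alpha = 0,
                          seed = 12)
  expect_equal(as.numeric(r_max), max(attr(r_max, "null_r")))
})

test_that("null-threshold coverage is calibrated at 5%", {
  counts <- withr::with_seed(13, {
    m <- matrix(rpois(600 * 14, lambda = 20), 600, 14)
    tibble::as_tibble(as.data.frame(m)) |>
      setNames(paste0("lib", 1:14)) |>
      dplyr::mutate(gene = paste0("n", 1:600), .before = 1)
  })
  prof <- expression_profiles(counts)
  r_star <- null_threshold(prof, n_random_pairs = 2e4, seed = 14)
  fresh <- attr(null_threshold(prof, n_random_pairs = 2e4, seed = 15),
                "null_r")
  coverage <- mean(fresh >= as.numeric(r_star))
  expect_gt(coverage, 0.04)
  expect_lt(coverage, 0.06)
})

test_that("divergent fractions stratify by age and handle empty strata", {
  pair_r <- tibble::tibble(r = c(1, 1, 1), ks = c(0.2, 0.5, 1.0))
  fr <- divergent_fractions(pair_r, r_star = 0.78)
  expect_equal(c(fr$overall, fr$young, fr$old), c(0, 0, 0))
  only_young <- divergent_fractions(
    tibble::tibble(r = c(0.1, 0.9), ks = c(0.1, 0.2)), 0.78)
  expect_true(is.na(only_young$old))
  expect_equal(only_young$young, 0.5)
})

test_that("r and Ks are uncorrelated when simulated independently", {
  d <- withr::with_seed(17, {
    tibble::tibble(r = runif(5000, -1, 1), ks = runif(5000, 0, 2))
  })
  fr <- divergent_fractions(d, r_star = 0.78)
  expect_lt(abs(fr$r_ks_correlation), 0.05)
})

test_that("tissue-shift tests match hypergeometric enumeration", {
  counts <- tibble::tibble(
    gene = c("fr", "veg", "flat1", "flat2", "tiny1", "tiny2"),
    !!!setNames(as.data.frame(rbind(
      c(10, 10, 0, 0, 0, 0, 0, 0),   # all 20 in fruit libs
      c(0, 0, 10, 10, 0, 0, 0, 0),   # all 20 in vegetative libs
      c(2, 2, 2, 2, 2, 2, 2, 2),
      c(3, 3, 3, 3, 3, 3, 3, 3),
      c(1, 0, 0, 0, 0, 0, 0, 0),
      c(0, 1, 0, 0, 0, 0, 0, 0)
    )), paste0("lib", 1:8))
  )
  tmap <- tibble::tibble(
    library = paste0("lib", 1:8),
    tissue = rep(c("fruit", "vegetative", "reproductive", "vascular"),
                 each = 2)
  )
  prof <- expression_profiles(counts, min_total = 0)
  res <- tissue_specificity("fr", "veg", prof, tmap)
  fruit_p <- res$p_value[res$tissue == "fruit"]
  expect_equal(fruit_p, 2 / choose(40, 20), tolerance = 1e-10)
  expect_true(attr(res, "shifted"))
  expect_equal(res$direction[res$tissue == "fruit"], "fr")

  flat <- tissue_specificity("flat1", "flat2", prof, tmap)
  expect_true(all(flat$p_value > 0.999))
  expect_false(attr(flat, "shifted"))

  low <- tissue_specificity("tiny1", "tiny2", prof, tmap)
  expect_equal(attr(low, "flag"), "low_count")
  expect_true(is.na(attr(low, "shifted")))
})

test_that("planted subfunctionalization is detected at depth", {
  tmap <- tibble::tibble(
    library = paste0("lib", 1:8),
    tissue = rep(c("fruit", "vegetative", "reproductive", "vascular"),
                 each = 2)
  )
  detected <- withr::with_seed(19, {
    vapply(1:20, function(i) {
      # disjoint class supports, >= 20 ESTs per gene
      # pa lives in fruit+vegetative libraries, pb in the other classes
      a <- c(stats::rmultinom(1, 25, rep(1 / 4, 4))[, 1], rep(0, 4))
      b <- c(rep(0, 4), stats::rmultinom(1, 25, rep(1 / 4, 4))[, 1])
      counts <- tibble::tibble(
        gene = c("pa", "pb"),
        !!!setNames(as.data.frame(rbind(a, b)), paste0("lib", 1:8))
      )
      prof <- expression_profiles(counts, min_total = 0)
      isTRUE(attr(tissue_specificity("pa", "pb", prof, tmap), "shifted"))
    }, logical(1))
  })
  expect_gte(sum(detected), 18)
})
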