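test_that("single-linkage families are the components of the pair graph", {
  pairs <- tibble::tibble(gene_a = c("A", "B", "X"),
                          gene_b = c("B", "C", "Y"))
  cl <- cluster_families(pairs)
  expect_equal(nrow(cl$families), 2)
  fam_abc <- cl$membership$family_id[cl$membership$gene == "A"]
  expect_setequal(cl$membership$gene[cl$membership$family_id == fam_abc],
                  c("A", "B", "C"))
  expect_equal(nrow(cluster_families(pairs[0, ])$families), 0)
})

test_that("duplication events equal the pair-graph spanning forest size", {
  ds <- simulate_dataset(sim_config(seed = 5, n_families = 40,
                                    size_range = c(2L, 8L)),
                         sequences = FALSE)
  cl <- cluster_families(ds$true_pair_ks)
  g <- igraph::graph_from_data_frame(
    ds$true_pair_ks[, c("gene_a", "gene_b")], directed = FALSE)
  forest_edges <- igraph::vcount(g) - igraph::components(g)$no
  expect_equal(sum(cl$families$n - 1), forest_edges)
})

test_that("node dating averages the redundant pairwise ages of one event", {
  # two-gene family: one node at its Ks
  nodes <- date_duplications(c("A", "B"),
                             tibble::tibble(gene_a = "A", gene_b = "B",
                                            ks = 0.3))
  expect_equal(nodes$age_ks, 0.3)
  # hand-derived UPGMA on a triple: merge A-B at 0.1, then C at mean 0.5
  ks3 <- tibble::tibble(gene_a = c("A", "A", "B"),
                        gene_b = c("B", "C", "C"),
                        ks = c(0.1, 0.5, 0.5))
  nodes3 <- date_duplications(c("A", "B", "C"), ks3)
  expect_equal(sort(nodes3$age_ks), c(0.1, 0.5))
  expect_error(date_duplications("A", ks3), ">= 2 members")
})

test_that("imputed Ks holds the dendrogram together but never dates nodes", {
  # A-B observed young, C attaches with only one observed old value;
  # the missing A-C entry is imputed for linkage but the C-merge age must
  # average only the observed B-C value
  ks <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C"),
                       ks = c(0.1, 0.8))
  nodes <- date_duplications(c("A", "B", "C"), ks)
  expect_equal(sort(nodes$age_ks), c(0.1, 0.8))
  expect_true(all(nodes$age_observed))
})

test_that("node ages recover the simulated duplication-age distribution", {
  ds <- simulate_dataset(sim_config(seed = 8, n_families = 500,
                                    size_range = c(2L, 12L)),
                         sequences = FALSE)
  cl <- cluster_families(ds$true_pair_ks)
  nodes <- date_all_families(cl, ds$true_pair_ks)
  expect_equal(nrow(nodes), nrow(ds$true_ages))
  d <- suppressWarnings(
    stats::ks.test(nodes$age_ks, ds$true_ages$age)$statistic
  )
  expect_lt(unname(d), 0.1)
})

test_that("young subsets and amplification ratios follow the printed rules", {
  nodes <- tibble::tibble(family_id = c("F1", "F1", "F2"),
                          age_ks = c(0.2, 1.5, 0.6))
  ks <- tibble::tibble(gene_a = c("A", "A", "C"),
                       gene_b = c("B", "B2", "D"),
                       ks = c(0.2, 1.5, 0.6))
  ys <- young_subset(ks, nodes, cutoff = 0.4)
  expect_equal(ys$d_young$d_young[ys$d_young$family_id == "F1"], 1)
  expect_equal(ys$d_young$d_young[ys$d_young$family_id == "F2"], 0)
  expect_equal(nrow(ys$young_clustering$families), 1)

  expect_equal(amplification_ratio(6, 5)$ratio, 6.00)
  expect_equal(amplification_ratio(18, 8)$ratio, 1.80)
  expect_equal(amplification_ratio(7, 0)$ratio, 1.00)
  expect_error(amplification_ratio(5, 5), "smaller than")
})

test_that("the power-law fit is exact on noiseless log-linear classes", {
  classes <- tibble::tibble(size = 2:20, frequency = 100 * (2:20)^-2)
  fit <- fit_powerlaw(classes, method = "ols")
  expect_equal(fit$b, 2, tolerance = 1e-10)
  expect_equal(fit$a, 100, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_powerlaw(rep(3L, 10)), "single size class")
  td <- tidy(fit)
  expect_setequal(td$term, c("a", "b"))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("family sizes compare against a reference by correlation", {
  tbl <- tibble::tibble(family = c("f1", "f2", "f3"), n = c(10, 6, 3))
  same <- compare_sizes(tbl, tbl)
  expect_equal(same$correlation, 1)
  anti <- compare_sizes(tbl, tibble::tibble(family = c("f1", "f2", "f3"),
                                            n = c(1, 5, 9)))
  expect_lt(anti$correlation, 0)
  # every amplified family is strictly larger than its Arabidopsis size
  amp <- amplified_families()
  cmp <- compare_sizes(
    dplyr::select(amp, family, n = apple),
    dplyr::select(amp, family, n = arabidopsis)
  )
  expect_equal(nrow(cmp$joined), 17)
  expect_true(all(cmp$joined$larger))
})
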