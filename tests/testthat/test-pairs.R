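test_that("hit loading removes self-hits and collapses reciprocals", {
  rows <- tibble::tibble(
    query = c("gA", "gA", "gB", "gC"),
    subject = c("gA", "gB", "gA", "gD"),
    pct = c(100, 80, 80, 45), len = c(200, 150, 150, 120),
    evalue = c(0, 1e-50, 1e-48, 1e-10), bits = c(400, 200, 195, 80)
  )
  hits <- load_hits(write_hit_file(rows))
  expect_equal(nrow(hits), 2)
  ab <- dplyr::filter(hits, gene_a == "gA", gene_b == "gB")
  expect_equal(ab$evalue, 1e-50)

  empty <- load_hits(write_hit_file(rows[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("malformed hit rows are rejected with their line number", {
  path <- tempfile()
  writeLines(c(
    "gA\tgB\t90\t100\t0\t0\t1\t100\t1\t100\t1e-20\t100",
    "gA\tgC\tbroken"
  ), path)
  expect_error(load_hits(path), "line 2")
  writeLines(c("gA\tgB\t90\tnot_a_number\t0\t0\t1\t100\t1\t100\t1e-20\t100"),
             path)
  expect_error(load_hits(path), "line 1")
})

test_that("paralog filters apply the exact length and identity boundaries", {
  rows <- tibble::tibble(
    query = c("g1", "g3", "g5", "g7"),
    subject = c("g2", "g4", "g6", "g8"),
    pct = c(80, 30.0, 61, 45), len = c(99, 100, 150, 150),
    evalue = rep(1e-30, 4), bits = rep(150, 4)
  )
  hits <- load_hits(write_hit_file(rows))
  called <- call_paralogs(hits, gene_ids = paste0("g", 1:9))
  # 99 aa rejected (< 100); 30.0% rejected (strict >30); 61%/150aa accepted
  expect_setequal(paste(called$pairs$gene_a, called$pairs$gene_b),
                  c("g5 g6", "g7 g8"))
  expect_true(called$pairs$ks_eligible[called$pairs$gene_a == "g5"])
  expect_false(called$pairs$ks_eligible[called$pairs$gene_a == "g7"])
  # partition: every gene is in a pair or a singlet, never both
  in_pairs <- unique(c(called$pairs$gene_a, called$pairs$gene_b))
  expect_setequal(c(in_pairs, called$singlets), paste0("g", 1:9))
  expect_length(intersect(in_pairs, called$singlets), 0)
})

test_that("raising the identity threshold never enlarges the paralog set", {
  rows <- tibble::tibble(
    query = sprintf("q%d", 1:20), subject = sprintf("s%d", 1:20),
    pct = seq(31, 88, by = 3), len = rep(120, 20),
    evalue = rep(1e-30, 20), bits = rep(150, 20)
  )
  hits <- load_hits(write_hit_file(rows))
  sets <- lapply(c(30, 45, 60, 75), function(th) {
    p <- call_paralogs(hits, min_pct_id = th)$pairs
    paste(p$gene_a, p$gene_b)
  })
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("the built-in aligner reports identities like a local search", {
  prot <- random_protein(180, seed = 5)
  genes <- tibble::tibble(id = c("dup1", "dup2"), protein = c(prot, prot))
  hits <- align_all_vs_all(genes)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$pct_identity, 100)
  expect_gte(hits$aln_length, 180)

  # unrelated random proteins must not pass the paralog filters
  n_pass <- 0L
  for (s in 1:100) {
    g <- tibble::tibble(
      id = c("r1", "r2"),
      protein = c(random_protein(150, seed = 1000 + s),
                  random_protein(150, seed = 5000 + s))
    )
    h <- call_paralogs(align_all_vs_all(g), gene_ids = g$id)$pairs
    n_pass <- n_pass + (nrow(h) > 0)
  }
  expect_lte(n_pass, 5)

  # a protein against its own reversal: no long qualifying alignment
  for (s in 1:10) {
    p <- random_protein(150, seed = 200 + s)
    g <- tibble::tibble(
      id = c("fwd", "rev"),
      protein = c(p, paste(rev(strsplit(p, "")[[1]]), collapse = ""))
    )
    h <- align_all_vs_all(g)
    if (nrow(h) > 0) expect_lt(h$aln_length, 100)
  }
})

test_that("zero-Ks components are reduced to a single representative", {
  ks <- tibble::tibble(
    gene_a = c("gA", "gB", "gD", "gX"),
    gene_b = c("gB", "gC", "gA", "gY"),
    ks = c(0, 0, 0.25, 0.01)
  )
  out <- dedupe_zero_ks(ks)
  # A-B and B-C at Ks=0 form one component: keep only gA
  expect_setequal(out$removed_genes, c("gB", "gC"))
  expect_setequal(out$representatives, "gA")
  # pairs touching removed genes are gone; Ks=0.01 pair survives
  expect_setequal(paste(out$kept$gene_a, out$kept$gene_b),
                  c("gD gA", "gX gY"))
})
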