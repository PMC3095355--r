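# in-code fixtures shared across test files

# write a BLAST-tabular hit file from a tibble of minimal fields
write_hit_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    paste(r$query, r$subject, r$pct, r$len, 0, 0, 1, r$len, 1, r$len,
          r$evalue, r$bits, sep = "\t")
  }, "")
  writeLines(lines, path)
  path
}

# tiny ontology: root a <- b <- c, plus d with two parents (b, a)
write_mini_obo <- function(path = tempfile(fileext = ".obo"),
                           with_cycle = FALSE, with_obsolete = FALSE) {
  stanza <- function(id, name, parents = character(), part_of = character(),
                     obsolete = FALSE) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      paste0("is_a: ", parents, " ! x"),
      paste0("relationship: part_of ", part_of, " ! y"),
      if (obsolete) "is_obsolete: true", "")
  }
  lines <- c(
    "format-version: 1.2", "",
    stanza("GO:0000001", "root"),
    stanza("GO:0000002", "mid", parents = "GO:0000001"),
    stanza("GO:0000003", "leaf", parents = "GO:0000002"),
    stanza("GO:0000004", "dual", parents = "GO:0000002",
           part_of = "GO:0000001")
  )
  if (with_cycle) {
    lines <- c(lines, stanza("GO:0000005", "cyc1", parents = "GO:0000006"),
               stanza("GO:0000006", "cyc2", parents = "GO:0000005"))
  }
  if (with_obsolete) {
    lines <- c(lines, stanza("GO:0000009", "gone", obsolete = TRUE))
  }
  writeLines(lines, path)
  path
}

# deterministic random protein of length n
random_protein <- function(n, seed) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, paste(sample(aa, n, replace = TRUE), collapse = ""))
}

# closed-form mean of an exponential truncated to (0, upper]
truncated_exp_mean <- function(rate, upper) {
  1 / rate - upper * exp(-rate * upper) / (1 - exp(-rate * upper))
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
# (minimum-likelihood method): sum of P(tables) no more probable than observed
brute_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b
  c1 <- a + c_
  n <- a + b + c_ + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
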