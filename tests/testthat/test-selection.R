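test_that("universe enumeration matches a full independent enumeration", {
  # single-codon gene: every change of ATG is missense, flat weights
  g <- coding_gene("M", "ATG")
  uni <- build_universe(g, flat_signature())
  expect_equal(nrow(uni), 9L)
  expect_equal(uni$weight, rep(1 / 9, 9))
  expect_true(all(uni$ref_aa == "M"))

  # degenerate signature: only entries in the favoured context keep weight
  gene <- random_coding_gene(40, seed = 2)
  sig1 <- mutational_signature(replace(rep(0, 96), 40, 1))  # one channel
  uni1 <- build_universe(gene, sig1)
  expect_true(all(uni1$channel[uni1$weight > 0] == 40L))

  # 30-codon gene: weights equal an independent enumeration oracle
  gene2 <- random_coding_gene(30, seed = 6)
  sig <- random_signature(31)
  uni2 <- build_universe(gene2, sig)
  seqc <- strsplit(gene2$cds, "")[[1]]
  L <- length(seqc)
  keys <- character(0); w <- numeric(0)
  gc <- Biostrings::GENETIC_CODE
  for (pos in seq_len(L)) {
    ci <- (pos - 1) %/% 3
    codon <- paste(seqc[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
    for (alt in setdiff(c("A", "C", "G", "T"), seqc[pos])) {
      mut <- codon
      substr(mut, (pos - 1) %% 3 + 1, (pos - 1) %% 3 + 1) <- alt
      a1 <- unname(gc[codon]); a2 <- unname(gc[mut])
      if (a1 != a2 && a2 != "*" && a1 != "*") {
        f5 <- if (pos == 1) gene2$flank5 else seqc[pos - 1]
        f3 <- if (pos == L) gene2$flank3 else seqc[pos + 1]
        lab <- oracle_channel_label(f5, seqc[pos], f3, alt)
        keys <- c(keys, paste(pos, alt))
        w <- c(w, as.numeric(sig)[match(lab, signature_channels())])
      }
    }
  }
  w <- w / sum(w)
  got <- uni2$weight[match(keys, paste(uni2$cds_position, uni2$alt_base))]
  expect_equal(got, w, tolerance = 1e-12)
})

test_that("Monte-Carlo selection test honours its conventions and exact limits", {
  gene <- random_coding_gene(25, seed = 3)
  uni <- build_universe(gene, flat_signature())
  obs <- uni[1:5, ]

  const <- monte_carlo_selection_test(obs, uni, function(p, r, a) rep(5, length(p)),
                                      n_permutations = 100, seed = 1)
  expect_equal(const$p_value, 1)
  expect_equal(const$effect_size, 0)

  # determinism: identical seeds give identical results
  met <- function(p, r, a) p
  r1 <- monte_carlo_selection_test(obs, uni, met, n_permutations = 500, seed = 7)
  r2 <- monte_carlo_selection_test(obs, uni, met, n_permutations = 500, seed = 7)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$permutation_stats, r2$permutation_stats)

  # coverage failures are hard errors
  bad <- tibble::tibble(protein_position = 999L, ref_aa = "A", alt_aa = "V")
  expect_error(monte_carlo_selection_test(bad, uni, met), "absent from the universe")
  expect_error(
    monte_carlo_selection_test(obs, uni,
                               tibble::tibble(protein_position = 1L, value = 1)),
    "does not cover")

  # n_observed = 1 on a 3-entry universe: p matches exhaustive enumeration
  u3 <- tibble::tibble(cds_position = 1:3, ref_base = "A", alt_base = "C",
                       protein_position = 1:3, ref_aa = c("K", "L", "M"),
                       alt_aa = "A", channel = 1L,
                       weight = c(0.8, 0.1, 0.1))
  class(u3) <- c("mutation_universe", class(u3))
  met3 <- tibble::tibble(protein_position = 1:3, ref_aa = c("K", "L", "M"),
                         alt_aa = "A", value = c(1, 2, 10))
  r <- monte_carlo_selection_test(u3[3, ], u3, met3, n_permutations = 100000,
                                  seed = 5, tail = "upper")
  p_exact <- 0.1  # total weight of entries with metric >= 10
  expect_lt(abs(r$p_value - p_exact), 2 * sqrt(p_exact * (1 - p_exact) / 100000))
})

test_that("dN/dS estimation handles boundaries and recovers neutral cohorts", {
  sig <- random_signature(42)
  gene <- random_coding_gene(60, seed = 4)

  # all observed synonymous: ratio 0 on the fallback-free path
  enum <- classify_consequence(gene, rep(seq_len(nchar(gene$cds)), each = 3),
                               rep(strsplit(gene$cds, "")[[1]], each = 3),
                               unlist(lapply(strsplit(gene$cds, "")[[1]],
                                             function(b) setdiff(c("A","C","G","T"), b))))
  syn <- enum[enum$consequence == "synonymous", ][1:5, ]
  d0 <- dnds_estimate(syn, gene, sig)
  expect_equal(d0$obs_N, 0L)
  expect_equal(d0$ratio, 0)
  expect_false(d0$fallback)

  # no synonymous observed: flagged pseudo-count fallback
  mis <- enum[enum$consequence == "missense", ][1:5, ]
  expect_warning(dF <- dnds_estimate(mis, gene, sig), "fallback")
  expect_true(dF$fallback)
  expect_true(is.finite(dF$ratio))

  # neutral simulation: mean log2 ratio near 0 (200 genes)
  coh <- make_dnds_cohort(200, 120, sig, omega = 1, mutations_per_gene = 50,
                          seed = 17)
  l2 <- vapply(names(coh$genes), function(nm) {
    dnds_estimate(coh$mutations[coh$mutations$gene == nm, ],
                  coh$genes[[nm]], sig)$log2_ratio
  }, numeric(1))
  expect_lt(abs(mean(l2)), 0.1)
})

test_that("NMC calls clusters only when positions are improbably tight", {
  expect_equal(nrow(nmc_clusters(42, 380)), 0L)

  # a tight planted cluster is called, and calls are well-formed
  set.seed(8)
  pos <- c(rep(201, 6), 202, 203, sample.int(400, 20, replace = TRUE))
  calls <- nmc_clusters(pos, 400)
  expect_gt(nrow(calls), 0)
  expect_true(any(calls$start_residue <= 203 & calls$end_residue >= 201))
  expect_true(all(calls$start_residue <= calls$end_residue))
  expect_true(all(calls$corrected_p <= 0.05))

  # widely spread positions yield nothing
  expect_equal(nrow(nmc_clusters(c(10, 110, 210, 310), 400)), 0L)
  expect_error(nmc_clusters(c(0, 5), 10), "within")
})
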