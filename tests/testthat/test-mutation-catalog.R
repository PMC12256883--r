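test_that("mutation tables are read per dialect and bad rows go to rejects", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tsample\tcds_pos\tref\talt",
               "WNT5A\tS1\t928\tG\tA",
               "WNT5A\tS2\t100\tC\tT",
               "WNT1\tS3\t55\tA\tG"), f)
  rec <- read_mutation_table(f, "simple_tsv")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$cds_position, c(928L, 100L, 55L))
  expect_equal(nrow(mutation_rejects(rec)), 0L)

  g <- tempfile(fileext = ".tsv")
  writeLines(c("GENE_SYMBOL\tSAMPLE_NAME\tMUTATION_CDS\tMUTATION_AA\tPRIMARY_SITE",
               "WNT5A\tT1\tc.928G>A\tp.V310M\tlarge_intestine",
               "WNT5A\tT2\tc.100_102del\tp.?\tlarge_intestine"), g)
  rec2 <- read_mutation_table(g, "cosmic_export")
  expect_equal(nrow(rec2), 1L)
  expect_equal(rec2$protein_change, "V310M")
  rej <- mutation_rejects(rec2)
  expect_equal(nrow(rej), 1L)
  expect_match(rej$reason, "unparseable")

  expect_error(read_mutation_table(f, "maf_like"), "missing mandatory column")
})

test_that("generated cohorts round-trip through the simple_tsv reader", {
  gene <- random_coding_gene(80, seed = 3, gene = "GENE1")
  sig <- random_signature(5)
  coh <- make_mutation_cohort(gene, sig, 500, seed = 21)
  f <- tempfile(fileext = ".tsv")
  write_simple_tsv(coh, f)
  back <- read_mutation_table(f, "simple_tsv")
  expect_equal(back$gene, coh$gene)
  expect_equal(back$cds_position, coh$cds_position)
  expect_equal(back$ref_base, coh$ref_base)
  expect_equal(back$alt_base, coh$alt_base)
  ann <- annotate_mutations(back, gene)
  expect_equal(ann$protein_change, coh$protein_change)
})

test_that("consequence calls agree with whole-CDS translation for every substitution", {
  # direct examples: ATG GCT ..., position 4 C>T is GCT->GTT (A2V)
  g <- coding_gene("EX", "ATGGCTAAAGAT")
  one <- classify_consequence(g, 5, "C", "T")
  expect_equal(one$consequence, "missense")
  expect_equal(one$protein_change, "A2V")
  syn <- classify_consequence(g, 6, "T", "C")  # GCT -> GCC, still Ala
  expect_equal(syn$consequence, "synonymous")
  expect_error(classify_consequence(g, 4, "C", "T"), "reference mismatch")

  # exhaustive brute-force oracle: mutate the full CDS, translate with
  # Biostrings, and diff the protein
  gene <- random_coding_gene(30, seed = 11)
  L <- nchar(gene$cds)
  wt_aa <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(gene$cds))), "")[[1]]
  for (pos in seq_len(L)) {
    ref <- substr(gene$cds, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      mut_cds <- gene$cds
      substr(mut_cds, pos, pos) <- alt
      mut_aa <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(mut_cds), no.init.codon = TRUE)), "")[[1]]
      got <- classify_consequence(gene, pos, ref, alt)
      changed <- which(wt_aa != mut_aa)
      want <- if (length(changed) == 0) "synonymous"
              else if (mut_aa[changed] == "*") "nonsense"
              else "missense"
      expect_equal(got$consequence, want)
      expect_equal(got$protein_position, (pos - 1) %/% 3 + 1)
      if (length(changed)) expect_equal(got$alt_aa, mut_aa[changed])
    }
  }
})

test_that("trinucleotide channels collapse strands and match an independent labeller", {
  g <- coding_gene("CTX", "ACGTAG" , flank5 = "T", flank3 = "C")
  ch <- trinucleotide_context(g, 2, "C", "T")
  expect_equal(names(ch), "A[C>T]G")

  # strand-collapse symmetry over all 192 raw substitution contexts
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (f5 in bases) for (ref in bases) for (f3 in bases) {
    for (alt in setdiff(bases, ref)) {
      g1 <- coding_gene("x", paste0(f5, ref, f3))
      ch1 <- trinucleotide_context(g1, 2, ref, alt)
      rc <- paste0(comp[[f3]], comp[[ref]], comp[[f5]])
      g2 <- coding_gene("y", rc)
      ch2 <- trinucleotide_context(g2, 2, comp[[ref]], comp[[alt]])
      expect_equal(as.integer(ch1), as.integer(ch2))
      expect_equal(names(ch1), oracle_channel_label(f5, ref, f3, alt))
    }
  }

  # channel tallies over a whole gene equal an independent enumeration
  gene <- random_coding_gene(33, seed = 9)
  seqc <- strsplit(gene$cds, "")[[1]]
  L <- length(seqc)
  want <- integer(96)
  for (pos in seq_len(L)) {
    f5 <- if (pos == 1) gene$flank5 else seqc[pos - 1]
    f3 <- if (pos == L) gene$flank3 else seqc[pos + 1]
    for (alt in setdiff(bases, seqc[pos])) {
      lab <- oracle_channel_label(f5, seqc[pos], f3, alt)
      i <- match(lab, signature_channels())
      want[i] <- want[i] + 1L
    }
  }
  pos <- rep(seq_len(L), each = 3)
  alts <- unlist(lapply(seqc, function(b) setdiff(bases, b)))
  got <- tabulate(trinucleotide_context(gene, pos, rep(seqc, each = 3), alts), 96)
  expect_equal(got, want)
})

test_that("signature estimation normalises, smooths, and recovers a planted signature", {
  g <- coding_gene("ONE", "ACGGGA", flank5 = "A", flank3 = "A")
  rec <- tibble::tibble(gene = "ONE", cds_position = 2L,
                        ref_base = "C", alt_base = "T")
  est <- estimate_signature(rec, g, pseudocount = 0)
  expect_equal(sum(as.numeric(est)), 1)
  expect_equal(as.numeric(est)[match("A[C>T]G", signature_channels())], 1)

  est2 <- estimate_signature(rec, g, pseudocount = 0.5)
  expect_equal(sum(as.numeric(est2)), 1)
  expect_true(all(as.numeric(est2) > 0))

  # parameter recovery: n = 10,000 draws from a known signature
  truth <- random_signature(42)
  gene <- random_coding_gene(500, seed = 8, gene = "RECOV")
  coh <- make_mutation_cohort(gene, truth, 10000, seed = 99)
  est3 <- estimate_signature(coh, gene, pseudocount = 0)
  expect_lt(max(abs(as.numeric(est3) - as.numeric(truth))), 0.01)

  expect_error(estimate_signature(rec[0, ], g), "no usable")
})

test_that("substitution spectrum collapses to six classes and finds the dominant one", {
  allct <- tibble::tibble(ref_base = c("C", "G"), alt_base = c("T", "A"))
  sp <- substitution_spectrum(allct)  # G>A is C>T on the other strand
  expect_equal(sp$proportion[sp$class == "C>T"], 1)

  even <- tibble::tibble(ref_base = c("C", "C", "C", "T", "T", "T"),
                         alt_base = c("A", "G", "T", "A", "C", "G"))
  expect_equal(substitution_spectrum(even)$proportion, rep(1 / 6, 6))

  # planted C>T-dominant cohort
  probs <- rep(0.2 / 80, 96)
  probs[33:48] <- 0.8 / 16  # the C>T block of channels
  sig <- mutational_signature(probs)
  gene <- random_coding_gene(200, seed = 14)
  coh <- make_mutation_cohort(gene, sig, 2000, seed = 15)
  sp2 <- substitution_spectrum(coh)
  expect_equal(sp2$class[which.max(sp2$proportion)], "C>T")
})

test_that("FoldX Dif tables and metric tables parse into the interchange layout", {
  f <- system.file("extdata", "synthetic_foldx_dif.fxout", package = "structselect")
  ddg <- read_foldx_dif(f)
  expect_equal(nrow(ddg), 4L)
  expect_equal(ddg$protein_position, c(310L, 317L, 305L, 313L))
  expect_equal(ddg$ref_aa[1], "V")
  expect_equal(ddg$alt_aa[1], "M")
  expect_equal(ddg$chain, rep("A", 4))
  expect_equal(ddg$value, c(1.234, 2.501, -0.35, 0.905))

  g <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(position = c(10L, 11L), ref_aa = c("V", "G"),
                                  alt_aa = c("M", "R"), value = c(0.5, -1.2)), g)
  mt <- read_metric_table(g)
  expect_equal(mt$protein_position, c(10L, 11L))
  expect_equal(mt$value, c(0.5, -1.2))
})
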