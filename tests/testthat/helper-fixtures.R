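# Shared fixtures, all built in code at test time.

# tiny alignment: two sequences over four columns
toy_clustal <- function(path = tempfile(fileext = ".aln")) {
  writeLines(c(
    "CLUSTAL O(1.2.4) multiple sequence alignment",
    "",
    "A   AC-G 3",
    "B   ACTG 4"
  ), path)
  path
}

# deterministic random gapped alignment for oracle comparisons
random_alignment <- function(n_seq, n_col, seed, gap_prob = 0.15) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  rows <- vapply(seq_len(n_seq), function(i) {
    chars <- sample(aa, n_col, replace = TRUE)
    chars[runif(n_col) < gap_prob] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  aligned_seqs(sprintf("seq%02d", seq_len(n_seq)), rows)
}

# hand-written 3-residue PDB fixture (one CA + one CB per residue)
tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.000   0.500   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  SER A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      5  OG  SER A   3       8.100   1.200   0.000  1.00  0.00           O",
    "END"
  ), path)
  path
}

# structure from a bare coordinate matrix (CA-only, chain A)
coords_structure <- function(m, element = "C") {
  protein_structure(tibble::tibble(
    chain = "A", resno = seq_len(nrow(m)), resid = "GLY", elety = "CA",
    element = element, x = m[, 1], y = m[, 2], z = m[, 3]
  ))
}

# straight CA chain with fixed spacing
chain_structure <- function(n, spacing = 3.8) {
  coords_structure(cbind((seq_len(n) - 1) * spacing, 0, 0))
}

# independent per-column conservation tally (brute force)
oracle_conservation <- function(aln) {
  mat <- do.call(rbind, strsplit(unname(aln$rows), ""))
  nseq <- nrow(mat)
  t(apply(mat, 2, function(col) {
    nog <- col[!col %in% c("-", ".")]
    if (!length(nog)) return(c(score = 0, coverage = 0))
    counts <- table(nog)
    c(score = max(counts) / nseq, coverage = length(nog) / nseq)
  }))
}

# independent pyrimidine-collapsed channel label for one substitution
oracle_channel_label <- function(f5, ref, f3, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref %in% c("A", "G")) {
    lab5 <- comp[[f3]]; labr <- comp[[ref]]; laba <- comp[[alt]]; lab3 <- comp[[f5]]
  } else {
    lab5 <- f5; labr <- ref; laba <- alt; lab3 <- f3
  }
  paste0(lab5, "[", labr, ">", laba, "]", lab3)
}

# textbook two-group log-rank statistic (hypergeometric variance)
oracle_logrank <- function(cohort, ga, gb) {
  d <- cohort[cohort$group %in% c(ga, gb), ]
  times <- sort(unique(d$time[d$event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- d$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & d$group == ga)
    dt <- sum(d$time == t & d$event == 1)
    d1 <- sum(d$time == t & d$event == 1 & d$group == ga)
    O <- O + d1
    E <- E + dt * n1 / n
    if (n > 1) V <- V + dt * (n1 / n) * (1 - n1 / n) * (n - dt) / (n - 1)
  }
  (O - E)^2 / V
}

# hand-rolled product-limit estimator for one group
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  tibble::tibble(time = ts, survival = out)
}
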