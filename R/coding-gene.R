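# Coding genes and per-substitution annotation: consequence calls by codon
# translation and trinucleotide-context channel assignment.

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Construct a coding gene
#'
#' Holds the coding sequence (CDS) of one gene together with the single
#' flanking nucleotide on each side, which supplies the trinucleotide context
#' at the first and last CDS positions.
#'
#' @param gene Gene symbol.
#' @param cds Coding nucleotide string (ACGT), length divisible by 3. May end
#'   with a stop codon; must not contain an internal stop.
#' @param flank5,flank3 Single context nucleotides immediately 5' and 3' of
#'   the CDS.
#' @return An object of class `coding_gene` with elements `gene`, `cds`,
#'   `flank5`, `flank3`, `n_codons`.
#' @export
coding_gene <- function(gene, cds, flank5 = "A", flank3 = "A") {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) abort("CDS length must be divisible by 3")
  if (grepl("[^ACGT]", cds)) abort("CDS must contain only A, C, G, T")
  if (!flank5 %in% BASES || !flank3 %in% BASES) {
    abort("flanks must be single nucleotides in {A,C,G,T}")
  }
  aa <- translate_cds(cds)
  internal <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("\\*", internal)) abort("CDS translation has an internal stop codon")
  structure(
    list(gene = gene, cds = cds, flank5 = flank5, flank3 = flank3,
         n_codons = nchar(cds) %/% 3L),
    class = "coding_gene"
  )
}

#' @export
print.coding_gene <- function(x, ...) {
  cat("<coding_gene>", x$gene, "-", x$n_codons, "codons\n")
  invisible(x)
}

translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(genetic_code()[codons], collapse = "")
}

#' Read coding sequences from a FASTA file
#'
#' @param path FASTA file of nucleotide CDS records; record names become gene
#'   symbols (first whitespace-delimited token).
#' @param flank5,flank3 Context nucleotides applied to every gene.
#' @return Named list of [coding_gene()] objects.
#' @export
read_cds_fasta <- function(path, flank5 = "A", flank3 = "A") {
  ss <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*$", "", names(ss))
  genes <- purrr::map2(nms, as.character(ss), coding_gene,
                       flank5 = flank5, flank3 = flank3)
  setNames(genes, nms)
}

#' Classify the protein consequence of single-nucleotide substitutions
#'
#' Translates the affected codon before and after the substitution and
#' reports the consequence class and a one-letter protein change such as
#' `"V310M"` (synonymous changes are written with identical reference and
#' alternate residues, e.g. `"A2A"`; nonsense changes use `"*"`).
#'
#' @param gene A [coding_gene()].
#' @param cds_position Integer vector of 1-based CDS nucleotide positions.
#' @param ref_base,alt_base Nucleotide vectors, recycled to a common length
#'   with `cds_position`.
#' @return A tibble with columns `cds_position`, `ref_base`, `alt_base`,
#'   `protein_position`, `ref_aa`, `alt_aa`, `consequence`
#'   (one of `"synonymous"`, `"missense"`, `"nonsense"`, `"other"`) and
#'   `protein_change`.
#' @details A `ref_base` that does not match the CDS is an error: reference
#'   mismatches are never auto-corrected.
#' @export
classify_consequence <- function(gene, cds_position, ref_base, alt_base) {
  stopifnot(inherits(gene, "coding_gene"))
  n <- max(length(cds_position), length(ref_base), length(alt_base))
  pos <- rep_len(as.integer(cds_position), n)
  ref <- rep_len(toupper(ref_base), n)
  alt <- rep_len(toupper(alt_base), n)
  L <- nchar(gene$cds)
  if (any(pos < 1L | pos > L)) {
    abort(sprintf("cds_position out of range 1..%d for gene %s", L, gene$gene))
  }
  if (any(ref == alt)) abort("ref_base and alt_base must differ")
  cds_ref <- substring(gene$cds, pos, pos)
  bad <- which(cds_ref != ref)
  if (length(bad)) {
    abort(sprintf(
      "reference mismatch for gene %s at CDS position(s) %s: CDS has %s, input says %s",
      gene$gene, paste(pos[bad], collapse = ","),
      paste(cds_ref[bad], collapse = ","), paste(ref[bad], collapse = ",")
    ))
  }
  codon_i <- (pos - 1L) %/% 3L          # 0-based codon index
  offset <- (pos - 1L) %% 3L            # position within codon
  codon <- substring(gene$cds, 3L * codon_i + 1L, 3L * codon_i + 3L)
  mut_codon <- paste0(substring(codon, 1L, offset), alt,
                      substring(codon, offset + 2L, 3L))
  gc <- genetic_code()
  ref_aa <- unname(gc[codon])
  alt_aa <- unname(gc[mut_codon])
  consequence <- dplyr::case_when(
    ref_aa == alt_aa ~ "synonymous",
    ref_aa != "*" & alt_aa == "*" ~ "nonsense",
    ref_aa == "*" ~ "other",            # stop-loss
    TRUE ~ "missense"
  )
  tibble(
    cds_position = pos, ref_base = ref, alt_base = alt,
    protein_position = codon_i + 1L, ref_aa = ref_aa, alt_aa = alt_aa,
    consequence = consequence,
    protein_change = paste0(ref_aa, codon_i + 1L, alt_aa)
  )
}

#' Trinucleotide context channel of single-nucleotide substitutions
#'
#' Maps substitutions to the 96-channel pyrimidine-centred frame. Purine
#' reference bases are reverse-complemented (together with their flanks and
#' the alternate base) before indexing, so a substitution and its reverse
#' complement always share a channel. The single flanking nucleotides of the
#' [coding_gene()] provide context at the CDS ends.
#'
#' @inheritParams classify_consequence
#' @return Integer vector of channel indices in 1..96 (COSMIC order; see
#'   [signature_channels()]), named by channel label. Note some tools index
#'   these channels 0-95; here the first channel is 1, matching R indexing.
#' @export
trinucleotide_context <- function(gene, cds_position, ref_base, alt_base) {
  stopifnot(inherits(gene, "coding_gene"))
  n <- max(length(cds_position), length(ref_base), length(alt_base))
  pos <- rep_len(as.integer(cds_position), n)
  ref <- rep_len(toupper(ref_base), n)
  alt <- rep_len(toupper(alt_base), n)
  L <- nchar(gene$cds)
  if (any(pos < 1L | pos > L)) abort("cds_position out of CDS range")
  f5 <- ifelse(pos == 1L, gene$flank5, substring(gene$cds, pos - 1L, pos - 1L))
  f3 <- ifelse(pos == L, gene$flank3, substring(gene$cds, pos + 1L, pos + 1L))
  pur <- ref %in% c("A", "G")
  # collapse purine-centred substitutions onto the pyrimidine strand
  r <- ifelse(pur, revcomp_chars(ref), ref)
  a <- ifelse(pur, revcomp_chars(alt), alt)
  l5 <- ifelse(pur, revcomp_chars(f3), f5)
  l3 <- ifelse(pur, revcomp_chars(f5), f3)
  cls <- paste0(r, ">", a)
  idx <- channel_index(cls, l5, l3)
  if (anyNA(idx)) abort("invalid substitution for context channel")
  setNames(idx, signature_channels()[idx])
}

#' Estimate a mutational signature from a mutation catalog
#'
#' Counts the trinucleotide-context channel of every usable substitution and
#' normalises with additive smoothing:
#' `prob[c] = (count[c] + pseudocount) / (total + 96 * pseudocount)`.
#'
#' @param records Mutation tibble with columns `gene`, `cds_position`,
#'   `ref_base`, `alt_base` (as returned by [read_mutation_table()] or
#'   [make_mutation_cohort()]).
#' @param genes Named list of [coding_gene()] objects covering the genes in
#'   `records`.
#' @param pseudocount Additive smoothing constant (default 0.5, so small
#'   cohorts never produce zero-probability channels).
#' @return A [mutational_signature()].
#' @export
estimate_signature <- function(records, genes, pseudocount = 0.5) {
  stopifnot(is.data.frame(records))
  if (inherits(genes, "coding_gene")) genes <- setNames(list(genes), genes$gene)
  usable <- records %>%
    filter(!is.na(.data$cds_position), !is.na(.data$ref_base),
           !is.na(.data$alt_base), .data$gene %in% names(genes))
  if (nrow(usable) == 0L) abort("no usable substitution records to estimate a signature")
  counts <- numeric(96)
  for (g in unique(usable$gene)) {
    rows <- usable[usable$gene == g, ]
    ch <- trinucleotide_context(genes[[g]], rows$cds_position,
                                rows$ref_base, rows$alt_base)
    tab <- tabulate(ch, nbins = 96L)
    counts <- counts + tab
  }
  probs <- (counts + pseudocount) / (sum(counts) + 96 * pseudocount)
  mutational_signature(probs, pseudocount = pseudocount)
}

#' Six-class substitution spectrum of a mutation catalog
#'
#' Collapses substitutions to the six pyrimidine-centred classes and returns
#' their proportions (mutation-weighted: every record counts once).
#'
#' @param records Mutation tibble with columns `ref_base` and `alt_base`.
#' @return A tibble with columns `class` and `proportion` (six rows summing
#'   to one).
#' @export
substitution_spectrum <- function(records) {
  stopifnot(is.data.frame(records))
  ok <- records %>%
    filter(!is.na(.data$ref_base), !is.na(.data$alt_base))
  if (nrow(ok) == 0L) abort("no substitution records")
  ref <- toupper(ok$ref_base)
  alt <- toupper(ok$alt_base)
  pur <- ref %in% c("A", "G")
  cls <- paste0(ifelse(pur, revcomp_chars(ref), ref), ">",
                ifelse(pur, revcomp_chars(alt), alt))
  tab <- table(factor(cls, levels = SUB_CLASSES))
  tibble(class = SUB_CLASSES, proportion = as.numeric(tab) / sum(tab))
}

#' Generate a random coding gene
#'
#' Draws codons uniformly from the 61 sense codons (first codon ATG, optional
#' terminal TAA), giving a stop-free CDS for simulation studies.
#'
#' @param n_codons Number of codons including the start (and stop, if
#'   `stop_codon`).
#' @param seed Integer seed.
#' @param gene Gene symbol for the simulated gene.
#' @param stop_codon Append TAA as the final codon? Default `FALSE`.
#' @return A [coding_gene()].
#' @export
random_coding_gene <- function(n_codons, seed, gene = "SIMGENE", stop_codon = FALSE) {
  stopifnot(n_codons >= 2)
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  local_seed_eval(seed, {
    body_n <- n_codons - 1L - as.integer(stop_codon)
    codons <- c("ATG", sample(sense, body_n, replace = TRUE),
                if (stop_codon) "TAA")
    flanks <- sample(BASES, 2, replace = TRUE)
    coding_gene(gene, paste(codons, collapse = ""), flanks[1], flanks[2])
  })
}
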