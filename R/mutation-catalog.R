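# Readers for somatic mutation tables in three dialects, normalised to one
# tidy record layout. Rows that cannot be interpreted as single-nucleotide
# substitutions (indels, "p.?", malformed HGVS) are routed to a rejects
# table attached to the result, never silently dropped.

PROT_RE <- "^p?\\.?([A-Z\\*])(\\d+)([A-Z\\*=])$"
CDNA_RE <- "^c?\\.?(\\d+)([ACGT])>([ACGT])$"

#' Read and normalise a somatic mutation table
#'
#' Supports three dialects:
#' \describe{
#'   \item{`simple_tsv`}{columns `gene`, `sample`, `cds_pos`, `ref`, `alt`
#'     (optional `tissue`).}
#'   \item{`cosmic_export`}{COSMIC-style columns `GENE_SYMBOL` (or
#'     `Gene name`), `MUTATION_CDS` (`c.928G>A`), `MUTATION_AA` (`p.V310M`),
#'     `SAMPLE_NAME` (or `Sample name`), optional `PRIMARY_SITE`.}
#'   \item{`maf_like`}{columns `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#'     `HGVSp_Short` (`p.V310M`), optional `HGVSc` (`c.928G>A`).}
#' }
#'
#' @param path Delimited text file (tab-separated).
#' @param dialect One of `"simple_tsv"`, `"cosmic_export"`, `"maf_like"`.
#' @return A tibble of mutation records with columns `gene`, `sample_id`,
#'   `tissue`, `cds_position`, `ref_base`, `alt_base`, `protein_change`,
#'   `consequence` (`NA` where not derivable from the file alone; see
#'   [annotate_mutations()]). Unparseable rows are attached as a tibble in
#'   `attr(, "rejects")` with a `reason` column; [mutation_rejects()]
#'   retrieves them.
#' @export
read_mutation_table <- function(path, dialect = c("simple_tsv", "cosmic_export", "maf_like")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  getcol <- function(...) {
    for (nm in c(...)) if (nm %in% names(raw)) return(raw[[nm]])
    NULL
  }
  need <- function(x, what) {
    if (is.null(x)) abort(sprintf("dialect '%s': missing mandatory column (%s)", dialect, what))
    x
  }
  if (dialect == "simple_tsv") {
    df <- tibble(
      gene = need(getcol("gene"), "gene"),
      sample_id = need(getcol("sample", "sample_id"), "sample"),
      tissue = getcol("tissue") %||% NA_character_,
      cds_position = suppressWarnings(as.integer(need(getcol("cds_pos", "cds_position"), "cds_pos"))),
      ref_base = toupper(need(getcol("ref", "ref_base"), "ref")),
      alt_base = toupper(need(getcol("alt", "alt_base"), "alt")),
      protein_change = getcol("protein_change") %||% NA_character_
    )
    bad <- is.na(df$cds_position) | !df$ref_base %in% BASES | !df$alt_base %in% BASES |
      df$ref_base == df$alt_base
    reason <- ifelse(is.na(df$cds_position), "unparseable cds position",
                     "not a single-nucleotide substitution")
  } else {
    if (dialect == "cosmic_export") {
      gene <- need(getcol("GENE_SYMBOL", "Gene name", "gene"), "gene symbol")
      sample_id <- need(getcol("SAMPLE_NAME", "Sample name", "sample"), "sample name")
      tissue <- getcol("PRIMARY_SITE", "Primary site") %||% NA_character_
      cdna <- need(getcol("MUTATION_CDS", "Mutation CDS"), "cDNA change")
      prot <- need(getcol("MUTATION_AA", "Mutation AA"), "protein change")
    } else {
      gene <- need(getcol("Hugo_Symbol"), "Hugo_Symbol")
      sample_id <- need(getcol("Tumor_Sample_Barcode"), "Tumor_Sample_Barcode")
      tissue <- getcol("Primary_Site") %||% NA_character_
      cdna <- getcol("HGVSc") %||% NA_character_
      prot <- need(getcol("HGVSp_Short"), "HGVSp_Short")
    }
    cm <- stringr::str_match(cdna, CDNA_RE)
    pm <- stringr::str_match(prot, PROT_RE)
    df <- tibble(
      gene = gene, sample_id = sample_id,
      tissue = rep_len(tissue, length(gene)),
      cds_position = suppressWarnings(as.integer(cm[, 2])),
      ref_base = cm[, 3], alt_base = cm[, 4],
      protein_change = ifelse(is.na(pm[, 1]), NA_character_,
                              paste0(pm[, 2], pm[, 3],
                                     ifelse(pm[, 4] == "=", pm[, 2], pm[, 4])))
    )
    # a row is usable if either side parsed as a single-base substitution
    bad <- is.na(df$cds_position) & is.na(df$protein_change)
    reason <- rep("unparseable protein and cDNA change", nrow(df))
  }
  rejects <- df[bad, , drop = FALSE]
  if (nrow(rejects)) rejects$reason <- reason[bad]
  out <- df[!bad, , drop = FALSE]
  out$consequence <- NA_character_
  attr(out, "rejects") <- rejects
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_mutation_table
#' @param records A tibble returned by [read_mutation_table()].
#' @export
mutation_rejects <- function(records) {
  attr(records, "rejects") %||% tibble()
}

#' Annotate mutation records against their coding sequences
#'
#' Fills in `consequence`, `protein_change`, `protein_position`, `ref_aa`,
#' `alt_aa` and the trinucleotide `channel` by codon translation of each
#' gene's CDS. Reference mismatches raise an error.
#'
#' @param records Mutation tibble with `gene`, `cds_position`, `ref_base`,
#'   `alt_base`.
#' @param genes Named list of [coding_gene()] objects (or a single gene).
#' @return The input tibble with annotation columns replaced/added.
#' @export
annotate_mutations <- function(records, genes) {
  if (inherits(genes, "coding_gene")) genes <- setNames(list(genes), genes$gene)
  missing_genes <- setdiff(unique(records$gene), names(genes))
  if (length(missing_genes)) {
    abort(paste("no coding sequence supplied for gene(s):",
                paste(missing_genes, collapse = ", ")))
  }
  records %>%
    mutate(.row = row_number()) %>%
    group_by(.data$gene) %>%
    dplyr::group_modify(function(d, key) {
      g <- genes[[key$gene]]
      ann <- classify_consequence(g, d$cds_position, d$ref_base, d$alt_base)
      d$protein_position <- ann$protein_position
      d$ref_aa <- ann$ref_aa
      d$alt_aa <- ann$alt_aa
      d$consequence <- ann$consequence
      d$protein_change <- ann$protein_change
      d$channel <- as.integer(trinucleotide_context(g, d$cds_position,
                                                    d$ref_base, d$alt_base))
      d
    }) %>%
    ungroup() %>%
    arrange(.data$.row) %>%
    select(-".row")
}

#' Write mutation records in the simple_tsv dialect
#'
#' @param records Mutation tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_simple_tsv <- function(records, path) {
  out <- tibble(
    gene = records$gene,
    sample = records$sample_id %||% paste0("S", seq_len(nrow(records))),
    tissue = if ("tissue" %in% names(records)) records$tissue else NA_character_,
    cds_pos = records$cds_position,
    ref = records$ref_base,
    alt = records$alt_base
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a per-mutation structural metric table
#'
#' The interchange format for externally computed metrics (for example FoldX
#' folding-energy changes): a TSV with columns `position`, `ref_aa`,
#' `alt_aa`, `value`.
#'
#' @param path TSV file.
#' @return Tibble with columns `protein_position`, `ref_aa`, `alt_aa`,
#'   `value`.
#' @export
read_metric_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    position = "i", ref_aa = "c", alt_aa = "c", value = "d"
  ), progress = FALSE)
  tibble(protein_position = df$position, ref_aa = df$ref_aa,
         alt_aa = df$alt_aa, value = df$value)
}

#' Parse a FoldX BuildModel "Dif_" energy-difference table
#'
#' Reads the tabular `Dif_*.fxout` dialect: lines up to and including the
#' header row starting with `Pdb` are skipped; each data row has a mutation
#' tag (for example `VA310M`: wild-type residue, chain, position, mutant
#' residue) in the first column and the total energy difference (ΔΔG,
#' kcal/mol) in the second.
#'
#' @param path FoldX Dif_ file.
#' @return Tibble with columns `protein_position`, `ref_aa`, `alt_aa`,
#'   `chain`, `value` — directly usable as a metric table.
#' @export
read_foldx_dif <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^Pdb\\b", lines)
  if (length(hdr)) lines <- lines[-seq_len(hdr[1])]
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split(lines, "\t")
  tag <- vapply(parts, `[`, character(1), 1)
  val <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  m <- stringr::str_match(tag, "([A-Z])([A-Za-z0-9])(\\d+)([A-Z])(?:\\.pdb)?$")
  if (anyNA(m[, 1])) {
    abort(sprintf("unparseable FoldX mutation tag(s): %s",
                  paste(head(tag[is.na(m[, 1])], 3), collapse = ", ")))
  }
  tibble(protein_position = as.integer(m[, 4]), ref_aa = m[, 2],
         alt_aa = m[, 5], chain = m[, 3], value = val)
}
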