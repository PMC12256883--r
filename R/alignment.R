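# Multiple sequence alignments in Clustal format, per-column conservation
# scoring, motif boxes, and residue <-> column index maps.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_CHARS <- c("-", ".")

#' Construct an aligned sequence set
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param rows Gapped amino-acid strings, one per id, all the same length.
#' @return An object of class `aligned_seqs` with elements `ids`, `rows`
#'   (named by id) and `n_columns`.
#' @export
aligned_seqs <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  if (length(ids) != length(rows)) abort("ids and rows must have equal length")
  if (anyDuplicated(ids)) abort("sequence ids must be unique")
  w <- unique(nchar(rows))
  if (length(w) != 1L) abort("all alignment rows must have equal length")
  ok <- c(AA_ALPHABET, GAP_CHARS, "X", "*")
  letters_used <- unique(strsplit(paste(rows, collapse = ""), "")[[1]])
  if (!all(letters_used %in% ok)) {
    abort(paste("unexpected alignment characters:",
                paste(setdiff(letters_used, ok), collapse = " ")))
  }
  structure(list(ids = ids, rows = setNames(rows, ids), n_columns = w),
            class = "aligned_seqs")
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat("<aligned_seqs>", length(x$ids), "sequences x", x$n_columns, "columns\n")
  invisible(x)
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$rows), ""))
  rownames(m) <- aln$ids
  m
}

#' Read a Clustal-format multiple sequence alignment
#'
#' Accepts plain Clustal and the `clustal_num` dialect (trailing residue
#' counts). Conservation annotation lines are ignored. Malformed input —
#' a missing CLUSTAL header, ragged rows, or blocks that disagree in
#' sequence order — raises a parse error naming the offending line.
#'
#' @param path Path to a `.aln` / `.clustal` / `.clustal_num` file.
#' @return An [aligned_seqs()] object.
#' @export
read_clustal <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^(CLUSTAL|MUSCLE)", lines[1], ignore.case = TRUE)) {
    abort(sprintf("%s line 1: not a Clustal file (missing CLUSTAL header)", path))
  }
  body <- lines[-1]
  seqs <- list()
  order_ref <- NULL
  block <- character(0)
  block_start <- 2L
  lineno <- 1L
  flush_block <- function(block, block_ids) {
    if (length(block) == 0L) return(invisible())
    if (is.null(order_ref)) {
      order_ref <<- block_ids
    } else if (!identical(block_ids, order_ref)) {
      abort(sprintf("%s line %d: alignment blocks disagree in sequence order",
                    path, block_start))
    }
    invisible()
  }
  block_ids <- character(0)
  for (ln in body) {
    lineno <- lineno + 1L
    if (!nzchar(trimws(ln))) {
      flush_block(block, block_ids)
      block <- character(0); block_ids <- character(0)
      block_start <- lineno + 1L
      next
    }
    if (grepl("^\\s", ln)) next  # conservation annotation line
    m <- stringr::str_match(ln, "^(\\S+)\\s+([A-Za-z\\-\\.\\*]+)(\\s+\\d+)?\\s*$")
    if (is.na(m[1, 1])) {
      abort(sprintf("%s line %d: malformed alignment row: %s", path, lineno, ln))
    }
    id <- m[1, 2]; chunk <- m[1, 3]
    if (length(block_ids) == 0L) block_start <- lineno
    block_ids <- c(block_ids, id)
    seqs[[id]] <- paste0(seqs[[id]] %||% "", chunk)
    block <- c(block, ln)
  }
  flush_block(block, block_ids)
  if (length(seqs) == 0L) abort(sprintf("%s: no sequences found", path))
  widths <- nchar(unlist(seqs))
  if (length(unique(widths)) != 1L) {
    abort(sprintf("%s: ragged alignment (sequence lengths %s)", path,
                  paste(unique(widths), collapse = ", ")))
  }
  aligned_seqs(names(seqs), unlist(seqs))
}

#' Write an alignment in Clustal format
#'
#' @param aln An [aligned_seqs()] object.
#' @param path Output path.
#' @param width Residues per block line.
#' @return `path`, invisibly. Round-trips through [read_clustal()].
#' @export
write_clustal <- function(aln, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("CLUSTAL multiple sequence alignment", "", ""), con)
  idw <- max(nchar(aln$ids)) + 3L
  done <- setNames(integer(length(aln$ids)), aln$ids)
  for (start in seq(1L, aln$n_columns, by = width)) {
    end <- min(start + width - 1L, aln$n_columns)
    for (id in aln$ids) {
      chunk <- substr(aln$rows[[id]], start, end)
      done[id] <- done[id] + sum(strsplit(chunk, "")[[1]] != "-")
      writeLines(sprintf("%-*s%s %d", idw, id, chunk, done[id]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Score per-column conservation of an alignment
#'
#' The score of a column is the count of its most frequent non-gap residue
#' divided by the number of sequences, so gappy columns are penalised; ties
#' between residues are broken alphabetically. All-gap columns score 0 and
#' carry the majority-residue sentinel `NA`.
#'
#' @param aln An [aligned_seqs()] object.
#' @return A tibble of class `conservation_profile` with columns `column`,
#'   `majority_residue`, `score` (in \[0,1\]) and `coverage` (fraction of
#'   non-gap entries).
#' @export
column_conservation <- function(aln) {
  stopifnot(inherits(aln, "aligned_seqs"))
  m <- aln_matrix(aln)
  nseq <- nrow(m)
  res <- apply(m, 2, function(col) {
    col <- col[!col %in% GAP_CHARS]
    if (length(col) == 0L) {
      return(c(NA_character_, "0", "0"))
    }
    tab <- table(col)
    best <- sort(names(tab)[tab == max(tab)])[1]  # alphabetical tie-break
    c(best, as.character(max(tab) / nseq), as.character(length(col) / nseq))
  })
  out <- tibble(
    column = seq_len(aln$n_columns),
    majority_residue = res[1, ],
    score = as.numeric(res[2, ]),
    coverage = as.numeric(res[3, ])
  )
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Find conserved motif boxes in a conservation profile
#'
#' A motif box is a maximal run of columns with conservation score at least
#' `min_score`, in which up to `max_gap` consecutive below-threshold columns
#' are tolerated inside the run. Boxes shorter than `min_length` columns are
#' dropped. Boxes always start and end on above-threshold columns, are
#' disjoint, and are ordered by start column.
#'
#' @param profile A [column_conservation()] tibble.
#' @param min_score Minimum column score in (0, 1\] (default 1.0: perfectly
#'   conserved columns only).
#' @param min_length Minimum box span in columns (default 2).
#' @param max_gap Maximum below-threshold columns bridged inside a box
#'   (default 1).
#' @return A tibble with columns `label`, `start_column`, `end_column`,
#'   `consensus` (majority residues across the box, below-threshold columns
#'   in lower case).
#' @export
find_conserved_motifs <- function(profile, min_score = 1.0, min_length = 2L,
                                  max_gap = 1L) {
  stopifnot(min_score > 0, min_score <= 1)
  hit <- which(!is.na(profile$score) & profile$score >= min_score)
  if (length(hit) == 0L) {
    return(tibble(label = integer(), start_column = integer(),
                  end_column = integer(), consensus = character()))
  }
  new_box <- c(TRUE, diff(hit) > max_gap + 1L)
  grp <- cumsum(new_box)
  boxes <- tibble(start_column = as.integer(tapply(hit, grp, min)),
                  end_column = as.integer(tapply(hit, grp, max))) %>%
    filter(.data$end_column - .data$start_column + 1L >= min_length) %>%
    arrange(.data$start_column)
  boxes$label <- seq_len(nrow(boxes))
  boxes$consensus <- purrr::map2_chr(boxes$start_column, boxes$end_column, function(s, e) {
    cols <- s:e
    res <- profile$majority_residue[cols]
    res[is.na(res)] <- "-"
    weak <- profile$score[cols] < min_score
    res[weak] <- tolower(res[weak])
    paste(res, collapse = "")
  })
  boxes %>% select("label", "start_column", "end_column", "consensus")
}

#' Map a residue index of one sequence to its alignment column (and back)
#'
#' `map_residue_to_column()` converts a 1-based ungapped residue index of a
#' sequence into the 1-based alignment column that holds it;
#' `column_to_residue()` is its inverse (returning `NA` for gap columns).
#'
#' @param aln An [aligned_seqs()] object.
#' @param seq_id Sequence identifier.
#' @param residue_index 1-based ungapped residue position(s).
#' @return Integer column index (or residue index for the inverse).
#' @export
map_residue_to_column <- function(aln, seq_id, residue_index) {
  row <- aln$rows[[seq_id]]
  if (is.null(row)) abort(sprintf("unknown sequence id '%s'", seq_id))
  chars <- strsplit(row, "")[[1]]
  cols <- which(!chars %in% GAP_CHARS)
  idx <- as.integer(residue_index)
  if (any(idx < 1L | idx > length(cols))) {
    abort(sprintf("residue index out of range 1..%d for sequence %s",
                  length(cols), seq_id))
  }
  cols[idx]
}

#' @rdname map_residue_to_column
#' @param column 1-based alignment column(s).
#' @export
column_to_residue <- function(aln, seq_id, column) {
  row <- aln$rows[[seq_id]]
  if (is.null(row)) abort(sprintf("unknown sequence id '%s'", seq_id))
  chars <- strsplit(row, "")[[1]]
  col <- as.integer(column)
  if (any(col < 1L | col > length(chars))) abort("column out of alignment range")
  resmap <- cumsum(!chars %in% GAP_CHARS)
  out <- resmap[col]
  out[chars[col] %in% GAP_CHARS] <- NA_integer_
  out
}

#' Count conserved columns whose majority residue matches a query
#'
#' Used, for example, to count how many times a fully conserved cysteine
#' appears along an alignment of paralogs.
#'
#' @param aln An [aligned_seqs()] object.
#' @param profile Its [column_conservation()] profile.
#' @param residue Single amino-acid letter.
#' @param min_score Minimum conservation score (default 1.0).
#' @return Integer count of matching columns.
#' @export
count_conserved_residue <- function(aln, profile, residue, min_score = 1.0) {
  residue <- toupper(residue)
  if (!residue %in% AA_ALPHABET) abort("residue must be a standard amino-acid letter")
  sum(!is.na(profile$majority_residue) &
        profile$majority_residue == residue &
        profile$score >= min_score)
}

#' Percent identity of two protein sequences
#'
#' Unaligned inputs are first globally aligned (Needleman-Wunsch, BLOSUM62);
#' already-aligned inputs (equal length, containing gaps) are used as is.
#' Identity is the number of identical aligned residue pairs divided by the
#' number of columns where neither sequence has a gap, so terminal
#' extensions of one sequence do not dilute the identity.
#'
#' @param seq_a,seq_b Amino-acid strings (gapped or ungapped).
#' @param aligned Treat inputs as already aligned? Default: auto-detect
#'   (equal lengths and at least one gap character).
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(seq_a, seq_b, aligned = NULL) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("sequences must be non-empty")
  if (is.null(aligned)) {
    aligned <- nchar(seq_a) == nchar(seq_b) && grepl("-", paste0(seq_a, seq_b))
  }
  if (!aligned) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5
    )
    seq_a <- as.character(Biostrings::alignedPattern(al))
    seq_b <- as.character(Biostrings::alignedSubject(al))
  }
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  if (length(a) != length(b)) abort("aligned sequences must have equal length")
  keep <- !(a %in% GAP_CHARS) & !(b %in% GAP_CHARS)
  if (!any(keep)) abort("no gap-free aligned columns")
  100 * sum(a[keep] == b[keep]) / sum(keep)
}

#' @rdname column_conservation
#' @param object A `conservation_profile`.
#' @param motifs Optional motif tibble from [find_conserved_motifs()] drawn
#'   as shaded boxes.
#' @param ... Unused.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, motifs = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$column, y = .data$score)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::labs(x = "alignment column", y = "conservation score") +
    ggplot2::theme_minimal()
  if (!is.null(motifs) && nrow(motifs)) {
    p <- p + ggplot2::geom_rect(
      data = motifs,
      ggplot2::aes(xmin = .data$start_column - 0.5, xmax = .data$end_column + 0.5,
                   ymin = 0, ymax = 1.02),
      inherit.aes = FALSE, fill = "orange", alpha = 0.25
    )
  }
  p
}
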