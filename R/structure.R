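# Protein structures: a light tibble-backed container around PDB-format
# coordinates, plus residue-level geometry used by the selection metrics.

#' Construct a protein structure
#'
#' @param atoms Tibble with columns `chain`, `resno`, `resid` (3-letter
#'   residue name), `elety` (atom name), `element`, `x`, `y`, `z` (Å) and
#'   optionally `occ`.
#' @return Object of class `protein_structure`: list with `atoms` (tibble)
#'   and `residues` (tibble with `chain`, `resno`, `resid`, `ca` row index
#'   into `atoms`, `NA` when the residue lacks a Cα).
#' @export
protein_structure <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    abort(paste("atoms tibble needs columns:", paste(need, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  atoms <- as_tibble(atoms) %>% arrange(.data$chain, .data$resno)
  res <- atoms %>%
    mutate(.idx = row_number()) %>%
    group_by(.data$chain, .data$resno) %>%
    summarise(resid = .data$resid[1],
              ca = { i <- which(.data$elety == "CA"); if (length(i)) .data$.idx[i[1]] else NA_integer_ },
              .groups = "drop") %>%
    arrange(.data$chain, .data$resno)
  structure(list(atoms = atoms, residues = res), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure>", nrow(x$residues), "residues,",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Cα coordinate matrix of a structure
#'
#' @param structure A [protein_structure()].
#' @return Numeric matrix (residues with a Cα) x 3, row names `chain:resno`.
#' @export
calpha_coords <- function(structure) {
  idx <- structure$residues$ca
  keep <- !is.na(idx)
  m <- as.matrix(structure$atoms[idx[keep], c("x", "y", "z")])
  rownames(m) <- paste0(structure$residues$chain[keep], ":",
                        structure$residues$resno[keep])
  m
}

element_from_pdb <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  el[miss] <- substr(gsub("[^A-Za-z].*", "", trimws(elety[miss])), 1, 1)
  el
}

#' Read a PDB-format structure file
#'
#' Thin wrapper around [bio3d::read.pdb()] that resolves alternate locations
#' to the highest-occupancy copy, orders residues by chain and residue
#' number, and warns when polymer residues lack a Cα atom.
#'
#' @param path PDB file (single- or multi-model).
#' @param model `"first"` (default) for one structure, `"all"` for a list of
#'   structures, one per MODEL block.
#' @return A [protein_structure()] (or list of them for `model = "all"`).
#' @seealso [read_ensemble()] for treating multi-model files as
#'   conformational ensembles.
#' @export
read_pdb <- function(path, model = c("first", "all")) {
  model <- match.arg(model)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = model == "all", verbose = FALSE),
    error = function(e) abort(sprintf("cannot parse PDB file %s: %s",
                                      path, conditionMessage(e)))
  )
  at_all <- pdb$atom
  keep_rows <- which(at_all$type == "ATOM")
  if (length(keep_rows) == 0L) abort(sprintf("no ATOM records in %s", path))
  at <- at_all[keep_rows, , drop = FALSE]
  atoms <- tibble(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    resid = at$resid,
    elety = at$elety,
    element = element_from_pdb(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    .orig = keep_rows
  )
  # resolve altlocs: keep the highest-occupancy copy of each atom
  atoms <- atoms %>%
    group_by(.data$chain, .data$resno, .data$elety) %>%
    arrange(dplyr::desc(.data$occ), .data$alt, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select(-"alt")
  orig_idx <- atoms$.orig
  atoms <- atoms %>% select(-".orig")
  build_one <- function(coords) {
    a <- atoms
    a$x <- coords[, 1]; a$y <- coords[, 2]; a$z <- coords[, 3]
    s <- protein_structure(a)
    no_ca <- s$residues %>% filter(is.na(.data$ca))
    if (nrow(no_ca)) {
      warn(sprintf("%d residue(s) without a CA atom: %s", nrow(no_ca),
                   paste(head(paste0(no_ca$chain, ":", no_ca$resno), 5),
                         collapse = ", ")))
    }
    s
  }
  if (model == "first" || is.null(dim(pdb$xyz)) || nrow(pdb$xyz) == 1L) {
    return(build_one(cbind(atoms$x, atoms$y, atoms$z)))
  }
  # multi-model: bio3d's xyz has one row per MODEL over all atoms of the
  # file; subset each frame to the retained (ATOM, best-altloc) atoms
  xyz <- pdb$xyz
  lapply(seq_len(nrow(xyz)), function(k) {
    co <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)[orig_idx, , drop = FALSE]
    build_one(co)
  })
}

pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, element = "") {
  name <- ifelse(nchar(elety) < 4L, sprintf(" %-3s", elety), elety)
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resid, chain, resno, x, y, z, occ, b, element)
}

#' Write a structure to a PDB-format file
#'
#' @param structure A [protein_structure()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- pdb_atom_line(seq_len(nrow(a)), a$elety, a$resid, a$chain,
                         a$resno, a$x, a$y, a$z,
                         if ("occ" %in% names(a)) a$occ else 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Interface residues between two structures
#'
#' Residues of `structure_a` with any heavy atom within `cutoff` of any
#' heavy atom of `structure_b` (hydrogens excluded). This implements the
#' common "within 10 Å of the binding partner" interface rule.
#'
#' @param structure_a,structure_b [protein_structure()] objects.
#' @param cutoff Distance cutoff in Å (default 10).
#' @return Tibble of interface residues of `structure_a` (`chain`, `resno`,
#'   `resid`, `min_distance`).
#' @export
interface_residues <- function(structure_a, structure_b, cutoff = 10.0) {
  ha <- structure_a$atoms %>% filter(.data$element != "H") %>%
    mutate(.res = paste0(.data$chain, ":", .data$resno))
  hb <- structure_b$atoms %>% filter(.data$element != "H")
  if (nrow(ha) == 0L || nrow(hb) == 0L) abort("both structures must contain heavy atoms")
  A <- as.matrix(ha[, c("x", "y", "z")])
  B <- as.matrix(hb[, c("x", "y", "z")])
  d2 <- cross_dist2(A, B)
  mind <- sqrt(apply(d2, 1, min))
  ha %>%
    mutate(min_distance = mind) %>%
    group_by(.data$chain, .data$resno) %>%
    summarise(resid = .data$resid[1], min_distance = min(.data$min_distance),
              .groups = "drop") %>%
    filter(.data$min_distance <= cutoff) %>%
    arrange(.data$chain, .data$resno)
}

# squared Euclidean cross-distances between rows of A (n x 3) and B (m x 3)
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d2
}

#' Minimum Cα distance of every residue to a target residue set
#'
#' The per-residue metric used to ask whether observed mutations fall closer
#' to (for example) hinge residues than the signature-expected mutations do.
#'
#' @param structure A [protein_structure()].
#' @param target_residues Residue numbers (vector), or a tibble/data.frame
#'   with columns `chain` and `resno` (such as a hinge set).
#' @return Tibble with `chain`, `resno`, `distance` (Å; 0 for the targets
#'   themselves), one row per residue with a Cα.
#' @export
distance_to_residue_set <- function(structure, target_residues) {
  ca <- calpha_coords(structure)
  res <- structure$residues %>% filter(!is.na(.data$ca))
  if (is.data.frame(target_residues)) {
    tkey <- paste0(target_residues$chain, ":", target_residues$resno)
  } else {
    tkey <- paste0(res$chain[match(target_residues, res$resno)], ":",
                   target_residues)
  }
  akey <- paste0(res$chain, ":", res$resno)
  ti <- match(tkey, akey)
  if (length(ti) == 0L) abort("target residue set is empty")
  if (anyNA(ti)) {
    abort(paste("target residue(s) not in structure:",
                paste(tkey[is.na(ti)], collapse = ", ")))
  }
  d2 <- cross_dist2(ca, ca[ti, , drop = FALSE])
  tibble(chain = res$chain, resno = res$resno,
         distance = unname(sqrt(apply(d2, 1, min))))
}
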