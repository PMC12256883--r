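# Conformational ensembles: multi-model PDB ingestion, Kabsch superposition,
# RMSD/RMSF, and the contact residence-time analysis.

#' Construct a conformational ensemble
#'
#' @param coords Numeric array `frames x atoms x 3` (Å).
#' @param atoms Atom tibble shared across frames (as in
#'   [protein_structure()]).
#' @param times Per-frame timestamps in ns, strictly increasing.
#' @return Object of class `conformation_ensemble` with elements `coords`,
#'   `atoms`, `times`, `n_frames`, `n_atoms`.
#' @export
conformation_ensemble <- function(coords, atoms, times) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[2] != nrow(atoms)) abort("coords and atoms disagree in atom count")
  if (length(times) != dim(coords)[1]) abort("one timestamp per frame required")
  if (any(diff(times) <= 0)) abort("frame times must be strictly increasing")
  structure(list(coords = coords, atoms = as_tibble(atoms),
                 times = as.numeric(times),
                 n_frames = dim(coords)[1], n_atoms = dim(coords)[2]),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat("<conformation_ensemble>", x$n_frames, "frames,", x$n_atoms, "atoms,",
      sprintf("t = %.3g..%.3g ns\n", min(x$times), max(x$times)))
  invisible(x)
}

frame_coords <- function(ens, i) {
  matrix(ens$coords[i, , ], ncol = 3)
}

ca_indices <- function(atoms) which(atoms$elety == "CA")

#' Read a conformational ensemble from a multi-model PDB file
#'
#' @param path Multi-model PDB file (one MODEL block per frame).
#' @param times_path Optional sidecar TSV with columns `frame`, `time_ns`.
#' @param dt Uniform frame spacing in ns, used when no sidecar is given
#'   (first frame at `t = 0`).
#' @return A [conformation_ensemble()].
#' @export
read_ensemble <- function(path, times_path = NULL, dt = 1) {
  frames <- read_pdb(path, model = "all")
  if (inherits(frames, "protein_structure")) frames <- list(frames)
  n <- length(frames)
  atoms <- frames[[1]]$atoms
  coords <- array(NA_real_, dim = c(n, nrow(atoms), 3))
  for (i in seq_len(n)) {
    a <- frames[[i]]$atoms
    if (nrow(a) != nrow(atoms)) abort("MODEL blocks disagree in atom count")
    coords[i, , ] <- as.matrix(a[, c("x", "y", "z")])
  }
  times <- if (!is.null(times_path)) {
    tt <- readr::read_tsv(times_path, col_types = readr::cols(), progress = FALSE)
    tt$time_ns[order(tt$frame)]
  } else {
    (seq_len(n) - 1) * dt
  }
  conformation_ensemble(coords, atoms, times)
}

#' Write an ensemble as a multi-model PDB plus times sidecar
#'
#' @param ens A [conformation_ensemble()].
#' @param path Output PDB path.
#' @param times_path Optional sidecar TSV path (`frame`, `time_ns`).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path, times_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- ens$atoms
  for (i in seq_len(ens$n_frames)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    co <- frame_coords(ens, i)
    writeLines(pdb_atom_line(seq_len(nrow(a)), a$elety, a$resid, a$chain,
                             a$resno, co[, 1], co[, 2], co[, 3],
                             1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (!is.null(times_path)) {
    readr::write_tsv(tibble(frame = seq_len(ens$n_frames), time_ns = ens$times),
                     times_path, progress = FALSE)
  }
  invisible(path)
}

#' Kabsch superposition of one coordinate set onto another
#'
#' Finds the proper rotation (determinant +1) and translation minimising
#' the RMSD between the selected atoms, and applies it to the whole mobile
#' set.
#'
#' @param mobile,reference Numeric `n x 3` coordinate matrices.
#' @param atom_subset Indices of the atoms used to fit (default: all).
#' @return List with `coords` (transformed mobile set) and `rmsd` (Å, over
#'   the fitted subset).
#' @export
kabsch_superpose <- function(mobile, reference, atom_subset = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(atom_subset)) atom_subset <- seq_len(nrow(mobile))
  if (length(atom_subset) < 3L) abort("need at least 3 atoms to superpose")
  P <- mobile[atom_subset, , drop = FALSE]
  Q <- reference[atom_subset, , drop = FALSE]
  if (nrow(P) != nrow(Q)) abort("subset sizes must match")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    abort("degenerate (collinear) atom subset: superposition is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- sweep(sweep(mobile, 2, cp) %*% t(R), 2, cq, "+")
  fitted <- moved[atom_subset, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(coords = moved, rmsd = rmsd, rotation = R)
}

#' Per-frame RMSD of an ensemble against a reference frame
#'
#' @param ens A [conformation_ensemble()].
#' @param reference_frame Frame index used as reference (default 1), or an
#'   `n x 3` coordinate matrix.
#' @param atom_subset Atom indices used for fitting and RMSD (default: Cα
#'   atoms).
#' @return Tibble with `frame`, `time_ns`, `rmsd`.
#' @export
rmsd_series <- function(ens, reference_frame = 1L, atom_subset = NULL) {
  if (is.null(atom_subset)) atom_subset <- ca_indices(ens$atoms)
  ref <- if (is.matrix(reference_frame)) reference_frame else frame_coords(ens, reference_frame)
  vals <- vapply(seq_len(ens$n_frames), function(i) {
    kabsch_superpose(frame_coords(ens, i), ref, atom_subset)$rmsd
  }, numeric(1))
  tibble(frame = seq_len(ens$n_frames), time_ns = ens$times, rmsd = vals)
}

window_frames <- function(ens, window) {
  if (is.null(window)) return(seq_len(ens$n_frames))
  idx <- which(ens$times >= window[1] & ens$times <= window[2])
  if (length(idx) < 2L) abort("time window selects fewer than 2 frames")
  idx
}

# Superpose frames onto their iterated mean structure (2 iterations) and
# return the superposed subset coordinates as frames x atoms x 3.
superpose_to_mean <- function(ens, frames, atom_subset, iterations = 2L) {
  co <- lapply(frames, function(i) frame_coords(ens, i)[atom_subset, , drop = FALSE])
  ref <- co[[1]]
  for (it in seq_len(iterations)) {
    co <- lapply(co, function(m) kabsch_superpose(m, ref)$coords)
    ref <- Reduce(`+`, co) / length(co)
  }
  co <- lapply(co, function(m) kabsch_superpose(m, ref)$coords)
  list(coords = co, mean = ref)
}

#' Per-residue RMSF over a time window
#'
#' Frames within the window are superposed onto their mean structure
#' (iterated twice), and the RMSF of residue *i* is the root mean squared
#' displacement of its Cα from its mean position across frames.
#'
#' @param ens A [conformation_ensemble()].
#' @param window `(t_start, t_end)` in ns, or `NULL` for all frames.
#' @param atom_subset Atom indices (default: Cα atoms).
#' @return Tibble with `resno`, `chain`, `rmsf` (Å).
#' @export
rmsf <- function(ens, window = NULL, atom_subset = NULL) {
  if (is.null(atom_subset)) atom_subset <- ca_indices(ens$atoms)
  frames <- window_frames(ens, window)
  sp <- superpose_to_mean(ens, frames, atom_subset)
  disp2 <- sapply(sp$coords, function(m) rowSums((m - sp$mean)^2))
  vals <- sqrt(rowMeans(disp2))
  tibble(chain = ens$atoms$chain[atom_subset],
         resno = ens$atoms$resno[atom_subset], rmsf = vals)
}

#' Block-resampled per-residue flexibility comparison of two ensembles
#'
#' Implements the block protocol for testing per-residue RMSF differences:
#' each ensemble's window is split into `n_blocks` contiguous equal-frame
#' blocks, the RMSF of every residue is computed independently per block,
#' and the two sets of block RMSFs are compared per residue with a Welch
#' two-sample t test.
#'
#' @param ens_a,ens_b [conformation_ensemble()] objects over the same atoms.
#' @param window `(t_start, t_end)` ns window applied to both (default: all
#'   frames).
#' @param n_blocks Number of blocks (default 5; must be at least 2 and each
#'   window must contain at least `2 * n_blocks` frames).
#' @param atom_subset Atom indices (default Cα).
#' @return Tibble of class `flexibility_comparison` with `chain`, `resno`,
#'   `rmsf_a`, `rmsf_b` (whole-window RMSFs), `t_statistic`, `p_value`.
#'   Identical ensembles give `t = 0`, `p = 1` everywhere.
#' @export
rmsf_difference_test <- function(ens_a, ens_b, window = NULL, n_blocks = 5L,
                                 atom_subset = NULL) {
  if (n_blocks < 2L) abort("n_blocks must be at least 2")
  if (is.null(atom_subset)) atom_subset <- ca_indices(ens_a$atoms)
  block_rmsf <- function(ens) {
    frames <- window_frames(ens, window)
    if (length(frames) < 2L * n_blocks) {
      abort(sprintf("window must contain at least %d frames (has %d)",
                    2L * n_blocks, length(frames)))
    }
    per <- length(frames) %/% n_blocks
    sapply(seq_len(n_blocks), function(b) {
      fr <- frames[((b - 1L) * per + 1L):(b * per)]
      sp <- superpose_to_mean(ens, fr, atom_subset)
      disp2 <- sapply(sp$coords, function(m) rowSums((m - sp$mean)^2))
      sqrt(rowMeans(disp2))
    })  # residues x blocks
  }
  ba <- block_rmsf(ens_a)
  bb <- block_rmsf(ens_b)
  nres <- nrow(ba)
  tt <- vapply(seq_len(nres), function(i) {
    a <- ba[i, ]; b <- bb[i, ]
    if (isTRUE(all.equal(a, b)) || (sd(a) < 1e-12 && sd(b) < 1e-12)) {
      return(c(0, 1))
    }
    ht <- t.test(a, b, var.equal = FALSE)
    c(unname(ht$statistic), ht$p.value)
  }, numeric(2))
  out <- tibble(
    chain = ens_a$atoms$chain[atom_subset],
    resno = ens_a$atoms$resno[atom_subset],
    rmsf_a = rmsf(ens_a, window, atom_subset)$rmsf,
    rmsf_b = rmsf(ens_b, window, atom_subset)$rmsf,
    t_statistic = tt[1, ], p_value = tt[2, ]
  )
  attr(out, "n_blocks") <- n_blocks
  attr(out, "window") <- window
  class(out) <- c("flexibility_comparison", class(out))
  out
}

#' @rdname rmsf_difference_test
#' @param object A `flexibility_comparison`.
#' @param ... Unused.
#' @method autoplot flexibility_comparison
#' @export
autoplot.flexibility_comparison <- function(object, ...) {
  top <- object %>%
    select("resno", "rmsf_a", "rmsf_b") %>%
    tidyr::pivot_longer(c("rmsf_a", "rmsf_b"), names_to = "ensemble",
                        values_to = "rmsf")
  df <- bind_rows(
    mutate(top, panel = "RMSF (A)", value = .data$rmsf),
    tibble(resno = object$resno, ensemble = "p",
           panel = "-log10 p", value = -log10(object$p_value))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$value,
                                   colour = .data$ensemble)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "residue", y = NULL) +
    ggplot2::theme_minimal()
}

#' Principal component analysis of ensemble coordinates
#'
#' Frames in the window are superposed onto their iterated mean structure,
#' flattened to `frames x (3 * atoms)` and decomposed with PCA.
#'
#' @inheritParams rmsf
#' @return List of class `ensemble_pca`: `projections` (tibble `frame`,
#'   `time_ns`, `PC1`, `PC2`, ...), `explained_variance` (non-increasing),
#'   `components` (orthonormal columns).
#' @export
coordinate_pca <- function(ens, window = NULL, atom_subset = NULL) {
  if (is.null(atom_subset)) atom_subset <- ca_indices(ens$atoms)
  frames <- window_frames(ens, window)
  if (length(frames) < 3L) abort("need at least 3 frames for PCA")
  sp <- superpose_to_mean(ens, frames, atom_subset)
  X <- t(sapply(sp$coords, function(m) as.numeric(t(m))))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  proj <- as_tibble(pc$x)
  proj <- dplyr::bind_cols(tibble(frame = frames, time_ns = ens$times[frames]),
                           proj)
  structure(list(projections = proj,
                 explained_variance = pc$sdev^2,
                 components = pc$rotation),
            class = "ensemble_pca")
}

#' @export
print.ensemble_pca <- function(x, ...) {
  ev <- x$explained_variance
  cat("<ensemble_pca>", nrow(x$projections), "frames;",
      sprintf("PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * ev[1] / sum(ev), 100 * ev[2] / sum(ev)))
  invisible(x)
}

#' Contact residence time of residue pairs across an ensemble
#'
#' A pair is "in contact" in a frame when the minimum heavy-atom distance
#' between the two residues is at most `cutoff` (default 4 Å); the residence
#' time is the percentage of frames in contact.
#'
#' @param ens A [conformation_ensemble()].
#' @param residue_pairs Tibble/data.frame with columns `resno_a`, `resno_b`
#'   (optionally `chain_a`, `chain_b`).
#' @param cutoff Contact cutoff in Å.
#' @param window Optional `(t_start, t_end)` ns window.
#' @return The input pairs with a `residence_pct` column.
#' @export
contact_residence <- function(ens, residue_pairs, cutoff = 4.0, window = NULL) {
  frames <- window_frames(ens, window)
  a <- ens$atoms
  heavy <- a$element != "H"
  pct <- purrr::map_dbl(seq_len(nrow(residue_pairs)), function(r) {
      pa <- residue_pairs[r, ]
      ia <- which(heavy & a$resno == pa$resno_a &
                    (if ("chain_a" %in% names(pa)) a$chain == pa$chain_a else TRUE))
      ib <- which(heavy & a$resno == pa$resno_b &
                    (if ("chain_b" %in% names(pa)) a$chain == pa$chain_b else TRUE))
      if (!length(ia) || !length(ib)) abort("residue pair not found in ensemble atoms")
      hits <- vapply(frames, function(f) {
        co <- frame_coords(ens, f)
        min(cross_dist2(co[ia, , drop = FALSE], co[ib, , drop = FALSE])) <= cutoff^2
      }, logical(1))
      100 * mean(hits)
    })
  out <- as_tibble(residue_pairs)
  out$residence_pct <- pct
  out
}
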