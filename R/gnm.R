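# Gaussian network model: Kirchhoff connectivity of the Cα trace, its
# eigendecomposition, slow-mode extraction and hinge detection.

#' Build a Gaussian network model of a structure
#'
#' Places a unit spring between every pair of Cα atoms within `cutoff`
#' (default 10 Å, i.e. 1 nm). The Kirchhoff (graph Laplacian) matrix has
#' off-diagonal entries -1 for connected pairs and row sums of zero; its
#' eigendecomposition orders eigenvalues ascending. One zero eigenvalue is
#' expected for a connected contact network; additional zero modes indicate
#' a disconnected network and are reported with a warning.
#'
#' @param structure A [protein_structure()] with at least 3 Cα atoms.
#' @param cutoff Contact cutoff in Å.
#' @return Object of class `gnm` with elements `kirchhoff`, `cutoff`,
#'   `eigenvalues` (ascending), `eigenvectors` (columns matched to
#'   eigenvalues), `n_zero_modes`, `residues` (tibble `chain`, `resno`).
#' @export
build_gnm <- function(structure, cutoff = 10.0) {
  ca <- calpha_coords(structure)
  n <- nrow(ca)
  if (n < 2L) abort("need at least 2 CA atoms to build a network model")
  d <- as.matrix(dist(ca))
  K <- -(d <= cutoff) * 1
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  e <- eigen(K, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  nz <- sum(abs(vals) <= 1e-8)
  if (nz > 1L) {
    warn(sprintf("contact network is disconnected: %d zero modes (%d components)",
                 nz, nz))
  }
  res <- structure$residues %>% filter(!is.na(.data$ca)) %>%
    select("chain", "resno")
  structure(list(kirchhoff = K, cutoff = cutoff, eigenvalues = vals,
                 eigenvectors = vecs, n_zero_modes = nz, residues = res),
            class = "gnm")
}

#' @export
print.gnm <- function(x, ...) {
  cat("<gnm>", nrow(x$kirchhoff), "nodes, cutoff", x$cutoff, "A,",
      x$n_zero_modes, "zero mode(s)\n")
  cat("slowest nontrivial eigenvalues:",
      paste(sprintf("%.3f", head(x$eigenvalues[-seq_len(x$n_zero_modes)], 5)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Extract a nontrivial GNM mode
#'
#' Mode `k = 1` is the slowest nontrivial mode (the first eigenvector with a
#' nonzero eigenvalue); zero modes are skipped. The sign convention makes
#' the first nonzero component positive so modes are reproducible.
#'
#' @param enm A [build_gnm()] object.
#' @param k 1-based nontrivial mode index.
#' @return Named numeric vector of per-residue eigenvector components
#'   (names `chain:resno`).
#' @export
gnm_mode <- function(enm, k = 1L) {
  stopifnot(inherits(enm, "gnm"))
  n <- length(enm$eigenvalues)
  if (k < 1L || k > n - enm$n_zero_modes) {
    abort(sprintf("mode index must be in 1..%d", n - enm$n_zero_modes))
  }
  v <- enm$eigenvectors[, enm$n_zero_modes + k]
  first <- which(abs(v) > 1e-12)[1]
  if (!is.na(first) && v[first] < 0) v <- -v
  setNames(v, paste0(enm$residues$chain, ":", enm$residues$resno))
}

#' Tidy a GNM into its eigen-spectrum
#'
#' @param x A `gnm`.
#' @param ... Unused.
#' @return Tibble with `mode` (0 for zero modes), `eigenvalue`.
#' @method tidy gnm
#' @export
tidy.gnm <- function(x, ...) {
  nz <- x$n_zero_modes
  tibble(index = seq_along(x$eigenvalues),
         nontrivial_mode = c(rep(NA_integer_, nz),
                             seq_len(length(x$eigenvalues) - nz)),
         eigenvalue = x$eigenvalues)
}

#' Find hinge residues of a GNM mode
#'
#' A residue is a hinge if its mode component magnitude is at most
#' `tolerance` (near-zero plateau) or if its component sign differs from
#' its predecessor's along the chain (zero crossing). In a slow mode, these
#' are the residues separating blocks that move in opposite directions.
#'
#' @param mode_vector Per-residue mode components, as from [gnm_mode()].
#' @param structure The [protein_structure()] the mode was computed from
#'   (supplies residue numbering). Optional if `mode_vector` is named.
#' @param tolerance Component-magnitude threshold; default
#'   `0.05 * max(abs(mode_vector))`, so flat near-zero plateaus are caught
#'   as well as exact sign flips.
#' @return Tibble of class `hinge_set` with `chain`, `resno`, `component`,
#'   `zero_crossing` (logical).
#' @export
find_hinges <- function(mode_vector, structure = NULL, tolerance = NULL) {
  v <- as.numeric(mode_vector)
  if (!is.null(structure)) {
    res <- structure$residues %>% filter(!is.na(.data$ca))
    if (nrow(res) != length(v)) {
      abort("mode vector length must equal the structure's CA residue count")
    }
    chain <- res$chain; resno <- res$resno
  } else if (!is.null(names(mode_vector))) {
    parts <- stringr::str_split_fixed(names(mode_vector), ":", 2)
    chain <- parts[, 1]; resno <- as.integer(parts[, 2])
  } else {
    chain <- rep("A", length(v)); resno <- seq_along(v)
  }
  if (is.null(tolerance)) tolerance <- 0.05 * max(abs(v))
  near_zero <- abs(v) <= tolerance
  flip <- c(FALSE, v[-1] * v[-length(v)] < 0)
  hinge <- near_zero | flip
  out <- tibble(chain = chain, resno = resno, component = v,
                zero_crossing = flip)[hinge, , drop = FALSE]
  class(out) <- c("hinge_set", class(out))
  out
}

#' Plot a GNM mode with hinge residues highlighted
#'
#' @param enm A [build_gnm()] object.
#' @param k Nontrivial mode index.
#' @param tolerance Passed to [find_hinges()].
#' @return A ggplot: mode component per residue, hinges marked.
#' @export
plot_gnm_mode <- function(enm, k = 1L, tolerance = NULL) {
  v <- gnm_mode(enm, k)
  df <- tibble(resno = enm$residues$resno, chain = enm$residues$chain,
               component = as.numeric(v))
  hinges <- find_hinges(v, tolerance = tolerance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = hinges, ggplot2::aes(xintercept = .data$resno),
                        colour = "red", alpha = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "residue", y = sprintf("mode %d eigenvector component", k)) +
    ggplot2::theme_minimal()
}
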