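# Shrake-Rupley solvent accessible surface area on heavy atoms, with the
# Fibonacci-lattice sphere sampling and the <= 20 A^2 "buried" rule.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Express coordinates in a molecule-intrinsic frame (centroid origin,
# principal axes of the atom cloud, signs and handedness fixed) so the
# sphere-point lattice rotates with the molecule and reported areas are
# invariant to rigid motion of the input.
canonical_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  if (nrow(X) == 1L) return(X)
  ev <- eigen(crossprod(X), symmetric = TRUE)$vectors
  # intrinsic sign convention: orient each axis by the atom-order moment of
  # the projections (falling back to their skewness), then make the frame
  # right-handed; these functionals move with the molecule, so the frame is
  # identical after any rigid motion of the input
  w <- seq_len(nrow(X)) - (nrow(X) + 1) / 2
  for (k in 1:2) {
    p <- X %*% ev[, k]
    m1 <- sum(w * p)
    crit <- if (abs(m1) > 1e-6 * sqrt(sum(p^2))) m1 else sum(p^3)
    if (crit < 0) ev[, k] <- -ev[, k]
  }
  ev[, 3] <- c(ev[2, 1] * ev[3, 2] - ev[3, 1] * ev[2, 2],
               ev[3, 1] * ev[1, 2] - ev[1, 1] * ev[3, 2],
               ev[1, 1] * ev[2, 2] - ev[2, 1] * ev[1, 2])
  X %*% ev
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Per-residue solvent accessible surface area (Shrake-Rupley)
#'
#' Heavy-atom SASA: each atom's sphere of radius `vdW + probe` is sampled at
#' `n_sphere_points` Fibonacci-lattice points; points falling inside any
#' neighbouring atom's probe-expanded sphere are occluded, and the
#' accessible fraction is converted to area. Hydrogens are excluded; atoms
#' whose element is not in the radius table (C 1.70, N 1.55, O 1.52,
#' S 1.80 Å) raise an error naming the atom.
#'
#' @param structure A [protein_structure()].
#' @param probe Probe radius in Å (default 1.4, a water molecule).
#' @param n_sphere_points Sample points per atom (default 960).
#' @return Tibble of class `sasa_profile` with `chain`, `resno`, `resid`,
#'   `area` (Å²) and `buried` (`area <= 20`).
#' @export
sasa <- function(structure, probe = 1.4, n_sphere_points = 960L) {
  a <- structure$atoms %>% filter(.data$element != "H")
  if (nrow(a) == 0L) abort("structure has no heavy atoms")
  unknown <- !a$element %in% names(VDW_RADII)
  if (any(unknown)) {
    bad <- a[unknown, ][1, ]
    abort(sprintf("no van der Waals radius for element '%s' (atom %s of %s %s:%d)",
                  bad$element, bad$elety, bad$resid, bad$chain, bad$resno))
  }
  xyz <- canonical_frame(as.matrix(a[, c("x", "y", "z")]))
  r <- VDW_RADII[a$element] + probe
  pts <- fibonacci_sphere(n_sphere_points)
  n <- nrow(xyz)
  area <- numeric(n)
  tol <- 1e-8
  d2 <- cross_dist2(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] <= (r[i] + r)^2 & seq_len(n) != i)
    sp <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        # points strictly inside a neighbour are buried; points exactly on a
        # neighbour's surface (duplicate atoms) are assigned to the
        # lower-index atom so shared surface is counted once
        buried <- dj2 < r[j]^2 - tol | (abs(dj2 - r[j]^2) <= tol & j < i)
        acc <- acc & !buried
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    area[i] <- frac * 4 * pi * r[i]^2
  }
  out <- a %>%
    mutate(.area = area) %>%
    group_by(.data$chain, .data$resno) %>%
    summarise(resid = .data$resid[1], area = sum(.data$.area), .groups = "drop") %>%
    mutate(buried = .data$area <= 20) %>%
    arrange(.data$chain, .data$resno)
  attr(out, "probe_radius") <- probe
  attr(out, "n_sphere_points") <- n_sphere_points
  class(out) <- c("sasa_profile", class(out))
  out
}
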