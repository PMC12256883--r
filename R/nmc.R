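# Nonrandom mutational clustering (NMC): order-statistic detection of
# improbably tight 1D clusters of mutation positions under a uniform null.

#' Detect nonrandom 1D clusters of mutation positions
#'
#' Under the null that `n` mutation positions fall uniformly on a protein of
#' length `L`, the fractional span between the i-th and j-th order
#' statistics, `(x(j) - x(i)) / L`, follows a Beta(j - i, n - j + i + 1)
#' distribution. Every ordered pair (i < j) is tested for being improbably
#' small; p-values are Bonferroni-corrected over all n(n-1)/2 pairs, and
#' significant pairs are merged into maximal overlapping cluster calls.
#' Because positions are discrete residues, spans carry a +1 continuity
#' correction (the continuous span underlying a discrete span `d` is at most
#' `(d + 1) / L`), which keeps chance collisions of integer positions from
#' producing spurious zero-span calls. Recurrent mutations at one residue
#' still enter as separate order statistics, so true hotspots are detected.
#'
#' @param positions 1-based residue positions of (missense) mutations; one
#'   entry per observed mutation.
#' @param protein_length Protein length in residues.
#' @param alpha Significance level applied to the corrected p-values
#'   (default 0.05).
#' @return A tibble with columns `start_residue`, `end_residue`,
#'   `corrected_p` (the smallest corrected pair p-value merged into the
#'   call), ordered by `start_residue`. Empty when `length(positions) < 2`
#'   or nothing is significant.
#' @export
nmc_clusters <- function(positions, protein_length, alpha = 0.05) {
  stopifnot(protein_length >= 1, alpha > 0, alpha <= 1)
  x <- sort(as.numeric(positions))
  n <- length(x)
  if (any(x < 1 | x > protein_length)) {
    abort("positions must lie within [1, protein_length]")
  }
  empty <- tibble(start_residue = integer(), end_residue = integer(),
                  corrected_p = numeric())
  if (n < 2L) return(empty)
  ij <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  k <- j - i
  # +1 continuity correction: positions are discrete residues, so the
  # continuous-uniform span u(j) - u(i) is bounded above by (d + 1) / L;
  # without it, chance collisions of integer positions give zero spans and
  # spurious p = 0 calls
  span <- pmin(1, (x[j] - x[i] + 1) / protein_length)
  p <- pbeta(span, k, n - k + 1)
  m <- n * (n - 1) / 2
  p_corr <- pmin(1, p * m)
  sig <- which(p_corr <= alpha)
  if (length(sig) == 0L) return(empty)
  iv <- tibble(start = x[i[sig]], end = x[j[sig]], p = p_corr[sig]) %>%
    arrange(.data$start, .data$end)
  # merge overlapping significant intervals into maximal calls
  out_s <- numeric(0); out_e <- numeric(0); out_p <- numeric(0)
  cs <- iv$start[1]; ce <- iv$end[1]; cp <- iv$p[1]
  if (nrow(iv) > 1L) {
    for (r in 2:nrow(iv)) {
      if (iv$start[r] <= ce) {
        ce <- max(ce, iv$end[r]); cp <- min(cp, iv$p[r])
      } else {
        out_s <- c(out_s, cs); out_e <- c(out_e, ce); out_p <- c(out_p, cp)
        cs <- iv$start[r]; ce <- iv$end[r]; cp <- iv$p[r]
      }
    }
  }
  out_s <- c(out_s, cs); out_e <- c(out_e, ce); out_p <- c(out_p, cp)
  tibble(start_residue = as.integer(out_s), end_residue = as.integer(out_e),
         corrected_p = out_p)
}
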