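---
title: "Signature-aware selection analysis of cancer mutations on protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-aware selection analysis of cancer mutations on protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structselect)
```

## The question the package answers

Somatic mutation catalogs tell us *where* a protein is mutated in tumors;
they do not by themselves tell us whether those positions are *unusual*.
Mutational processes are strongly sequence-biased — a C>T in an NpCpG
context is far more likely than most other changes — so mutations cluster
in some codons for purely chemical reasons. Before interpreting mutations
as functionally selected (for example, "they fall near the hinge of the
protein's slow collective motion"), one must ask: would the mutational
process alone, with no selection, have produced mutations this extreme?

`structselect` formalises that question as a conditional Monte-Carlo test.
The pipeline is:

1. estimate the cohort's **96-channel trinucleotide mutational signature**;
2. enumerate the gene's **mutation universe** — every single-nucleotide
   change of the coding sequence that yields a missense mutation — and
   weight each entry by the signature probability of its context;
3. attach a **structural metric** to every possible mutation (distance to
   hinge residues from an elastic network model, a folding-energy change
   from an external ΔΔG table, solvent accessibility, ...);
4. compare the observed mutations' mean metric with the distribution of
   means of signature-weighted random draws.

Companion analyses cover the rest of a typical study of this kind:
signature-conditioned dN/dS, one-dimensional mutation clustering,
alignment conservation, conformational-ensemble statistics, and
Kaplan–Meier survival comparison. Synthetic-data generators with known
ground truth make the whole pipeline testable offline.

## The mutational-signature null

A signature is a probability vector over the 96 classes formed by the six
pyrimidine-centred substitutions (C>A, C>G, C>T, T>A, T>C, T>G) crossed
with the 5' and 3' flanking bases; purine-centred changes are
reverse-complemented onto this frame. `estimate_signature()` counts
channels over the cohort and smooths with a pseudocount (default 0.5 —
small cohorts never produce impossible channels):

\[
\hat p_c = \frac{n_c + \alpha}{N + 96\alpha}.
\]

The signature is estimated from coding-sequence context counts without
genome-wide opportunity normalisation. This is a deliberate
simplification: the same convention is applied to both the observed and
the expected side of every downstream test, so the shared bias cancels
within a gene. It does mean cross-gene comparisons inherit the genes'
context composition; tools built around full trinucleotide-opportunity
models (e.g. the dndscv family) handle that differently, and we flag it
as a known limitation.

## The Monte-Carlo selection test

`build_universe()` enumerates all \(3L\) substitutions of a CDS, keeps the
missense ones, and assigns entry \(i\) in channel \(c(i)\) the weight
\(w_i \propto \hat p_{c(i)}\). `monte_carlo_selection_test()` then draws
`n_observed` entries **with replacement** (mutations recur independently
across tumors) `n_permutations` times (default 100,000), computes the mean
metric of each draw, and reports

\[
p = \frac{b + 1}{n_{\mathrm{perm}} + 1},
\]

where \(b\) counts permutation means at least as extreme as the observed
mean. The add-one rule keeps \(p > 0\) at finite permutation counts. The
test statistic is the **mean** of the drawn set (switchable to the
median): the hypotheses of interest here are location shifts — "closer to
hinges than expected" — and the mean is the interpretable location summary
of Monte-Carlo mean-vs-mean comparisons. Tails: `lower` ("smaller metric
than expected", e.g. closer to hinges), `upper`, or two-sided by doubling
the smaller tail, capped at 1. Two conventions are fixed for degenerate
inputs: a metric that is constant over the universe yields effect 0 and
\(p = 1\); an observed mutation missing from the universe or from the
metric's coverage is a hard error, never silently imputed.

## dN/dS with a Poisson likelihood-ratio test

For one gene, let \(N, S\) be observed nonsynonymous (missense + nonsense)
and synonymous counts, and \(e_N, e_S\) the signature-expected proportions
from enumerating all coding changes. The model is

\[
N \sim \mathrm{Pois}(\mu\, e_N\, \omega), \qquad
S \sim \mathrm{Pois}(\mu\, e_S),
\]

with \(\mu\) profiled out. The estimate is
\(\hat\omega = (N/e_N)/(S/e_S)\) and the test is the 1-df likelihood-ratio
test of \(\omega = 1\). When \(S = 0\) the ratio is undefined; the
function applies a flagged 0.5 pseudo-count to all four quantities and
warns, rather than failing or silently truncating. This is a deliberately
minimal dN/dS: it omits per-channel rate matrices and covariate regression,
so estimates on real cohorts are approximate relative to the full
dndscv-style machinery.

## Nonrandom mutational clustering

`nmc_clusters()` tests every pair of order statistics of the mutation
positions: under a uniform null on a protein of length \(L\), the
fractional span between the \(i\)-th and \(j\)-th of \(n\) ordered
positions follows \(\mathrm{Beta}(j-i,\; n-j+i+1)\). Two details matter in
practice:

* **Discreteness.** Residue positions are integers, so chance collisions
  produce zero spans, and the continuous beta null would call them
  infinitely significant. We therefore test the corrected span
  \((x_{(j)} - x_{(i)} + 1)/L\), an upper bound on the underlying
  continuous span. Without the correction, uniformly random positions
  trigger calls in well over half of simulations; with it the any-call
  rate sits below the nominal level (the test is conservative, as
  Bonferroni over all \(n(n-1)/2\) pairs is).
* **Recurrence.** Recurrent mutations at one residue enter as separate
  order statistics, so true hotspots still produce extreme spans and are
  detected essentially always.

Significant pairs (after Bonferroni) are merged into maximal overlapping
cluster calls. Merging can join two nearby tight clusters through a
bridging significant pair; the reported `corrected_p` of a call is the
smallest corrected pair p-value inside it.

## Gaussian network model and hinges

`build_gnm()` places unit springs between Cα atoms within 10 Å (1 nm) and
forms the Kirchhoff (graph Laplacian) matrix: off-diagonal \(-1\) for
contacts, diagonal minus the row sum. Eigenvalues are reported ascending;
a connected contact graph has exactly one zero mode, and extra zero modes
(counted at \(|\lambda| \le 10^{-8}\)) indicate a disconnected network and
trigger a warning. `gnm_mode(enm, k)` returns the \(k\)-th **nontrivial**
mode with a fixed sign convention (first nonzero component positive).
Published analyses sometimes index modes including the trivial one or
describe the hinge mode as "second" when the slowest mode is dominated by
a disordered terminus; the explicit mode index makes either reading
reproducible. One further terminological note: hinges are residues where
the mode **eigenvector components** are near zero (not the eigenvalues —
eigenvalues are per-mode, not per-residue); `find_hinges()` flags a
residue when its component magnitude is at most `tolerance` (default 5% of
the mode's maximum magnitude — a pure sign-change rule misses flat
near-zero plateaus) or when its sign differs from its predecessor's.

## Solvent accessibility and interfaces

`sasa()` is a Shrake–Rupley implementation on heavy atoms: each atom's
probe-expanded sphere (van der Waals radii C 1.70, N 1.55, O 1.52,
S 1.80 Å; probe 1.4 Å) is sampled at 960 Fibonacci-lattice points, points
inside any neighbour's expanded sphere are buried, and per-atom areas sum
per residue. Residues at or below 20 Å² are labelled buried. Two numerical
choices are worth stating. First, coordinates are re-expressed in a
molecule-intrinsic frame (centroid origin, principal axes, signs fixed by
intrinsic moments of the projections) before the lattice is laid down, so
reported areas are exactly invariant under rigid motion of the input —
a fixed laboratory-frame lattice would make areas drift by
\(O(1/\sqrt{n_{\text{points}}})\) under rotation. Second, points exactly
on a neighbour's surface (duplicate atoms) are assigned to the
lower-index atom, so coincident duplicates count their shared surface
once. `interface_residues()` implements the "within 10 Å of the binding
partner" rule with heavy-atom distances, checked against a brute-force
all-pairs oracle in the tests.

## Ensemble analysis

Conformational ensembles are ingested as multi-model PDB files with frame
times from a sidecar TSV (or a uniform-spacing flag). Binary MD trajectory
formats are intentionally out of scope — converting a trajectory to
multi-model PDB is a one-liner in any MD toolchain, and it keeps this
package's format surface small and text-only.

* `kabsch_superpose()` computes the optimal proper rotation by SVD;
  collinear fitting subsets are rejected.
* `rmsf()` superposes the windowed frames onto their mean structure,
  iterated twice (fit → new mean → refit), a common convention when the
  protocol leaves the reference unstated, then reports per-residue root
  mean squared displacement. For isotropic per-axis noise of scale
  \(\sigma\) the expected RMSF is \(\sigma\sqrt{3}\); the global fit
  absorbs six rigid degrees of freedom, which shrinks RMSF by roughly
  \(\sqrt{1 - 6/(3n)}\) (about 1.6% at 64 residues) — visible in the
  recovery ratio the acceptance script reports.
* `rmsf_difference_test()` implements a block protocol: each window is cut
  into `n_blocks` contiguous equal-frame blocks (default 5; the underlying
  protocol in the field does not fix a count), block RMSFs are computed
  independently, and each residue gets a Welch two-sample t test across
  blocks. Welch rather than pooled variance because the working hypothesis
  is precisely that variances differ between the two ensembles. Identical
  inputs give \(t = 0, p = 1\) exactly. A known artifact: because frames
  are superposed globally, a strongly flexible segment perturbs the fit of
  all residues slightly, which can push a few unaffected residues below
  loose thresholds; flagging at \(p < 0.01\) keeps specificity high.
* `coordinate_pca()` runs PCA on superposed, flattened coordinates;
  `contact_residence()` reports the percentage of frames with minimum
  heavy-atom distance within 4 Å.

## Survival and conservation

Kaplan–Meier curves and the two-group log-rank test are delegated to the
`survival` package (`survfit`/`survdiff`, hypergeometric-variance ties
handling; patients censored at an event time count as at risk at that
time) behind a tidy interface; the unit tests check both against
hand-rolled product-limit and textbook log-rank oracles. Grouping patients
into "altered"/"WT" is a caller decision (`label_altered()` implements the
nonsynonymous-or-copy-number rule) because which copy-number calls qualify
is study-specific.

Conservation scoring is intentionally simple and fully specified: a
column's score is the count of its most frequent non-gap residue divided
by the number of sequences (ties broken alphabetically; all-gap columns
score 0 with an `NA` majority). Motif boxes are maximal runs of columns at
or above `min_score` (default 1.0), bridging at most `max_gap` (default 1)
weak columns, of span at least `min_length` (default 2). These defaults
reproduce box-like runs on synthetic alignments with planted conserved
runs; on real paralog alignments the box count depends on the thresholds,
which published figures typically leave unstated, so box recovery there is
qualitative. Percent identity divides identical aligned pairs by the
number of columns where **neither** sequence is gapped, so terminal
extensions of one sequence do not dilute identity; unaligned inputs are
first globally aligned (Needleman–Wunsch, BLOSUM62, gap open 10 /
extend 0.5 via Biostrings).

## The synthetic-data generators

Every input class can be generated with known ground truth, and every
generator is deterministic given its seed and emits a machine-readable
ground-truth record (`ground_truth()`, `write_ground_truth()`).

* `make_two_domain_structure()` builds two compact random-coil Cα globules
  (backbone spacing 3.8 Å; domain radius from a protein-like packing
  density of 0.008 residues/Å³) joined by an extended linker (3.6 Å/residue
  along the inter-domain axis). Each domain is rotated about its
  attachment so the linker leaves from the domain surface — without this
  the linker hugs one domain, inherits its contacts, and the slow-mode
  sign change migrates to the other domain's boundary. With it, the
  slowest nontrivial GNM mode hinges inside the linker in 100/100 seeds,
  which is the planted ground truth.
* `make_mutation_cohort()` samples **channel-first**: a channel from the
  signature, then a site uniformly within that channel, so at
  `enrichment_fold = 1` the empirical context distribution converges to
  the signature exactly (this is what lets the signature-recovery test ask
  for ±0.01 per channel at n = 10,000). Spatial selection multiplies site
  weights by `enrichment_fold` within `k = 5` residues of the targets
  (sequence mode, the default, needs no structure) or within 10 Å of their
  Cα atoms when a structure is supplied. Note the analysis-side universe
  keeps its own convention (site weight proportional to channel
  probability); the two coincide channel-by-channel up to within-channel
  site multiplicity, and the selection-test calibration draws its null
  sets from the universe itself, so the test is exercised against its own
  null.
* `make_dnds_cohort()` draws each mutation nonsynonymous with probability
  \(\omega e_N / (\omega e_N + e_S)\) per gene — consistent with the
  estimator's expected side, so \(\omega\) recovery is unbiased in rate
  space (the log2 ratio carries the usual small-sample Jensen bias of a
  few hundredths at 50 mutations/gene).
* `make_ensemble()` adds independent isotropic Gaussian displacement per
  residue plus a random global rigid transform per frame, so superposition
  is always exercised. The noise is frame-independent: block statistics
  are calibrated for the *statistics*, not for MD physics — autocorrelated
  real trajectories need longer blocks than white noise, and passing tests
  here say nothing about choosing block lengths on real data.
* `make_survival_cohort()` uses exponential event times (arm A median 24
  months; arm B hazard multiplied by the hazard ratio) with independent
  exponential censoring calibrated to the requested censored fraction.

## Problem sizes and test design

The test-suite and acceptance-script problem sizes are chosen as the
smallest that make each check statistically meaningful: 100 seeded
structures for hinge recovery; 500 null tests of 2,000 permutations for
selection-test calibration (a Kolmogorov–Smirnov check against
uniformity); 100 seeds at enrichment 10 and 50 observed mutations for
power; 1,000 neutral genes of 120 codons with 50 mutations each for dN/dS
calibration and 200 genes at \(\omega = 4\) for recovery; 1,000
simulations for NMC and log-rank calibration; 2,000 frames for RMSF
recovery and 500 frames per ensemble, 5 blocks, for the flexibility
comparison. At these sizes the full suite runs in about a minute on one
core.

## Known limitations

* No genome-wide context-opportunity normalisation in the signature (see
  above); no decomposition into reference COSMIC signatures.
* Indels and copy-number events are not modelled — substitutions only.
* The NMC merge step can fuse nearby clusters through bridging pairs;
  Bonferroni makes the test conservative.
* The block flexibility test treats blocks as independent samples; on
  autocorrelated trajectories the effective sample size is smaller than
  the block count.
* External energy tables (e.g. FoldX ΔΔG) are parsed and consumed, never
  recomputed; mmCIF and binary trajectory formats are not read.
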