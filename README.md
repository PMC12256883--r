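# structselect

Signature-aware selection analysis of cancer mutations on protein
structures.

## The problem

Cancer mutation catalogs (COSMIC exports, MAF files) show *where* genes
are mutated; they do not show whether those positions are surprising.
Mutational processes are heavily biased by trinucleotide context, so some
codons accumulate mutations for purely chemical reasons. `structselect`
is for computational biologists who want to test, rather than eyeball,
statements like "the observed mutations sit closer to the protein's hinge
residues than expected" or "this gene carries more nonsynonymous change
than its sequence context predicts".

The package conditions every test on the cohort's mutational signature:

- **Signature estimation** — the 96-channel pyrimidine-centred
  substitution-in-context probability vector
  `p̂_c = (n_c + α) / (N + 96α)`.
- **Mutation universe** — all single-nucleotide missense changes of a
  coding sequence, each weighted by the signature probability of its
  context.
- **Monte-Carlo selection test** — draw `n_observed` mutations from the
  weighted universe with replacement, `n_perm` times; compare the observed
  mean of any per-mutation structural metric (distance to hinges, ΔΔG,
  SASA) against the permutation means; `p = (b + 1) / (n_perm + 1)`.
- **dN/dS** — `ω̂ = (N/e_N)/(S/e_S)` with a 1-df Poisson likelihood-ratio
  test of `ω = 1`, where `e_N : e_S` are signature-expected proportions.
- **NMC clustering** — order-statistic test of 1D mutation clusters: the
  span of order statistics `(x(j) − x(i) + 1)/L` against
  `Beta(j−i, n−j+i+1)`, Bonferroni over all pairs.
- **Structure layer** — Gaussian network model (Cα Kirchhoff matrix, 10 Å
  cutoff), slow modes and hinge residues, Shrake–Rupley SASA with the
  ≤ 20 Å² buried rule, 10 Å interface residues.
- **Ensemble layer** — Kabsch superposition, RMSD/RMSF, block-resampled
  Welch tests for per-residue flexibility differences, PCA, 4 Å contact
  residence times, for conformational ensembles supplied as multi-model
  PDB.
- **Cohort layer** — Kaplan–Meier curves and the log-rank test.
- **Synthetic data** — generators for every input class with known ground
  truth (planted hinges, planted selection, planted ω, planted
  flexibility, planted hazard ratios).

All tabular inputs and outputs are tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate a two-domain protein with a planted hinge, find the hinge from
the elastic-network slow mode, simulate a mutation cohort enriched near
the hinge under a random mutational signature, and test for selection:

```r
library(structselect)

structure <- make_two_domain_structure(n_per_domain = 30, linker_length = 4, seed = 101)
enm       <- build_gnm(structure, cutoff = 10)
hinges    <- find_hinges(gnm_mode(enm, 1), structure)
hinges$resno
#> [1] 33                                  # inside the planted linker 31-34

signature <- random_signature(seed = 7)
gene      <- random_coding_gene(64, seed = 8, gene = "TOY")
universe  <- build_universe(gene, signature)
cohort    <- make_mutation_cohort(gene, signature, n_mutations = 40,
                                  target_residues = hinges$resno,
                                  enrichment_fold = 8, seed = 9,
                                  classes = "missense", structure = structure)

dist_map <- distance_to_residue_set(structure, hinges$resno)
metric   <- function(pos, ref_aa, alt_aa) dist_map$distance[match(pos, dist_map$resno)]
fit <- monte_carlo_selection_test(cohort, universe, metric,
                                  n_permutations = 100000, seed = 10,
                                  tail = "lower")
fit
#> <selection_test>
#>   observed mean 13.11 vs expected 17.35 (effect -4.246)
#>   Monte-Carlo p = 1e-05 (lower tail, 100000 permutations, n = 40)
```

The observed mutations average 13.1 Å from the hinge set versus 17.4 Å
expected under the signature alone: the planted enrichment is recovered as
a significant lower-tail shift. The same cohort shows a 1D cluster over
the hinge region:

```r
nmc_clusters(cohort$protein_position, protein_length = 64)
#> # A tibble: 1 × 3
#>   start_residue end_residue corrected_p
#> 1            31          36      0.0281
```

`tidy(fit)` returns the one-row summary as a tibble, and `autoplot(fit)`
draws the permutation distribution with the observed mean marked. Real
data enter through `read_mutation_table()` (COSMIC export / MAF-like /
simple TSV dialects), `read_cds_fasta()`, `read_clustal()`, `read_pdb()`,
`read_ensemble()`, `read_metric_table()` / `read_foldx_dif()` and
`read_survival_tsv()`.

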