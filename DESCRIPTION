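Package: structselect
Title: Signature-Aware Selection Analysis of Cancer Mutations on Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking whether the somatic mutations observed in a cancer
    cohort are unusual with respect to a structural property of the mutated
    protein. The package estimates a 96-channel trinucleotide mutational
    signature from a mutation catalog, enumerates the signature-weighted
    universe of possible missense changes of a coding gene, and compares
    observed mutations to that null by Monte-Carlo permutation against any
    per-mutation structural metric (distance to elastic-network hinge
    residues, folding energy change, solvent accessibility). It also provides
    a signature-conditioned Poisson dN/dS estimate with a likelihood-ratio
    test, order-statistic detection of one-dimensional mutation clusters,
    Gaussian-network-model mode and hinge computation, Shrake-Rupley solvent
    accessible surface area, conformational-ensemble statistics (Kabsch
    superposition, RMSD, RMSF, block-resampled flexibility comparison, PCA,
    contact residence times), alignment conservation scoring, Kaplan-Meier
    survival comparison, and synthetic-data generators with known ground
    truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
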