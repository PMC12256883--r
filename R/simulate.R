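# Synthetic-data generators with known ground truth for every input class
# the pipeline consumes. All generators are deterministic given their seed
# and attach a machine-readable ground-truth record to their output.

set_truth <- function(x, truth) {
  attr(x, "ground_truth") <- truth
  x
}

#' Ground truth attached to a generated dataset
#'
#' @param x A generator output.
#' @return The ground-truth list (planted hinge residues, selection
#'   strength, signature, per-residue sigma, hazard ratio — whichever
#'   applies).
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' @rdname ground_truth
#' @param path JSON output path.
#' @export
write_ground_truth <- function(x, path) {
  truth <- ground_truth(x)
  truth <- purrr::map(truth, function(v) if (inherits(v, "mutational_signature")) as.numeric(v) else v)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

random_unit <- function(n = 1) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# confined random-coil walk: successive points 3.8 A apart, pulled back
# toward `center` whenever the walk strays past `radius`
coil_walk <- function(n, center, radius, start = center) {
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- start
  for (i in seq_len(n - 1L)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      dir <- random_unit()
      off <- pos[i, ] - center
      r <- sqrt(sum(off^2))
      if (r > 0.6 * radius) {
        pull <- (center - pos[i, ]) / r
        dir <- dir + 1.5 * (r / radius) * pull
        dir <- dir / sqrt(sum(dir^2))
      }
      cand <- pos[i, ] + 3.8 * dir
      # light self-avoidance: reject steps that collide with earlier residues
      if (tries > 50L || i < 3L ||
          min(rowSums(sweep(pos[1:(i - 1L), , drop = FALSE], 2, cand)^2)) > 3.2^2) {
        pos[i + 1L, ] <- cand
        break
      }
    }
  }
  pos
}

#' Generate a toy two-domain structure with a planted hinge
#'
#' Two compact random-coil globules (Cα trace, 3.8 Å spacing, domain radius
#' scaled so intradomain contacts dominate) joined by an extended linker.
#' The slowest nontrivial GNM mode of such a structure is the anticorrelated
#' motion of the two domains, with its sign change in the linker — the
#' planted hinge.
#'
#' @param n_per_domain Residues per domain (at least 10; default 30).
#' @param linker_length Residues in the extended linker (default 4; 0 gives
#'   a single-domain control with no planted hinge).
#' @param seed Integer seed.
#' @return A [protein_structure()] (Cα-only, chain A) with ground truth
#'   `linker_residues` (1-based residue range, empty for
#'   `linker_length = 0`) retrievable via [ground_truth()].
#' @export
make_two_domain_structure <- function(n_per_domain = 30L, linker_length = 4L,
                                      seed = 1L) {
  stopifnot(n_per_domain >= 10L, linker_length >= 0L)
  n <- n_per_domain
  # protein-like packing density: radius ~ (3 n / (4 pi rho))^(1/3), rho ~ 0.008 res/A^3
  radius <- (3 * n / (4 * pi * 0.008))^(1 / 3)
  # rotate points about `center` so that (anchor - center) points along +x:
  # puts the linker attachment on the domain surface facing the linker axis
  face_x <- function(points, center, anchor) {
    u <- anchor - center
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) return(points)
    u <- u / nu
    e1 <- c(1, 0, 0)
    v <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
           u[1] * e1[2] - u[2] * e1[1])
    s <- sqrt(sum(v^2)); cth <- sum(u * e1)
    R <- if (s < 1e-12) {
      if (cth > 0) diag(3) else diag(c(1, -1, -1))
    } else {
      K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                  byrow = TRUE)
      diag(3) + K + K %*% K * ((1 - cth) / s^2)
    }
    sweep(sweep(points, 2, center) %*% t(R), 2, center, "+")
  }
  coords <- local_seed_eval(seed, {
    a <- coil_walk(n, center = c(0, 0, 0), radius = radius)
    a <- face_x(a, colMeans(a), a[n, ])
    pa <- a[n, ]
    step <- 3.6
    link <- if (linker_length > 0) {
      t(vapply(seq_len(linker_length), function(i) {
        pa + c(i * step, 0, 0) + c(0, rnorm(2, 0, 0.25))
      }, numeric(3)))
    } else {
      matrix(numeric(0), 0, 3)
    }
    pb0 <- pa + c((linker_length + 1L) * step, 0, 0)
    cb <- pb0 + c(0.9 * radius, 0, 0)
    b <- coil_walk(n, center = cb, radius = radius, start = pb0)
    b <- face_x(b, pb0, colMeans(b))  # grow domain B away from the linker
    rbind(a, link, b)
  })
  total <- nrow(coords)
  atoms <- tibble(chain = "A", resno = seq_len(total), resid = "GLY",
                  elety = "CA", element = "C",
                  x = coords[, 1], y = coords[, 2], z = coords[, 3])
  s <- protein_structure(atoms)
  linker <- if (linker_length > 0) (n + 1L):(n + linker_length) else integer(0)
  set_truth(s, list(kind = "two_domain_structure", n_per_domain = n,
                    linker_length = linker_length, linker_residues = linker,
                    seed = seed))
}

#' Simulate a mutation cohort under a mutational signature with optional
#' spatial selection
#'
#' Substitutions are drawn channel-first: a trinucleotide channel is sampled
#' from the signature, then a site uniformly among the gene's sites in that
#' channel, so at `enrichment_fold = 1` the empirical context distribution
#' converges to the signature. Positional selection multiplies the weight of
#' sites near `target_residues` by `enrichment_fold` before renormalisation
#' — either within `k` residues in sequence (default) or within `cutoff` Å
#' of the targets' Cα atoms when a structure is supplied.
#'
#' @param gene A [coding_gene()].
#' @param signature A [mutational_signature()].
#' @param n_mutations Number of mutations to draw.
#' @param target_residues Protein positions under selection (default none).
#' @param enrichment_fold Weight multiplier near the targets (>= 1;
#'   default 1 = neutral).
#' @param seed Integer seed.
#' @param classes Consequence classes to draw from (default all
#'   substitution classes; use `"missense"` for selection-test input).
#' @param structure Optional [protein_structure()] switching proximity to
#'   3D distance.
#' @param k Sequence-proximity half-width in residues (default 5).
#' @param cutoff 3D proximity cutoff in Å (default 10).
#' @return Annotated mutation tibble (`gene`, `sample_id`, `tissue`,
#'   `cds_position`, `ref_base`, `alt_base`, `protein_position`, `ref_aa`,
#'   `alt_aa`, `consequence`, `protein_change`, `channel`) with ground truth
#'   attached ([ground_truth()]); write with [write_simple_tsv()].
#' @export
make_mutation_cohort <- function(gene, signature, n_mutations,
                                 target_residues = integer(0),
                                 enrichment_fold = 1, seed = 1L,
                                 classes = c("missense", "synonymous", "nonsense"),
                                 structure = NULL, k = 5L, cutoff = 10.0) {
  stopifnot(enrichment_fold >= 1)
  enum <- enumerate_substitutions(gene) %>%
    filter(.data$consequence %in% classes)
  if (nrow(enum) == 0L) abort("no substitutions in the requested classes")
  p_ch <- as.numeric(signature)[enum$channel]
  n_ch <- table(factor(enum$channel, levels = 1:96))
  w <- p_ch / as.numeric(n_ch[enum$channel])
  if (length(target_residues) > 0 && enrichment_fold > 1) {
    if (!is.null(structure)) {
      d <- distance_to_residue_set(structure, target_residues)
      near_res <- d$resno[d$distance <= cutoff]
    } else {
      near_res <- unique(unlist(lapply(target_residues, function(t) (t - k):(t + k))))
    }
    near <- enum$protein_position %in% near_res
    w[near] <- w[near] * enrichment_fold
  }
  w <- w / sum(w)
  out <- if (n_mutations > 0) {
    idx <- local_seed_eval(seed, sample.int(nrow(enum), n_mutations,
                                            replace = TRUE, prob = w))
    enum[idx, , drop = FALSE] %>%
      mutate(gene = gene$gene, sample_id = sprintf("S%04d", row_number()),
             tissue = "simulated") %>%
      select("gene", "sample_id", "tissue", dplyr::everything())
  } else {
    enum[0, , drop = FALSE] %>%
      mutate(gene = character(0), sample_id = character(0), tissue = character(0))
  }
  set_truth(out, list(kind = "mutation_cohort", signature = signature,
                      target_residues = target_residues,
                      enrichment_fold = enrichment_fold, classes = classes,
                      n_mutations = n_mutations, seed = seed))
}

#' Simulate mutation cohorts for dN/dS estimation
#'
#' Generates `n_genes` random coding genes and, for each, draws
#' `mutations_per_gene` substitutions with nonsynonymous : synonymous rates
#' in proportion `omega * exp_N : exp_S`, where `exp_N` and `exp_S` are the
#' gene's signature-expected proportions. `omega = 1` gives neutral genes;
#' `omega > 1` plants positive selection.
#'
#' @param n_genes Number of genes.
#' @param gene_length Codons per gene.
#' @param signature A [mutational_signature()].
#' @param omega Selection strength (> 0), scalar or vector of length
#'   `n_genes`.
#' @param mutations_per_gene Substitutions drawn per gene.
#' @param seed Integer seed.
#' @return List with `genes` (named list of [coding_gene()]), `mutations`
#'   (tibble over all genes), and ground truth attached to the list.
#' @export
make_dnds_cohort <- function(n_genes, gene_length, signature, omega = 1,
                             mutations_per_gene = 50L, seed = 1L) {
  stopifnot(all(omega > 0))
  omega <- rep_len(omega, n_genes)
  seeds <- local_seed_eval(seed, sample.int(.Machine$integer.max - 1L, n_genes + 1L))
  genes <- purrr::imap(seeds[-1], function(s, i) {
    random_coding_gene(gene_length, seed = s, gene = sprintf("G%04d", i))
  })
  names(genes) <- vapply(genes, `[[`, character(1), "gene")
  muts <- local_seed_eval(seeds[1], {
    purrr::imap(genes, function(g, nm) {
      enum <- enumerate_substitutions(g) %>%
        filter(.data$consequence != "other")
      w <- as.numeric(signature)[enum$channel]
      isN <- enum$consequence %in% c("missense", "nonsense")
      i <- which(names(genes) == nm)
      w <- w * ifelse(isN, omega[i], 1)
      idx <- sample.int(nrow(enum), mutations_per_gene, replace = TRUE,
                        prob = w / sum(w))
      enum[idx, , drop = FALSE] %>%
        mutate(gene = nm, sample_id = sprintf("%s_S%03d", nm, row_number()),
               tissue = "simulated")
    }) %>% bind_rows()
  })
  out <- list(genes = genes, mutations = muts)
  set_truth(out, list(kind = "dnds_cohort", omega = omega,
                      gene_length = gene_length,
                      mutations_per_gene = mutations_per_gene, seed = seed))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Simulate a conformational ensemble with planted per-residue variance
#'
#' Each frame is the base structure plus independent isotropic Gaussian
#' displacement per residue (standard deviation `per_residue_sigma[i]` per
#' axis), then a random global rigid transform so that superposition is
#' exercised. Noise is frame-independent (no autocorrelation).
#'
#' @param structure Base [protein_structure()].
#' @param per_residue_sigma Per-residue displacement sigma in Å (recycled).
#' @param n_frames Number of frames.
#' @param frame_dt Frame spacing in ns.
#' @param seed Integer seed.
#' @return A [conformation_ensemble()] with ground truth (`sigma`)
#'   attached; write with [write_ensemble()].
#' @export
make_ensemble <- function(structure, per_residue_sigma, n_frames = 100L,
                          frame_dt = 0.1, seed = 1L) {
  a <- structure$atoms
  res_key <- paste0(a$chain, ":", a$resno)
  res_levels <- unique(res_key)
  sigma <- rep_len(per_residue_sigma, length(res_levels))
  if (any(sigma < 0)) abort("per-residue sigma must be non-negative")
  sig_atom <- sigma[match(res_key, res_levels)]
  base <- as.matrix(a[, c("x", "y", "z")])
  coords <- local_seed_eval(seed, {
    arr <- array(NA_real_, c(n_frames, nrow(a), 3))
    for (f in seq_len(n_frames)) {
      jit <- base + matrix(rnorm(3 * nrow(a), 0, sig_atom), ncol = 3)
      R <- random_rotation()
      shift <- runif(3, -5, 5)
      arr[f, , ] <- sweep(jit %*% t(R), 2, shift, "+")
    }
    arr
  })
  ens <- conformation_ensemble(coords, a, (seq_len(n_frames) - 1) * frame_dt)
  set_truth(ens, list(kind = "ensemble", sigma = sigma, n_frames = n_frames,
                      frame_dt = frame_dt, seed = seed))
}

#' Simulate a two-arm survival cohort with a specified hazard ratio
#'
#' Event times are exponential; arm B's hazard is `hazard_ratio` times arm
#' A's. Independent exponential censoring is calibrated so the expected
#' censored fraction is `censor_rate` in each arm.
#'
#' @param n_per_arm Patients per arm.
#' @param hazard_ratio Arm B : arm A hazard ratio (> 0).
#' @param censor_rate Expected censored fraction in \[0, 1) (default 0.2).
#' @param seed Integer seed.
#' @param base_hazard Arm A event hazard per month (default log(2)/24:
#'   24-month median survival).
#' @return Survival tibble (`patient_id`, `time`, `event`, `group` with
#'   levels `"A"`/`"B"`) with ground truth attached.
#' @export
make_survival_cohort <- function(n_per_arm, hazard_ratio, censor_rate = 0.2,
                                 seed = 1L, base_hazard = log(2) / 24) {
  stopifnot(hazard_ratio > 0, censor_rate >= 0, censor_rate < 1)
  out <- local_seed_eval(seed, {
    arm <- function(label, rate) {
      ev <- rexp(n_per_arm, rate)
      cs <- if (censor_rate > 0) {
        rexp(n_per_arm, rate * censor_rate / (1 - censor_rate))
      } else {
        rep(Inf, n_per_arm)
      }
      tibble(time = pmin(ev, cs), event = as.integer(ev <= cs), group = label)
    }
    bind_rows(arm("A", base_hazard), arm("B", base_hazard * hazard_ratio)) %>%
      mutate(patient_id = sprintf("P%04d", row_number())) %>%
      select("patient_id", "time", "event", "group")
  })
  set_truth(out, list(kind = "survival_cohort", hazard_ratio = hazard_ratio,
                      censor_rate = censor_rate, n_per_arm = n_per_arm,
                      base_hazard = base_hazard, seed = seed))
}
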