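# Signature-conditioned selection inference: the weighted universe of
# possible missense changes, the Monte-Carlo selection test on an arbitrary
# structural metric, and a Poisson likelihood-ratio dN/dS estimate.

#' Enumerate the signature-weighted universe of missense mutations
#'
#' Every one of the 3L possible single-nucleotide changes of the coding
#' sequence is classified; missense changes are retained and weighted by the
#' mutational-signature probability of their trinucleotide channel,
#' renormalised to sum to one. This is the null model of
#' [monte_carlo_selection_test()]: it describes which amino-acid changes a
#' mutational process would produce in the absence of selection.
#'
#' @param gene A [coding_gene()].
#' @param signature A [mutational_signature()].
#' @return A tibble of class `mutation_universe` with columns `cds_position`,
#'   `ref_base`, `alt_base`, `protein_position`, `ref_aa`, `alt_aa`,
#'   `channel`, `weight` (summing to one).
#' @export
build_universe <- function(gene, signature) {
  stopifnot(inherits(gene, "coding_gene"),
            inherits(signature, "mutational_signature"))
  enum <- enumerate_substitutions(gene)
  uni <- enum %>% filter(.data$consequence == "missense")
  if (nrow(uni) == 0L) abort(sprintf("gene %s admits no missense change", gene$gene))
  w <- as.numeric(signature)[uni$channel]
  if (sum(w) <= 0) abort("signature assigns zero mass to every missense context of this gene")
  uni$weight <- w / sum(w)
  uni <- uni %>% select(-"consequence", -"protein_change")
  class(uni) <- c("mutation_universe", class(uni))
  uni
}

# All 3L single-nucleotide changes of a gene, annotated with consequence and
# context channel. Vectorised; used by the universe, dN/dS and generators.
enumerate_substitutions <- function(gene) {
  L <- nchar(gene$cds)
  ref <- strsplit(gene$cds, "")[[1]]
  pos <- rep(seq_len(L), each = 3L)
  refv <- rep(ref, each = 3L)
  altv <- unlist(lapply(ref, function(b) setdiff(BASES, b)), use.names = FALSE)
  ann <- classify_consequence(gene, pos, refv, altv)
  ann$channel <- as.integer(trinucleotide_context(gene, pos, refv, altv))
  ann
}

normalise_observed <- function(observed) {
  if (is.data.frame(observed)) {
    need <- c("protein_position", "ref_aa", "alt_aa")
    if (!all(need %in% names(observed))) {
      abort("observed mutations need columns protein_position, ref_aa, alt_aa (run annotate_mutations())")
    }
    tibble(protein_position = as.integer(observed$protein_position),
           ref_aa = observed$ref_aa, alt_aa = observed$alt_aa)
  } else {
    abort("observed must be a data frame of annotated mutations")
  }
}

# Resolve a metric (function or table) to a value for each row of `keys`
# (tibble with protein_position, ref_aa, alt_aa). Missing coverage is a hard
# error listing the missing keys.
metric_values <- function(metric, keys, what = "metric") {
  if (is.function(metric)) {
    vals <- metric(keys$protein_position, keys$ref_aa, keys$alt_aa)
  } else if (is.data.frame(metric)) {
    if (!all(c("protein_position", "value") %in% names(metric))) {
      abort("metric table needs columns protein_position, (ref_aa, alt_aa,) value")
    }
    by_aa <- all(c("ref_aa", "alt_aa") %in% names(metric))
    key_cols <- if (by_aa) c("protein_position", "ref_aa", "alt_aa") else "protein_position"
    joined <- dplyr::left_join(keys, distinct(metric, dplyr::across(dplyr::all_of(key_cols)),
                                              .keep_all = TRUE),
                               by = key_cols)
    vals <- joined$value
  } else {
    abort("metric must be a function(position, ref_aa, alt_aa) or a metric table")
  }
  if (anyNA(vals) || any(!is.finite(vals))) {
    miss <- keys[is.na(vals) | !is.finite(vals), , drop = FALSE] %>%
      mutate(key = paste0(.data$ref_aa, .data$protein_position, .data$alt_aa))
    abort(paste0(what, " does not cover ", nrow(miss), " mutation(s): ",
                 paste(head(unique(miss$key), 8), collapse = ", ")))
  }
  as.numeric(vals)
}

#' Monte-Carlo selection test of a structural metric
#'
#' Tests whether the observed missense mutations of a gene sit at unusual
#' values of a per-mutation structural metric (distance to hinge residues,
#' folding ΔΔG, solvent accessibility, ...), relative to the expectation
#' under the cohort's mutational signature and no selection. Sets of
#' `n_observed` mutations are repeatedly drawn from the weighted universe
#' with replacement and the mean metric of each draw forms the permutation
#' distribution; the p-value uses the add-one rule `(b + 1) / (n_perm + 1)`
#' so it is never exactly zero.
#'
#' @param observed Annotated mutation tibble (columns `protein_position`,
#'   `ref_aa`, `alt_aa`); every row must exist in the universe.
#' @param universe A [build_universe()] tibble.
#' @param metric Either `function(position, ref_aa, alt_aa)` returning
#'   numeric values, or a metric table (see [read_metric_table()]). Must
#'   cover every universe entry.
#' @param n_permutations Number of Monte-Carlo permutations (default 1e5).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param tail `"two_sided"` (double the smaller tail, capped at 1),
#'   `"lower"` (observed mean smaller than expected) or `"upper"`.
#' @param statistic Summary of each drawn set: `"mean"` (default) or
#'   `"median"`.
#' @return An object of class `selection_test` with fields `observed_mean`,
#'   `expected_mean`, `effect_size` (observed - expected), `p_value`,
#'   `n_permutations`, `n_observed`, `tail`, `statistic`, `seed`, and the
#'   permutation statistics in `$permutation_stats`. If the metric is
#'   constant over the universe the result has effect 0 and p 1 by
#'   convention.
#' @export
monte_carlo_selection_test <- function(observed, universe, metric,
                                       n_permutations = 100000L, seed = 1L,
                                       tail = c("two_sided", "lower", "upper"),
                                       statistic = c("mean", "median")) {
  tail <- match.arg(tail)
  statistic <- match.arg(statistic)
  stopifnot(inherits(universe, "mutation_universe"))
  obs <- normalise_observed(observed)
  if (nrow(obs) < 1L) abort("need at least one observed mutation")
  # coverage: every observed mutation must be reachable in the universe
  key <- function(d) paste(d$protein_position, d$ref_aa, d$alt_aa)
  missing <- setdiff(key(obs), key(universe))
  if (length(missing)) {
    abort(paste("observed mutation(s) absent from the universe:",
                paste(head(missing, 8), collapse = ", ")))
  }
  m_uni <- metric_values(metric, universe)
  m_obs <- metric_values(metric, obs, what = "metric (observed)")
  stat_fun <- if (statistic == "mean") mean else stats::median
  obs_stat <- stat_fun(m_obs)
  expected_mean <- sum(universe$weight * m_uni)
  n_obs <- nrow(obs)
  if (diff(range(m_uni)) < .Machine$double.eps^0.5) {
    perm <- rep(expected_mean, 0)
    res <- list(p_value = 1, effect_size = 0, observed_mean = obs_stat,
                perm = numeric(0))
  } else {
    perm <- local_seed_eval(seed, {
      idx <- sample.int(nrow(universe), n_permutations * n_obs,
                        replace = TRUE, prob = universe$weight)
      draws <- matrix(m_uni[idx], nrow = n_permutations, ncol = n_obs)
      if (statistic == "mean") rowMeans(draws) else apply(draws, 1, stats::median)
    })
    p_lower <- (sum(perm <= obs_stat) + 1) / (n_permutations + 1)
    p_upper <- (sum(perm >= obs_stat) + 1) / (n_permutations + 1)
    p <- switch(tail,
                lower = p_lower,
                upper = p_upper,
                two_sided = min(1, 2 * min(p_lower, p_upper)))
    res <- list(p_value = p, effect_size = obs_stat - expected_mean,
                observed_mean = obs_stat, perm = perm)
  }
  structure(
    list(observed_mean = res$observed_mean, expected_mean = expected_mean,
         effect_size = res$effect_size, p_value = res$p_value,
         n_permutations = as.integer(n_permutations), n_observed = n_obs,
         tail = tail, statistic = statistic, seed = as.integer(seed),
         permutation_stats = res$perm),
    class = "selection_test"
  )
}

#' @export
print.selection_test <- function(x, ...) {
  cat("<selection_test>\n")
  cat(sprintf("  observed %s %.4g vs expected %.4g (effect %+.4g)\n",
              x$statistic, x$observed_mean, x$expected_mean, x$effect_size))
  cat(sprintf("  Monte-Carlo p = %.4g (%s tail, %d permutations, n = %d)\n",
              x$p_value, x$tail, x$n_permutations, x$n_observed))
  invisible(x)
}

#' Tidy/glance a Monte-Carlo selection test
#'
#' @param x,object A `selection_test`.
#' @param ... Unused.
#' @return One-row tibble of the test summary.
#' @method tidy selection_test
#' @export
tidy.selection_test <- function(x, ...) {
  tibble(observed_mean = x$observed_mean, expected_mean = x$expected_mean,
         effect_size = x$effect_size, p_value = x$p_value,
         n_permutations = x$n_permutations, n_observed = x$n_observed,
         tail = x$tail, statistic = x$statistic, seed = x$seed)
}

#' @rdname tidy.selection_test
#' @method glance selection_test
#' @export
glance.selection_test <- function(x, ...) tidy.selection_test(x)

#' @rdname tidy.selection_test
#' @method autoplot selection_test
#' @export
autoplot.selection_test <- function(object, ...) {
  df <- tibble(stat = object$permutation_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed_mean, colour = "red") +
    ggplot2::geom_vline(xintercept = object$expected_mean, colour = "black",
                        linetype = "dashed") +
    ggplot2::labs(x = paste("permutation", object$statistic),
                  y = "count",
                  title = sprintf("Monte-Carlo selection test: p = %.3g (%s)",
                                  object$p_value, object$tail)) +
    ggplot2::theme_minimal()
}

#' Signature-conditioned dN/dS estimate with likelihood-ratio test
#'
#' Compares the observed nonsynonymous/synonymous split of a gene's
#' substitutions with the split expected under the mutational signature.
#' Expected proportions come from enumerating all coding changes of the gene
#' weighted by signature channel probability. The ratio is
#' `(obs_N / exp_N) / (obs_S / exp_S)` and significance comes from a
#' 1-degree-of-freedom likelihood-ratio test of the Poisson model
#' `obs_N ~ Poisson(mu * exp_N * omega)`, `obs_S ~ Poisson(mu * exp_S)`
#' against `omega = 1`, with `mu` profiled out. Nonsense changes count as
#' nonsynonymous.
#'
#' @param records Mutation tibble for one gene with `cds_position`,
#'   `ref_base`, `alt_base` (consequences are recomputed from the CDS).
#' @param gene A [coding_gene()].
#' @param signature A [mutational_signature()].
#' @return An object of class `dnds_fit` with fields `gene`, `obs_N`,
#'   `obs_S`, `exp_N`, `exp_S` (signature-expected counts scaled to the
#'   observed total), `ratio`, `log2_ratio`, `p_value`, and `fallback`
#'   (`TRUE` when `obs_S = 0` forced the 0.5 pseudo-count fallback).
#' @export
dnds_estimate <- function(records, gene, signature) {
  stopifnot(inherits(gene, "coding_gene"),
            inherits(signature, "mutational_signature"))
  if (nrow(records) < 1L) abort("need at least one observed substitution")
  ann <- classify_consequence(gene, records$cds_position, records$ref_base,
                              records$alt_base)
  obs_N <- sum(ann$consequence %in% c("missense", "nonsense"))
  obs_S <- sum(ann$consequence == "synonymous")
  enum <- enumerate_substitutions(gene)
  w <- as.numeric(signature)[enum$channel]
  eN_raw <- sum(w[enum$consequence %in% c("missense", "nonsense")])
  eS_raw <- sum(w[enum$consequence == "synonymous"])
  if (eN_raw <= 0 || eS_raw <= 0) {
    abort("signature-expected N and S proportions must both be positive")
  }
  total <- obs_N + obs_S
  pN <- eN_raw / (eN_raw + eS_raw)
  exp_N <- total * pN
  exp_S <- total * (1 - pN)
  fallback <- obs_S == 0L
  nN <- obs_N; nS <- obs_S; eN <- exp_N; eS <- exp_S
  if (fallback) {
    warn(sprintf("gene %s: no synonymous mutations observed; applying 0.5 pseudo-count fallback",
                 gene$gene))
    nN <- nN + 0.5; nS <- nS + 0.5; eN <- eN + 0.5; eS <- eS + 0.5
  }
  ratio <- if (nS > 0) (nN / eN) / (nS / eS) else NA_real_
  # profile likelihood-ratio test of omega = 1 (1 df)
  ll <- function(muN, muS) {
    (-muN + ifelse(nN > 0, nN * log(muN), 0)) +
      (-muS + ifelse(nS > 0, nS * log(muS), 0))
  }
  ll_free <- ll(max(nN, .Machine$double.xmin), max(nS, .Machine$double.xmin))
  mu0 <- (nN + nS) / (eN + eS)
  ll_null <- ll(mu0 * eN, mu0 * eS)
  stat <- max(0, 2 * (ll_free - ll_null))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  structure(
    list(gene = gene$gene, obs_N = obs_N, obs_S = obs_S,
         exp_N = exp_N, exp_S = exp_S, ratio = ratio,
         log2_ratio = if (!is.na(ratio) && ratio > 0) log2(ratio) else NA_real_,
         p_value = p, statistic = stat, fallback = fallback),
    class = "dnds_fit"
  )
}

#' @export
print.dnds_fit <- function(x, ...) {
  cat(sprintf("<dnds_fit> %s: dN/dS = %.3f (log2 = %.3f), LRT p = %.3g%s\n",
              x$gene, x$ratio, x$log2_ratio, x$p_value,
              if (x$fallback) " [pseudo-count fallback]" else ""))
  invisible(x)
}

#' Tidy/glance a dN/dS fit
#'
#' @param x,object A `dnds_fit`.
#' @param ... Unused.
#' @return One-row tibble with counts, expected counts, ratio, log2 ratio
#'   and LRT p-value.
#' @method tidy dnds_fit
#' @export
tidy.dnds_fit <- function(x, ...) {
  tibble(gene = x$gene, obs_N = x$obs_N, obs_S = x$obs_S,
         exp_N = x$exp_N, exp_S = x$exp_S, ratio = x$ratio,
         log2_ratio = x$log2_ratio, statistic = x$statistic,
         p_value = x$p_value, fallback = x$fallback)
}

#' @rdname tidy.dnds_fit
#' @method glance dnds_fit
#' @export
glance.dnds_fit <- function(x, ...) tidy.dnds_fit(x)
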