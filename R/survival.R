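# Minimal two-group survival comparison: Kaplan-Meier curves and the
# log-rank test, plus the caller-side "genetically altered" labelling rule.

check_cohort <- function(cohort) {
  need <- c("time", "event", "group")
  if (!all(need %in% names(cohort))) {
    abort("survival cohort needs columns time, event, group")
  }
  if (any(cohort$time < 0)) abort("survival times must be non-negative")
  if (!all(cohort$event %in% c(0, 1))) abort("event must be 0 (censored) or 1 (death)")
  cohort
}

#' Read a survival cohort TSV
#'
#' @param path TSV with columns `patient_id`, `time` (months), `event`
#'   (1 death, 0 censored), `group`.
#' @return Tibble cohort.
#' @export
read_survival_tsv <- function(path) {
  check_cohort(readr::read_tsv(path, col_types = readr::cols(), progress = FALSE))
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate of overall survival per group (via
#' `survival::survfit`); censored-at-event patients count as at risk at that
#' time.
#'
#' @param cohort Tibble with columns `time`, `event` (1 death, 0 censored)
#'   and `group`.
#' @param groups Optional subset of groups to keep.
#' @return Tibble of class `km_fit` with `group`, `time`, `n_at_risk`,
#'   `n_event`, `survival` (non-increasing per group, starting at 1).
#' @export
kaplan_meier <- function(cohort, groups = NULL) {
  cohort <- check_cohort(cohort)
  if (!is.null(groups)) cohort <- filter(cohort, .data$group %in% groups)
  if (nrow(cohort) == 0L) abort("no patients in the requested group(s)")
  fits <- cohort %>%
    group_by(.data$group) %>%
    dplyr::group_modify(function(d, key) {
      sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
      tibble(time = sf$time, n_at_risk = sf$n.risk, n_event = sf$n.event,
             survival = sf$surv)
    }) %>%
    ungroup()
  class(fits) <- c("km_fit", class(fits))
  fits
}

#' @rdname kaplan_meier
#' @param object A `km_fit`.
#' @param ... Unused.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  start <- object %>% distinct(.data$group) %>%
    mutate(time = 0, survival = 1)
  df <- bind_rows(start, select(object, "group", "time", "survival")) %>%
    arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "overall survival") +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom (hypergeometric
#' variance, via `survival::survdiff`).
#'
#' @param cohort Tibble with `time`, `event`, `group`.
#' @param group_a,group_b The two group labels to compare.
#' @return One-row tibble with `statistic` (chi-square), `df`, `p_value`,
#'   `n_a`, `n_b`, `events`.
#' @export
logrank_test <- function(cohort, group_a, group_b) {
  cohort <- check_cohort(cohort) %>%
    filter(.data$group %in% c(group_a, group_b))
  if (!all(c(group_a, group_b) %in% cohort$group)) {
    abort("both groups must be non-empty")
  }
  if (sum(cohort$event) == 0L) abort("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = cohort)
  tibble(statistic = sd$chisq, df = 1L,
         p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         n_a = sum(cohort$group == group_a),
         n_b = sum(cohort$group == group_b),
         events = sum(cohort$event))
}

#' Label patients as genetically altered from a mutation table
#'
#' Implements the common grouping rule for survival stratification: a
#' patient is "altered" if it carries at least one nonsynonymous mutation
#' in the gene of interest (or appears in the optional copy-number altered
#' list), else "WT".
#'
#' @param cohort Survival tibble with a `patient_id` column.
#' @param records Annotated mutation tibble (`sample_id`, `gene`,
#'   `consequence`).
#' @param gene Gene symbol to stratify on.
#' @param cna_samples Optional character vector of copy-number-altered
#'   sample ids.
#' @return The cohort with a `group` column of `"altered"` / `"WT"`.
#' @export
label_altered <- function(cohort, records, gene, cna_samples = character(0)) {
  hit <- records %>%
    filter(.data$gene == !!gene,
           .data$consequence %in% c("missense", "nonsense")) %>%
    pull("sample_id")
  mutate(cohort, group = ifelse(.data$patient_id %in% c(hit, cna_samples),
                                "altered", "WT"))
}
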