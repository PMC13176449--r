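#' Filter phenotype mentions to confirmed current patient diseases
#'
#' Keeps mentions whose context qualifiers mark a confirmed, current,
#' patient-attributed disease: `subject = patient`, `temporality = current`,
#' `certainty = confirmed`. Negated findings ("No vomiting"), prior
#' diagnoses ("Had sleep apnea last year"), hypothetical or suspected
#' conditions ("Rule out gastroparesis") and other-subject mentions are
#' removed. Structured diagnosis codes carry no free-text qualifiers and
#' pass by definition.
#'
#' @param mentions tibble with `source`, `subject`, `temporality`,
#'   `certainty` columns (see `phenotypes.csv` schema).
#' @return Filtered tibble.
#' @export
filter_mentions <- function(mentions) {
  mentions |>
    dplyr::filter(source == "structured" |
                    (subject == "patient" & temporality == "current" &
                       certainty == "confirmed"))
}

#' Pre-treatment patient-level disease prevalence
#'
#' Counts, per concept, the patients with at least one qualifying mention in
#' the pre-treatment window (default 1 year to 30 days before the index
#' date, both boundaries inclusive). A patient counts once per concept no
#' matter how many mentions fall in the window.
#'
#' @param mentions filtered mentions (see [filter_mentions()]).
#' @param cohort_ids character vector: the denominator cohort.
#' @param index_dates tibble `patient_id`, `index_date`.
#' @param window two integers, days before index (default `c(365, 30)`).
#' @return Tibble `concept`, `count`, `n` (denominator = cohort size).
#' @export
pretreatment_prevalence <- function(mentions, cohort_ids, index_dates,
                                    window = c(365, 30)) {
  counts <- mentions |>
    dplyr::filter(patient_id %in% cohort_ids) |>
    dplyr::inner_join(index_dates[c("patient_id", "index_date")],
                      by = "patient_id") |>
    dplyr::filter(date >= index_date - window[1],
                  date <= index_date - window[2]) |>
    dplyr::distinct(patient_id, concept) |>
    dplyr::count(concept, name = "count")
  counts$n <- length(cohort_ids)
  counts
}

#' Rate ratio with chi-square p-value for one disease
#'
#' `RR = (count_a / n_a) / (count_b / n_b)` — the prevalence in cohort a
#' (super responders) over the prevalence in cohort b (the comparator) —
#' with a two-sided p-value from the uncorrected Pearson chi-square test on
#' the affected/unaffected x cohort 2x2 table. A zero comparator count
#' leaves the RR undefined (`NA`, flagged); both counts zero skips the test.
#'
#' @param count_a,n_a affected count and cohort size in arm a.
#' @param count_b,n_b affected count and cohort size in arm b.
#' @return Tibble `rr`, `p_value`, `rr_defined`, `low_expected` (any
#'   expected cell below 5).
#' @export
rate_ratio <- function(count_a, n_a, count_b, n_b) {
  stopifnot(n_a > 0, n_b > 0, count_a <= n_a, count_b <= n_b)
  rr <- if (count_b > 0) (count_a / n_a) / (count_b / n_b) else NA_real_
  if (count_a == 0 && count_b == 0)
    return(tibble::tibble(rr = NA_real_, p_value = NA_real_,
                          rr_defined = FALSE, low_expected = TRUE))
  tab <- matrix(c(count_a, n_a - count_a, count_b, n_b - count_b),
                nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  tibble::tibble(rr = rr, p_value = p, rr_defined = count_b > 0,
                 low_expected = any(expected < 5))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjusted p-values, `min over j >= rank(i) of (m / j) p_(j)`
#' capped at 1, applied across one comparison's disease panel.
#'
#' @param p numeric p-values in `[0, 1]` (`NA`s preserved).
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Phenome-wide pre-treatment prevalence screen
#'
#' Compares pre-treatment disease prevalence between two (typically
#' propensity-matched) cohorts across a disease panel: per concept the
#' patient counts, rate ratio, chi-square p-value and BH-adjusted p-value
#' (family = all concepts of this one comparison by default), plus the
#' strong-effect flag (RR > 2 or RR < 0.5).
#'
#' @param phenotypes raw phenotype mentions.
#' @param cohort_a_ids,cohort_b_ids patient id vectors (a = super
#'   responders, b = comparator).
#' @param index_dates tibble `patient_id`, `index_date`.
#' @param panel optional character vector of concepts to screen; default all
#'   concepts observed in the filtered mentions.
#' @param window pre-treatment window in days before index.
#' @return Tibble of `ScreenResult` rows: `concept`, `count_a`, `n_a`,
#'   `count_b`, `n_b`, `rr`, `p_value`, `fdr_p`, `strong_effect`,
#'   `rr_defined`, `low_expected`.
#' @export
screen_phenotypes <- function(phenotypes, cohort_a_ids, cohort_b_ids,
                              index_dates, panel = NULL,
                              window = c(365, 30)) {
  m <- filter_mentions(phenotypes)
  prev_a <- pretreatment_prevalence(m, cohort_a_ids, index_dates, window)
  prev_b <- pretreatment_prevalence(m, cohort_b_ids, index_dates, window)
  if (is.null(panel))
    panel <- sort(union(prev_a$concept, prev_b$concept))
  res <- tibble::tibble(concept = panel) |>
    dplyr::left_join(prev_a, by = "concept") |>
    dplyr::left_join(prev_b, by = "concept",
                     suffix = c("_a", "_b")) |>
    dplyr::mutate(count_a = dplyr::coalesce(count_a, 0L),
                  count_b = dplyr::coalesce(count_b, 0L),
                  n_a = length(cohort_a_ids), n_b = length(cohort_b_ids))
  stats_rows <- purrr::pmap_dfr(
    res[c("count_a", "n_a", "count_b", "n_b")],
    function(count_a, n_a, count_b, n_b)
      rate_ratio(count_a, n_a, count_b, n_b))
  res <- dplyr::bind_cols(res[c("concept", "count_a", "n_a", "count_b", "n_b")],
                          stats_rows)
  res$fdr_p <- bh_adjust(res$p_value)
  res$strong_effect <- !is.na(res$rr) & (res$rr > 2 | res$rr < 0.5)
  res
}

#' Select diseases for the cross-drug heatmap
#'
#' Candidate diseases are those reaching both statistical significance
#' (FDR-adjusted p < `alpha`) and a strong effect size (RR > 2.0 or
#' RR < 0.5) in at least one drug's comparison. Per drug, up to `cap`
#' candidates with the highest RRs and up to `cap` with the lowest RRs are
#' kept (ties broken by smaller FDR p, then lexicographic concept); the
#' union across drugs forms the heatmap rows.
#'
#' @param results_by_drug named list of screen tibbles from
#'   [screen_phenotypes()], one per drug.
#' @param alpha FDR significance threshold (default 0.05).
#' @param rr_high,rr_low strong-effect bounds (default 2.0 and 0.5).
#' @param cap maximum diseases per side per drug (default 5).
#' @return List with `selected` (character vector of concepts, heatmap
#'   rows), `per_drug` (tibble `drug`, `concept`, `side`), and `matrix`
#'   (concepts x drugs RR tibble).
#' @export
select_heatmap_features <- function(results_by_drug, alpha = 0.05,
                                    rr_high = 2.0, rr_low = 0.5, cap = 5L) {
  qualifies <- function(df)
    !is.na(df$fdr_p) & df$fdr_p < alpha & !is.na(df$rr) &
      (df$rr > rr_high | df$rr < rr_low)
  candidates <- unique(unlist(lapply(results_by_drug, function(df)
    df$concept[qualifies(df)])))
  if (!length(candidates)) {
    warning("no disease meets the significance and effect-size thresholds")
    return(list(selected = character(0),
                per_drug = tibble::tibble(drug = character(0),
                                          concept = character(0),
                                          side = character(0)),
                matrix = tibble::tibble()))
  }
  per_drug <- purrr::imap_dfr(results_by_drug, function(df, drug) {
    cand <- df[df$concept %in% candidates & !is.na(df$rr), ]
    hi <- cand[order(-cand$rr, cand$fdr_p, cand$concept), ]
    hi <- utils::head(hi[hi$rr > 1, ], cap)
    lo <- cand[order(cand$rr, cand$fdr_p, cand$concept), ]
    lo <- utils::head(lo[lo$rr < 1, ], cap)
    dplyr::bind_rows(
      tibble::tibble(drug = drug, concept = hi$concept, side = "high"),
      tibble::tibble(drug = drug, concept = lo$concept, side = "low"))
  })
  selected <- sort(unique(per_drug$concept))
  rr_mat <- purrr::imap_dfr(results_by_drug, function(df, drug) {
    tibble::tibble(drug = drug, concept = df$concept, rr = df$rr)
  }) |>
    dplyr::filter(concept %in% selected) |>
    tidyr::pivot_wider(names_from = drug, values_from = rr)
  list(selected = selected, per_drug = per_drug, matrix = rr_mat)
}
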