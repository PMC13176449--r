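#' Normalize weight measurements to kilograms with a plausibility gate
#'
#' Converts pound-denominated rows to kilograms (x 0.45359237) when a `units`
#' column says `lb`, then drops implausible values outside (20, 400) kg. The
#' number of dropped rows is recorded in the `n_dropped` attribute and
#' reported as a message.
#'
#' @param weights tibble with `patient_id`, `date`, `weight` and optionally
#'   `units` (`"kg"` or `"lb"`).
#' @return The normalized tibble with column `weight_kg`.
#' @export
normalize_weights <- function(weights) {
  w <- weights
  if ("units" %in% names(w)) {
    lb <- !is.na(w$units) & tolower(w$units) %in% c("lb", "lbs", "pound", "pounds")
    w$weight_kg <- ifelse(lb, w$weight * 0.45359237, w$weight)
  } else {
    w$weight_kg <- w$weight
  }
  keep <- w$weight_kg > 20 & w$weight_kg < 400 & !is.na(w$weight_kg)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " weight measurement(s) outside (20, 400) kg dropped")
  out <- w[keep, c("patient_id", "date", "weight_kg")]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Treatment-exposure filter
#'
#' Keeps patients with at least `min_orders` GLP-1RA orders whose first and
#' last orders span at least `min_span_days` calendar days ("at least 1
#' month" operationalised as 30 days).
#'
#' @param prescriptions tibble with `patient_id` and `date`.
#' @param min_orders minimum number of orders (default 3).
#' @param min_span_days minimum first-to-last span in days (default 30).
#' @return Character vector of eligible patient ids.
#' @export
apply_exposure_filter <- function(prescriptions, min_orders = 3L,
                                  min_span_days = 30) {
  stopifnot(nrow(prescriptions) > 0)
  prescriptions |>
    dplyr::summarise(n_orders = dplyr::n(),
                     span = as.numeric(max(date) - min(date)),
                     .by = patient_id) |>
    dplyr::filter(n_orders >= min_orders, span >= min_span_days) |>
    dplyr::pull(patient_id)
}

#' Exclude patients with a pre-index history of bariatric surgery
#'
#' Uses the boolean `bariatric_history` flag when present, or a table of
#' bariatric procedure events dated before each patient's index date.
#' Post-index surgery does not constitute "history" and is ignored.
#'
#' @param patients tibble with `patient_id` and either `bariatric_history`.
#' @param procedure_events optional tibble `patient_id`, `date` of bariatric
#'   procedures; used with `index_dates` when the flag column is absent.
#' @param index_dates optional tibble `patient_id`, `index_date`.
#' @return Character vector of retained patient ids.
#' @export
exclude_bariatric <- function(patients, procedure_events = NULL,
                              index_dates = NULL) {
  if ("bariatric_history" %in% names(patients) && is.null(procedure_events))
    return(patients$patient_id[!patients$bariatric_history])
  stopifnot(!is.null(procedure_events), !is.null(index_dates))
  flagged <- procedure_events |>
    dplyr::inner_join(index_dates, by = "patient_id") |>
    dplyr::filter(date < index_date) |>
    dplyr::distinct(patient_id) |>
    dplyr::pull(patient_id)
  setdiff(patients$patient_id, flagged)
}

#' Brand- and drug-exclusive strata
#'
#' Labels each patient with a brand iff every one of their GLP-1RA orders
#' carries that brand (Bydureon and Bydureon BCise are merged as
#' pharmacologically equivalent); switchers get `NA` and are excluded from
#' brand-stratified analyses. The same rule at the ingredient level yields
#' the drug-exclusive stratum.
#'
#' @param prescriptions tibble with `patient_id`, `brand`, `ingredient`.
#' @return Tibble `patient_id`, `brand_exclusive`, `drug_exclusive` (`NA`
#'   where the patient switched).
#' @export
brand_exclusive_strata <- function(prescriptions) {
  prescriptions |>
    dplyr::mutate(brand = dplyr::if_else(brand == "Bydureon BCise",
                                         "Bydureon", brand)) |>
    dplyr::summarise(
      brand_exclusive = if (dplyr::n_distinct(brand) == 1L)
        brand[1L] else NA_character_,
      drug_exclusive = if (dplyr::n_distinct(ingredient) == 1L)
        ingredient[1L] else NA_character_,
      .by = patient_id)
}

#' Baseline clinical flags from diagnosis events
#'
#' T2DM status requires three or more diabetes-concept events in the 5 years
#' before the index date; pregnancy status requires one or more
#' pregnancy-concept events in the preceding year. Both windows are
#' `[index - k years, index)`, excluding the index day itself.
#'
#' @param phenotypes tibble with `patient_id`, `date`, `concept`.
#' @param index_dates tibble with `patient_id`, `index_date`.
#' @param diabetes_concepts,pregnancy_concepts character vectors of concept
#'   names counted toward each flag.
#' @return Tibble `patient_id`, `t2dm`, `pregnant_prior_year`.
#' @export
baseline_flags <- function(phenotypes, index_dates,
                           diabetes_concepts = "type 2 diabetes mellitus",
                           pregnancy_concepts = "pregnancy") {
  ev <- phenotypes |>
    dplyr::inner_join(index_dates[c("patient_id", "index_date")],
                      by = "patient_id")
  t2dm <- ev |>
    dplyr::filter(concept %in% diabetes_concepts,
                  date >= index_date - round(5 * 365.25), date < index_date) |>
    dplyr::summarise(n = dplyr::n(), .by = patient_id) |>
    dplyr::filter(n >= 3L)
  preg <- ev |>
    dplyr::filter(concept %in% pregnancy_concepts,
                  date >= index_date - 365, date < index_date) |>
    dplyr::distinct(patient_id)
  index_dates |>
    dplyr::transmute(patient_id,
                     t2dm = patient_id %in% t2dm$patient_id,
                     pregnant_prior_year = patient_id %in% preg$patient_id)
}

#' Derive index dates, baseline weights and the eligibility funnel
#'
#' Applies the full eligibility funnel: exposure (>= 3 orders spanning >= 30
#' days), no pre-index bariatric history, an available baseline weight
#' (measurement closest to the index date within the closed 90-day pre-index
#' window, same-day duplicates averaged), and at least one weight strictly
#' inside the first post-treatment year `(index, index + 365]`. The index
#' date is the date of the first GLP-1RA prescription.
#'
#' @param patients,prescriptions,weights the input tables; `weights` should
#'   already be normalized (see [normalize_weights()]), otherwise they are
#'   normalized here.
#' @param baseline_window_days width of the pre-index baseline window
#'   (default 90, closed on both ends).
#' @return List with `cohort` (one row per retained patient: `patient_id`,
#'   `index_date`, `baseline_weight_kg`, `baseline_weight_date`,
#'   `age_at_index`, `gender`, `race`) and `funnel` (tibble `stage`, `n`).
#' @export
derive_index <- function(patients, prescriptions, weights,
                         baseline_window_days = 90) {
  if (!"weight_kg" %in% names(weights)) weights <- normalize_weights(weights)
  funnel <- tibble::tibble(stage = "all_patients",
                           n = dplyr::n_distinct(patients$patient_id))

  exposed <- apply_exposure_filter(prescriptions)
  funnel <- dplyr::add_row(funnel, stage = "exposure_3plus_orders_30d_span",
                           n = length(exposed))

  no_bari <- intersect(exposed, exclude_bariatric(patients))
  funnel <- dplyr::add_row(funnel, stage = "no_bariatric_history",
                           n = length(no_bari))

  idx <- prescriptions |>
    dplyr::filter(patient_id %in% no_bari) |>
    dplyr::summarise(index_date = min(date), .by = patient_id)

  # baseline: same-day duplicates averaged, then closest to index wins
  bl <- weights |>
    dplyr::inner_join(idx, by = "patient_id") |>
    dplyr::filter(date >= index_date - baseline_window_days,
                  date <= index_date) |>
    dplyr::summarise(weight_kg = mean(weight_kg),
                     .by = c(patient_id, date, index_date)) |>
    dplyr::mutate(dist = as.numeric(index_date - date)) |>
    dplyr::slice_min(dist, n = 1, by = patient_id, with_ties = FALSE) |>
    dplyr::select(patient_id, index_date,
                  baseline_weight_kg = weight_kg,
                  baseline_weight_date = date)
  funnel <- dplyr::add_row(funnel, stage = "baseline_weight_within_90d",
                           n = nrow(bl))

  post <- weights |>
    dplyr::inner_join(bl[c("patient_id", "index_date")], by = "patient_id") |>
    dplyr::filter(date > index_date, date <= index_date + 365) |>
    dplyr::distinct(patient_id)
  cohort <- bl |>
    dplyr::filter(patient_id %in% post$patient_id) |>
    dplyr::left_join(patients[c("patient_id", "birth_date", "gender", "race")],
                     by = "patient_id") |>
    dplyr::mutate(age_at_index = whole_years(birth_date, index_date)) |>
    dplyr::select(-birth_date)
  funnel <- dplyr::add_row(funnel, stage = "post_treatment_weight",
                           n = nrow(cohort))
  stopifnot(all(diff(funnel$n) <= 0))
  list(cohort = cohort, funnel = funnel)
}

# whole calendar years elapsed between two dates
whole_years <- function(from, to) {
  from <- lubridate::as_date(from); to <- lubridate::as_date(to)
  as.integer(lubridate::interval(from, to) %/% lubridate::years(1))
}

#' Build the analytic cohort with strata and baseline flags
#'
#' Convenience wrapper chaining [derive_index()], [brand_exclusive_strata()]
#' and [baseline_flags()] into one indexed-patient table.
#'
#' @param tables an `ehr_tables` list.
#' @return List with `cohort` (indexed patients joined with brand/drug
#'   exclusivity and T2DM / pregnancy flags) and `funnel`.
#' @export
build_cohort <- function(tables) {
  di <- derive_index(tables$patients, tables$prescriptions, tables$weights)
  strata <- brand_exclusive_strata(tables$prescriptions)
  flags <- baseline_flags(tables$phenotypes, di$cohort)
  cohort <- di$cohort |>
    dplyr::left_join(strata, by = "patient_id") |>
    dplyr::left_join(flags, by = "patient_id")
  list(cohort = cohort, funnel = di$funnel)
}
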