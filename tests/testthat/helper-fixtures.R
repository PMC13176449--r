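# Small in-code fixtures shared across test files.

# a compact generator configuration for fast end-to-end tests
small_config <- function(n = 600, seed = 101, pre_years = 20, ...) {
  generator_config(n_patients = n, seed = seed, pre_years = pre_years, ...)
}

# single-brand configuration with a given class mix
one_brand_config <- function(n, mix, brand = "Zepbound", seed = 1, ...) {
  generator_config(
    n_patients = n, seed = seed,
    brand_mix = stats::setNames(1, brand),
    class_proportions_by_brand = stats::setNames(list(mix), brand),
    ...)
}

# hand-built weight series for one or more patients
make_series <- function(patient_id, t_days, pct_change) {
  tibble::tibble(patient_id = patient_id, t_days = t_days,
                 pct_change = pct_change,
                 weight_kg = 100 * (1 + pct_change / 100))
}

# minimal indexed cohort for joining
make_cohort <- function(ids, index = as.Date("2023-06-01"), baseline = 100) {
  tibble::tibble(patient_id = ids, index_date = index,
                 baseline_weight_kg = baseline)
}

# phenotype mention row(s) with qualifier defaults
make_mentions <- function(patient_id, date, concept,
                          source = "structured", subject = "patient",
                          temporality = "current", certainty = "confirmed") {
  tibble::tibble(patient_id = patient_id, date = as.Date(date),
                 concept = concept, source = source, subject = subject,
                 temporality = temporality, certainty = certainty)
}

# simulated two-arm mention table with one planted effect, for screen tests
simulate_screen_inputs <- function(n_per_arm, m_concepts, planted_rr = 1,
                                   planted_prev = 0.05, seed = 1) {
  set.seed(seed)
  idx <- tibble::tibble(
    patient_id = sprintf("S%05d", seq_len(2 * n_per_arm)),
    index_date = as.Date("2023-01-01"))
  a_ids <- idx$patient_id[seq_len(n_per_arm)]
  b_ids <- idx$patient_id[n_per_arm + seq_len(n_per_arm)]
  p0 <- stats::runif(m_concepts, 0.01, 0.12)
  p0[1] <- planted_prev
  rr <- rep(1, m_concepts); rr[1] <- planted_rr
  rows <- lapply(seq_len(m_concepts), function(k) {
    has_a <- a_ids[stats::runif(n_per_arm) < min(1, p0[k] * rr[k])]
    has_b <- b_ids[stats::runif(n_per_arm) < p0[k]]
    ids <- c(has_a, has_b)
    if (!length(ids)) return(NULL)
    make_mentions(ids,
                  as.Date("2023-01-01") -
                    sample(30:365, length(ids), replace = TRUE),
                  sprintf("concept%03d", k))
  })
  list(mentions = dplyr::bind_rows(rows), index = idx,
       a_ids = a_ids, b_ids = b_ids,
       panel = sprintf("concept%03d", seq_len(m_concepts)))
}
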