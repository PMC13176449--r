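#' Brand / ingredient lookup for GLP-1 receptor agonists
#'
#' Fixed mapping from branded formulation to active ingredient. Bydureon and
#' Bydureon BCise are pharmacologically equivalent and are merged into a
#' single "Bydureon" stratum by [brand_exclusive_strata()].
#'
#' @format A tibble with columns `brand` and `ingredient`.
#' @export
glp1_brands <- tibble::tribble(
  ~brand,            ~ingredient,
  "Ozempic",         "semaglutide",
  "Wegovy",          "semaglutide",
  "Rybelsus",        "semaglutide",
  "Mounjaro",        "tirzepatide",
  "Zepbound",        "tirzepatide",
  "Victoza",         "liraglutide",
  "Saxenda",         "liraglutide",
  "Trulicity",       "dulaglutide",
  "Byetta",          "exenatide",
  "Bydureon",        "exenatide",
  "Bydureon BCise",  "exenatide"
)

response_classes <- c("super", "moderate", "minimal", "regainer")

#' The four weight-loss response categories
#'
#' Category levels, in display order: super responders (maximum first-year
#' loss >= 15% of baseline), moderate responders (5-15%), minimal
#' weight-loss (< 5%), and weight regainers (>= 5% loss followed by a
#' >= 5-point regain).
#'
#' @return Character vector of length 4.
#' @export
response_levels <- function() response_classes

#' Default disease panel with planted class-conditional enrichments
#'
#' A small panel of pre-treatment disease concepts with base prevalences and
#' per-class log rate ratios. Planted effects mirror the scale of real-world
#' super-responder enrichments (for example psoriasis enriched about 2.5-fold
#' and fibromyalgia depleted about 5-fold among super responders relative to
#' the minimal weight-loss group); the remaining concepts carry no planted
#' signal and act as the null background for FDR calibration.
#'
#' @param n_null number of additional null (no planted effect) concepts.
#' @return A tibble with columns `concept`, `base_prevalence`, and
#'   `log_rr_super`, `log_rr_moderate`, `log_rr_minimal`, `log_rr_regainer`.
#' @export
default_disease_panel <- function(n_null = 24) {
  planted <- tibble::tribble(
    ~concept,           ~base_prevalence, ~log_rr_super,
    "psoriasis",                   0.030,      log(2.5),
    "melanoma",                    0.010,      log(4.4),
    "muscle stiffness",            0.040,      log(2.4),
    "fibromyalgia",                0.050,      log(0.2),
    "osteoarthritis",              0.120,      log(0.5),
    "obstructive sleep apnea",     0.150,      log(0.4),
    "chronic obstructive pulmonary disease", 0.040, log(0.2),
    "polycystic ovarian syndrome", 0.050,      log(0.2)
  )
  nulls <- tibble::tibble(
    concept = sprintf("background condition %02d", seq_len(n_null)),
    base_prevalence = stats::runif(n_null, 0.01, 0.12),
    log_rr_super = 0
  )
  out <- dplyr::bind_rows(planted, nulls)
  out$log_rr_moderate <- 0
  out$log_rr_minimal <- 0
  out$log_rr_regainer <- 0
  out
}

#' Configuration for the synthetic EHR cohort generator
#'
#' Defaults encode the study conditions the generator emulates: brand mix and
#' per-brand response-class proportions matching the brand-exclusive cohorts
#' of a large real-world GLP-1RA population (super-response rates of 34% for
#' Zepbound, 26% for Wegovy, 24% for Mounjaro and 10% for Ozempic, with
#' moderate response at 40-42% throughout); a saturating-exponential
#' post-treatment loss reaching about 18% of baseline at one year for super
#' responders and about 10% for moderate responders; multi-decade pre-treatment
#' weight drift (about 0.9%/year for the super class, so the one-year
#' post-treatment weight matches the weight ~20 years before therapy);
#' class-conditional demographics (super responders younger, mean age 51 vs
#' 55, and more often female, 80% vs 58-65%); and about 2% pregnancy and
#' sizeable T2DM prevalence in the year(s) before the index date.
#'
#' @param n_patients number of patients to simulate.
#' @param brand_mix named probability vector over brands.
#' @param class_proportions_by_brand named list; per brand a named probability
#'   vector over `super, moderate, minimal, regainer`.
#' @param baseline_weight_mean_kg,baseline_weight_sd_kg baseline weight
#'   distribution (kg), truncated to (50, 250).
#' @param pre_drift_pct_per_year_by_class named vector; percent of baseline
#'   weight gained per year over the pre-treatment decades.
#' @param post_curve_params_by_class named list; per class `A` (amplitude,
#'   percent of baseline), `tau` (time constant, days), and for the regainer
#'   class `t_nadir` (days) and `regain_slope` (percent points/day).
#' @param measurement_noise_sd_kg i.i.d. Gaussian noise added to every weight
#'   measurement (kg).
#' @param visits_per_month_rate post-treatment visit rate (Poisson).
#' @param weight_visit_fraction fraction of post-treatment visits at which a
#'   weight is recorded.
#' @param pre_weights_per_year expected historical weight measurements per
#'   year before the index date.
#' @param pre_years length of the simulated pre-treatment history (years).
#' @param baseline_weight_prob probability that a patient has a weight
#'   recorded within the 30 days before the first prescription (treatment
#'   initiation usually triggers a recent weigh-in; the remainder exercise
#'   the baseline-availability funnel stage).
#' @param compliant_fraction fraction of patients given >= 3 orders spanning
#'   >= 30 days; the rest receive too few or too closely spaced orders and
#'   are removed by the exposure filter.
#' @param demographics_by_class named list; per class `age_mean`, `age_sd`,
#'   `female_frac`, and `race_probs` (named over
#'   `white, black, hispanic, other_unknown`).
#' @param t2dm_prevalence,pregnancy_prevalence prevalence of type 2 diabetes
#'   (>= 3 coded events over the 5 pre-index years) and of pregnancy-related
#'   diagnoses in the pre-index year.
#' @param bariatric_fraction fraction with a history of bariatric surgery.
#' @param disease_panel tibble as produced by [default_disease_panel()].
#' @param qualifier_noise named fractions (`negated`, `past`, `other`,
#'   `suspected`) of spurious text-derived mentions emitted with
#'   disqualifying context qualifiers.
#' @param seed integer seed; a fixed seed makes [generate_population()]
#'   byte-identical across runs.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_patients = 5000,
    brand_mix = c(Ozempic = 0.5387, Wegovy = 0.1343,
                  Mounjaro = 0.2358, Zepbound = 0.0912),
    class_proportions_by_brand = list(
      Ozempic  = c(super = 0.100, moderate = 0.420, minimal = 0.435, regainer = 0.045),
      Wegovy   = c(super = 0.260, moderate = 0.400, minimal = 0.303, regainer = 0.037),
      Mounjaro = c(super = 0.240, moderate = 0.420, minimal = 0.284, regainer = 0.056),
      Zepbound = c(super = 0.340, moderate = 0.410, minimal = 0.230, regainer = 0.020)
    ),
    baseline_weight_mean_kg = 100,
    baseline_weight_sd_kg = 18,
    pre_drift_pct_per_year_by_class = c(super = 0.9, moderate = 1.0,
                                        minimal = 0.05, regainer = 0.8),
    post_curve_params_by_class = list(
      super    = list(A = 19.0, tau = 120),
      moderate = list(A = 10.3, tau = 90),
      minimal  = list(A = 1.2,  tau = 100),
      regainer = list(A = 10.0, tau = 60, t_nadir = 150, regain_slope = 0.045)
    ),
    measurement_noise_sd_kg = 0.8,
    visits_per_month_rate = 3,
    weight_visit_fraction = 0.35,
    pre_weights_per_year = 2,
    pre_years = 20,
    baseline_weight_prob = 0.93,
    compliant_fraction = 0.90,
    demographics_by_class = list(
      super    = list(age_mean = 51, age_sd = 12, female_frac = 0.80,
                      race_probs = c(white = 0.900, black = 0.022,
                                     hispanic = 0.011, other_unknown = 0.067)),
      moderate = list(age_mean = 55, age_sd = 12, female_frac = 0.65,
                      race_probs = c(white = 0.840, black = 0.060,
                                     hispanic = 0.035, other_unknown = 0.065)),
      minimal  = list(age_mean = 55, age_sd = 12, female_frac = 0.58,
                      race_probs = c(white = 0.800, black = 0.091,
                                     hispanic = 0.051, other_unknown = 0.058)),
      regainer = list(age_mean = 55, age_sd = 12, female_frac = 0.62,
                      race_probs = c(white = 0.820, black = 0.075,
                                     hispanic = 0.045, other_unknown = 0.060))
    ),
    t2dm_prevalence = 0.35,
    pregnancy_prevalence = 0.02,
    bariatric_fraction = 0.02,
    disease_panel = NULL,
    qualifier_noise = c(negated = 0.05, past = 0.03,
                        other = 0.01, suspected = 0.03),
    seed = 20260101L) {
  if (is.null(disease_panel)) {
    # panel drawn from its own fixed stream so config defaults are stable
    old <- .Random.seed_exists()
    set.seed(777L)
    disease_panel <- default_disease_panel()
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    brand_mix = brand_mix,
    class_proportions_by_brand = class_proportions_by_brand,
    baseline_weight_mean_kg = baseline_weight_mean_kg,
    baseline_weight_sd_kg = baseline_weight_sd_kg,
    pre_drift_pct_per_year_by_class = pre_drift_pct_per_year_by_class,
    post_curve_params_by_class = post_curve_params_by_class,
    measurement_noise_sd_kg = measurement_noise_sd_kg,
    visits_per_month_rate = visits_per_month_rate,
    weight_visit_fraction = weight_visit_fraction,
    pre_weights_per_year = pre_weights_per_year,
    pre_years = pre_years,
    baseline_weight_prob = baseline_weight_prob,
    compliant_fraction = compliant_fraction,
    demographics_by_class = demographics_by_class,
    t2dm_prevalence = t2dm_prevalence,
    pregnancy_prevalence = pregnancy_prevalence,
    bariatric_fraction = bariatric_fraction,
    disease_panel = disease_panel,
    qualifier_noise = qualifier_noise,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_patients <= 0L)
    stop("n_patients must be a positive integer (empty tables are not generated)",
         call. = FALSE)
  check_simplex <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(sprintf("%s must be a probability vector summing to 1 (got sum %.12f)",
                   what, sum(p)), call. = FALSE)
  }
  check_simplex(cfg$brand_mix, "brand_mix")
  for (b in names(cfg$class_proportions_by_brand)) {
    p <- cfg$class_proportions_by_brand[[b]]
    if (!setequal(names(p), response_classes))
      stop("class proportions must be named over the four response classes",
           call. = FALSE)
    check_simplex(p, paste0("class_proportions_by_brand$", b))
  }
  for (cl in response_classes) {
    pr <- cfg$post_curve_params_by_class[[cl]]
    if (is.null(pr) || pr$tau <= 0)
      stop("post-curve tau must be > 0 for every class", call. = FALSE)
    check_simplex(cfg$demographics_by_class[[cl]]$race_probs,
                  paste0("race_probs for class ", cl))
  }
  with(cfg, stopifnot(
    baseline_weight_mean_kg > 0, baseline_weight_sd_kg > 0,
    measurement_noise_sd_kg > 0, visits_per_month_rate > 0,
    all(disease_panel$base_prevalence >= 0),
    all(disease_panel$base_prevalence <= 1),
    all(qualifier_noise >= 0), all(qualifier_noise <= 1)
  ))
  invisible(cfg)
}

#' Noise-free latent weight curve
#'
#' The ground-truth weight of a simulated patient as a function of time from
#' the index date. Before the index date weight drifts linearly downward into
#' the past at a class-specific rate (so the population gains weight over the
#' decades approaching therapy). After the index date the loss classes follow
#' a saturating exponential, `baseline * (1 - A/100 * (1 - exp(-t/tau)))`;
#' the regainer class follows the same form until its nadir time and then
#' rebounds linearly. The curve is continuous at `t = 0` and at the nadir.
#'
#' @param class one of `super`, `moderate`, `minimal`, `regainer` (scalar).
#' @param baseline_kg baseline weight at the index date (kg); scalar or a
#'   vector parallel to `t`.
#' @param t days from index; vectorised; must lie in `[-7300, 365]`.
#' @param params list with `A`, `tau` and, for regainers, `t_nadir` and
#'   `regain_slope`.
#' @param drift_pct_per_year pre-treatment drift, percent of baseline/year.
#' @return Numeric vector of weights (kg).
#' @export
true_weight_curve <- function(class, baseline_kg, t, params,
                              drift_pct_per_year = 0) {
  class <- match.arg(class, response_classes)
  if (any(t < -7300 | t > 365))
    stop("t must lie within [-7300, 365] days from index", call. = FALSE)
  b <- rep_len(baseline_kg, length(t))
  w <- numeric(length(t))
  pre <- t < 0
  w[pre] <- b[pre] * (1 - drift_pct_per_year / 100 * abs(t[pre]) / 365)
  post <- !pre
  tp <- t[post]
  bp <- b[post]
  loss <- bp * (1 - params$A / 100 * (1 - exp(-tp / params$tau)))
  if (class == "regainer") {
    tn <- params$t_nadir
    nadir_w <- bp * (1 - params$A / 100 * (1 - exp(-tn / params$tau)))
    reb <- tp > tn
    loss[reb] <- nadir_w[reb] +
      bp[reb] * params$regain_slope / 100 * (tp[reb] - tn)
  }
  w[post] <- loss
  w
}

#' Generate a synthetic longitudinal EHR cohort
#'
#' Simulates the four input tables of the pipeline (patients, prescriptions,
#' weight measurements, phenotype mentions) plus a ground-truth sidecar that
#' no pipeline stage reads. Latent response classes are drawn per brand from
#' the configured mixes; weights are sampled at irregular visit times from
#' [true_weight_curve()] plus i.i.d. measurement noise; prescriptions for the
#' compliant fraction satisfy the exposure filter (>= 3 orders spanning >= 30
#' days) while the rest do not; disease mentions are drawn per concept with
#' class-conditional prevalence `p * exp(log_rr)` capped at 1, with extra
#' negated/past/other-subject/suspected mentions at the configured qualifier
#' noise rates.
#'
#' @param config a [generator_config()].
#' @return A list of class `ehr_tables` with elements `patients`,
#'   `prescriptions`, `weights`, `phenotypes` (the pipeline inputs) and
#'   `truth` (latent per-patient state, held separately).
#' @export
generate_population <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  cls_levels <- response_classes

  patient_id <- sprintf("P%06d", seq_len(n))
  brand <- sample(names(config$brand_mix), n, replace = TRUE,
                  prob = config$brand_mix)
  class <- character(n)
  for (b in unique(brand)) {
    i <- which(brand == b)
    class[i] <- sample(cls_levels, length(i), replace = TRUE,
                       prob = config$class_proportions_by_brand[[b]][cls_levels])
  }

  baseline_kg <- pmin(pmax(stats::rnorm(n, config$baseline_weight_mean_kg,
                                        config$baseline_weight_sd_kg), 50), 250)
  index_date <- as.Date("2022-01-01") + sample.int(730L, n, replace = TRUE)

  # demographics conditioned on latent class
  age <- numeric(n); gender <- character(n); race <- character(n)
  for (cl in cls_levels) {
    i <- which(class == cl)
    if (!length(i)) next
    d <- config$demographics_by_class[[cl]]
    age[i] <- pmin(pmax(stats::rnorm(length(i), d$age_mean, d$age_sd), 18), 95)
    gender[i] <- ifelse(stats::runif(length(i)) < d$female_frac,
                        "female", "male")
    race[i] <- sample(names(d$race_probs), length(i), replace = TRUE,
                      prob = d$race_probs)
  }
  birth_date <- index_date - round(age * 365.25)
  patients <- tibble::tibble(
    patient_id, birth_date,
    gender = gender, race = race,
    bariatric_history = stats::runif(n) < config$bariatric_fraction,
    height_cm = round(ifelse(gender == "female",
                             stats::rnorm(n, 163, 7), stats::rnorm(n, 177, 8)))
  )

  compliant <- stats::runif(n) < config$compliant_fraction
  prescriptions <- .gen_prescriptions(patient_id, brand, index_date, compliant)
  weights <- .gen_weights(config, patient_id, class, baseline_kg, index_date)
  phen <- .gen_phenotypes(config, patient_id, class, index_date)

  truth <- tibble::tibble(
    patient_id, class = class, brand = brand,
    baseline_weight_kg = baseline_kg, index_date = index_date,
    compliant = compliant, age_at_index = floor(age)
  )
  structure(list(patients = patients, prescriptions = prescriptions,
                 weights = weights, phenotypes = phen$mentions, truth = truth,
                 truth_diseases = phen$truth_diseases),
            class = "ehr_tables")
}

.gen_prescriptions <- function(patient_id, brand, index_date, compliant) {
  n <- length(patient_id)
  n_orders <- integer(n)
  n_orders[compliant] <- 3L + stats::rpois(sum(compliant), 6)
  # non-compliant: either too few orders or a sub-30-day span
  nc <- which(!compliant)
  few <- stats::runif(length(nc)) < 0.5
  n_orders[nc[few]] <- sample(1:2, sum(few), replace = TRUE)
  n_orders[nc[!few]] <- 3L
  tight_span <- logical(n)
  tight_span[nc[!few]] <- TRUE   # 3 orders but all within < 30 days
  rows_id <- rep(seq_len(n), n_orders)
  gap <- numeric(length(rows_id))
  first <- !duplicated(rows_id)
  tight <- rep(tight_span, n_orders)
  gap[!first & !tight] <- round(stats::runif(sum(!first & !tight), 20, 45))
  gap[!first & tight] <- round(stats::runif(sum(!first & tight), 3, 12))
  offset <- stats::ave(gap, rows_id, FUN = cumsum)
  tibble::tibble(
    patient_id = patient_id[rows_id],
    date = index_date[rows_id] + offset,
    brand = brand[rows_id]
  ) |>
    dplyr::left_join(glp1_brands, by = "brand") |>
    dplyr::select(patient_id, date, ingredient, brand)
}

.gen_weights <- function(config, patient_id, class, baseline_kg, index_date) {
  n <- length(patient_id)
  pre_days <- config$pre_years * 365
  n_pre <- stats::rpois(n, config$pre_weights_per_year * config$pre_years)
  n_post <- stats::rbinom(n, stats::rpois(n, config$visits_per_month_rate * 12),
                          config$weight_visit_fraction)
  has_bl <- stats::runif(n) < config$baseline_weight_prob

  idx <- c(rep(seq_len(n), n_pre), rep(seq_len(n), n_post),
           which(has_bl))
  t <- c(-round(stats::runif(sum(n_pre), 1, pre_days)),
         round(stats::runif(sum(n_post), 1, 365)),
         -round(stats::runif(sum(has_bl), 0, 30)))
  w_true <- numeric(length(idx))
  for (cl in response_classes) {
    sel <- class[idx] == cl
    if (!any(sel)) next
    w_true[sel] <- true_weight_curve(
      cl, baseline_kg[idx[sel]], t[sel],
      config$post_curve_params_by_class[[cl]],
      config$pre_drift_pct_per_year_by_class[[cl]])
  }
  tibble::tibble(
    patient_id = patient_id[idx],
    date = index_date[idx] + t,
    weight = w_true + stats::rnorm(length(idx), 0, config$measurement_noise_sd_kg),
    units = "kg"
  ) |> dplyr::arrange(patient_id, date)
}

.gen_phenotypes <- function(config, patient_id, class, index_date) {
  n <- length(patient_id)
  panel <- config$disease_panel
  qn <- config$qualifier_noise
  out <- vector("list", nrow(panel) + 2L)
  truth_rows <- vector("list", nrow(panel))

  emit <- function(idx, concept, t_lo, t_hi, n_mentions,
                   subject = "patient", temporality = "current",
                   certainty = "confirmed", source = NULL) {
    rid <- rep(idx, n_mentions)
    if (!length(rid)) return(NULL)
    if (is.null(source))
      source <- sample(c("structured", "text_derived"), length(rid),
                       replace = TRUE, prob = c(0.6, 0.4))
    tibble::tibble(
      patient_id = patient_id[rid],
      date = index_date[rid] - round(stats::runif(length(rid), t_lo, t_hi)),
      concept = concept, source = source,
      subject = subject, temporality = temporality, certainty = certainty
    )
  }

  for (k in seq_len(nrow(panel))) {
    p0 <- panel$base_prevalence[k]
    lrr <- c(super = panel$log_rr_super[k], moderate = panel$log_rr_moderate[k],
             minimal = panel$log_rr_minimal[k], regainer = panel$log_rr_regainer[k])
    p <- pmin(p0 * exp(lrr[class]), 1)
    has <- stats::runif(n) < p
    idx <- which(has)
    real <- emit(idx, panel$concept[k], 30, 365,
                 1L + stats::rpois(length(idx), 1))
    # qualifier-noise mentions on patients without the disease
    pool <- which(!has)
    noise <- list()
    qmap <- list(
      negated  = list(subject = "patient", temporality = "current", certainty = "negated"),
      past     = list(subject = "patient", temporality = "past", certainty = "confirmed"),
      other    = list(subject = "other", temporality = "current", certainty = "confirmed"),
      suspected = list(subject = "patient", temporality = "current", certainty = "suspected")
    )
    for (q in names(qmap)) {
      nq <- stats::rbinom(1, length(pool), p0 * qn[[q]])
      if (nq > 0) {
        qi <- sample(pool, nq)
        noise[[q]] <- emit(qi, panel$concept[k], 30, 365, rep(1L, nq),
                           subject = qmap[[q]]$subject,
                           temporality = qmap[[q]]$temporality,
                           certainty = qmap[[q]]$certainty,
                           source = "text_derived")
      }
    }
    out[[k]] <- dplyr::bind_rows(c(list(real), noise))
    truth_rows[[k]] <- tibble::tibble(patient_id = patient_id[idx],
                                      concept = panel$concept[k])
  }

  # T2DM: >= 3 coded diagnoses over the 5 pre-index years
  t2dm_idx <- which(stats::runif(n) < config$t2dm_prevalence)
  out[[nrow(panel) + 1L]] <- emit(t2dm_idx, "type 2 diabetes mellitus",
                                  1, 5 * 365,
                                  3L + stats::rpois(length(t2dm_idx), 2),
                                  source = "structured")
  # pregnancy: >= 1 diagnosis in the pre-index year
  preg_idx <- which(stats::runif(n) < config$pregnancy_prevalence)
  out[[nrow(panel) + 2L]] <- emit(preg_idx, "pregnancy", 1, 365,
                                  1L + stats::rpois(length(preg_idx), 1),
                                  source = "structured")

  list(mentions = dplyr::bind_rows(out) |> dplyr::arrange(patient_id, date),
       truth_diseases = dplyr::bind_rows(truth_rows))
}
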