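rx <- function(id, days, brand = "Ozempic") {
  tibble::tibble(patient_id = id, date = as.Date("2023-01-01") + days,
                 ingredient = glp1_brands$ingredient[match(brand, glp1_brands$brand)],
                 brand = brand)
}

test_that("exposure filter enforces >= 3 orders spanning >= 30 days", {
  p <- dplyr::bind_rows(
    rx("short_span", c(0, 10, 24)),    # span 24 d -> out
    rx("boundary", c(0, 15, 31)),      # span 31 d -> in
    rx("exact30", c(0, 10, 30)),       # span exactly 30 -> in
    rx("two_orders", c(0, 90)),        # only 2 orders -> out
    rx("many", c(0, 35, 70, 120)))
  keep <- apply_exposure_filter(p)
  expect_setequal(keep, c("boundary", "exact30", "many"))
})

test_that("bariatric exclusion applies to pre-index history only", {
  pats <- tibble::tibble(patient_id = c("a", "b", "c"))
  idx <- tibble::tibble(patient_id = c("a", "b", "c"),
                        index_date = as.Date("2023-01-01"))
  ev <- tibble::tibble(patient_id = c("a", "c"),
                       date = as.Date(c("2018-01-01",   # 5 y pre -> excluded
                                        "2023-06-01"))) # post-index -> retained
  keep <- exclude_bariatric(pats, procedure_events = ev, index_dates = idx)
  expect_setequal(keep, c("b", "c"))
  # flag-based path
  pats2 <- tibble::tibble(patient_id = c("x", "y"),
                          bariatric_history = c(TRUE, FALSE))
  expect_equal(exclude_bariatric(pats2), "y")
})

test_that("baseline weight is the closest measurement in the closed 90-day
           window, with same-day duplicates averaged", {
  pats <- tibble::tibble(patient_id = c("p1", "p2", "p3"),
                         birth_date = as.Date("1980-01-01"),
                         gender = "female", race = "white",
                         bariatric_history = FALSE)
  p <- dplyr::bind_rows(rx("p1", c(0, 35, 70)), rx("p2", c(0, 35, 70)),
                        rx("p3", c(0, 35, 70)))
  idxd <- as.Date("2023-01-01")
  w <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p3", "p3", "p1", "p2", "p3"),
    date = c(idxd - 80, idxd - 5,             # p1: closest = -5 d
             idxd - 120,                       # p2: outside window -> dropped
             idxd - 10, idxd - 10,             # p3: same-day pair -> mean
             idxd + 100, idxd + 100, idxd + 100),
    weight = c(95, 90, 88, 100, 102, 85, 80, 96),
    units = "kg")
  di <- derive_index(pats, p, w)
  expect_setequal(di$cohort$patient_id, c("p1", "p3"))
  expect_equal(di$cohort$baseline_weight_kg[di$cohort$patient_id == "p1"], 90)
  expect_equal(di$cohort$baseline_weight_kg[di$cohort$patient_id == "p3"], 101)
  expect_equal(di$cohort$baseline_weight_date[di$cohort$patient_id == "p1"],
               idxd - 5)
  # funnel monotone and p2 dropped at the baseline stage
  expect_true(all(diff(di$funnel$n) <= 0))
  expect_equal(di$funnel$n[di$funnel$stage == "baseline_weight_within_90d"], 2)
})

test_that("patients without a strictly post-index first-year weight are
           dropped", {
  pats <- tibble::tibble(patient_id = "q", birth_date = as.Date("1980-01-01"),
                         gender = "male", race = "white",
                         bariatric_history = FALSE)
  idxd <- as.Date("2023-01-01")
  w <- tibble::tibble(patient_id = "q",
                      date = c(idxd - 5, idxd, idxd + 400),
                      weight = c(90, 91, 80), units = "kg")
  di <- derive_index(pats, rx("q", c(0, 35, 70)), w)
  expect_equal(nrow(di$cohort), 0)
})

test_that("brand exclusivity labels non-switchers and merges Bydureon
           variants", {
  p <- dplyr::bind_rows(
    rx("only_zep", c(0, 40), "Zepbound"),
    dplyr::bind_rows(rx("switcher", 0, "Ozempic"), rx("switcher", 40, "Wegovy")),
    dplyr::bind_rows(rx("byd", 0, "Bydureon"), rx("byd", 40, "Bydureon BCise")))
  s <- brand_exclusive_strata(p)
  expect_equal(s$brand_exclusive[s$patient_id == "only_zep"], "Zepbound")
  expect_true(is.na(s$brand_exclusive[s$patient_id == "switcher"]))
  expect_equal(s$brand_exclusive[s$patient_id == "byd"], "Bydureon")
  # switching brand within one molecule still breaks brand exclusivity
  # but preserves drug exclusivity
  expect_equal(s$drug_exclusive[s$patient_id == "switcher"], "semaglutide")
})

test_that("baseline flags use the 5-year / 1-year windows and counts", {
  idx <- tibble::tibble(patient_id = c("a", "b", "c"),
                        index_date = as.Date("2023-01-01"))
  d0 <- as.Date("2023-01-01")
  ph <- make_mentions(
    c("a", "a",                       # 2 diabetes dx in window -> FALSE
      "b", "b", "b",                  # 3 dx but one outside 5 y -> FALSE
      "c", "c", "c",                  # 3 in window -> TRUE
      "a"),                           # pregnancy at -200 d -> TRUE
    c(d0 - 100, d0 - 400,
      d0 - 100, d0 - 400, d0 - 6 * 365,
      d0 - 100, d0 - 400, d0 - 1500,
      d0 - 200),
    c(rep("type 2 diabetes mellitus", 8), "pregnancy"))
  fl <- baseline_flags(ph, idx)
  expect_equal(fl$t2dm, c(FALSE, FALSE, TRUE))
  expect_equal(fl$pregnant_prior_year, c(TRUE, FALSE, FALSE))
})

test_that("weight normalization converts pounds and gates implausible
           values", {
  w <- tibble::tibble(patient_id = c("a", "b", "c"),
                      date = as.Date("2023-01-01"),
                      weight = c(220, 100, 900), units = c("lb", "kg", "kg"))
  expect_message(out <- normalize_weights(w), "dropped")
  expect_equal(nrow(out), 2)
  expect_equal(out$weight_kg[out$patient_id == "a"], 220 * 0.45359237)
  expect_equal(attr(out, "n_dropped"), 1)
})

test_that("funnel results are invariant to input row order and idempotent", {
  tab <- generate_population(small_config(n = 250, seed = 17, pre_years = 2))
  di1 <- derive_index(tab$patients, tab$prescriptions, tab$weights)
  shuffle <- function(df) df[sample(nrow(df)), ]
  set.seed(1)
  di2 <- derive_index(shuffle(tab$patients), shuffle(tab$prescriptions),
                      shuffle(tab$weights))
  expect_equal(di1$funnel, di2$funnel)
  o1 <- di1$cohort[order(di1$cohort$patient_id), ]
  o2 <- di2$cohort[order(di2$cohort$patient_id), ]
  expect_equal(o1, o2)
  # idempotence: re-filtering already-eligible prescriptions changes nothing
  keep <- apply_exposure_filter(tab$prescriptions)
  again <- apply_exposure_filter(
    tab$prescriptions[tab$prescriptions$patient_id %in% keep, ])
  expect_setequal(keep, again)
})
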