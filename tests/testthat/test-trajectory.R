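test_that("percent change is computed relative to baseline", {
  w <- tibble::tibble(patient_id = c("a", "a", "b"),
                      date = as.Date("2023-06-01") + c(30, 60, 30),
                      weight_kg = c(85, 100, 92))
  cohort <- make_cohort(c("a", "b"), baseline = c(100, 80))
  s <- pct_change_series(w, cohort)
  expect_equal(s$pct_change, c(-15, 0, 15))
  cohort$baseline_weight_kg[1] <- 0
  expect_error(pct_change_series(w, cohort), "positive")
})

test_that("four-way classification matches the category definitions", {
  cases <- list(
    # series, expected, comment
    list(t = c(100, 300, 360), pct = c(-10, -20, -18), exp = "super"),
    list(t = c(60, 150, 360), pct = c(-4, -8, -1), exp = "regainer"),
    list(t = c(60, 300), pct = c(-1, -3), exp = "minimal"),
    list(t = c(60, 300), pct = c(-10, -15), exp = "super"),    # boundary >= 15
    list(t = c(60, 300), pct = c(-10, -14.99), exp = "moderate"),
    list(t = c(60, 200, 360), pct = c(-10, -16, -10), exp = "regainer"),
    list(t = c(60, 300), pct = c(-2, -5), exp = "moderate"))   # boundary >= 5
  for (cs in cases) {
    lab <- classify_response(make_series("x", cs$t, cs$pct))
    expect_equal(as.character(lab$category), cs$exp,
                 info = paste(cs$pct, collapse = ","))
  }
})

test_that("regain precedence, supporting quantities and the strict-super
           option behave as configured", {
  s <- make_series("x", c(50, 150, 250, 360), c(-6, -16, -12, -10))
  lab <- classify_response(s)
  expect_equal(as.character(lab$category), "regainer")
  expect_equal(lab$max_loss_pct, 16)
  expect_equal(lab$nadir_t, 150)
  expect_equal(lab$regain_pct, 6)
  # comparator option: > 15 makes an exact-15 loss moderate
  s15 <- make_series("y", c(60, 300), c(-10, -15))
  expect_equal(as.character(
    classify_response(s15, super_comparator = ">")$category), "moderate")
  # regain_mode = "any" catches an intra-year rebound the last point misses
  s_dip <- make_series("z", c(50, 150, 250, 360), c(-3, -9, -3, -8.5))
  expect_equal(as.character(classify_response(s_dip)$category), "moderate")
  expect_equal(as.character(
    classify_response(s_dip, regain_mode = "any")$category), "regainer")
})

test_that("classification partitions the cohort and ignores out-of-window
           measurements", {
  tab <- generate_population(small_config(n = 400, seed = 31, pre_years = 2))
  cb <- suppressWarnings(build_cohort(tab))
  ser <- pct_change_series(normalize_weights(tab$weights), cb$cohort)
  lab <- classify_response(ser)
  expect_equal(nrow(lab), nrow(cb$cohort))     # every patient labeled
  expect_false(any(duplicated(lab$patient_id)))  # exactly once
  expect_false(any(is.na(lab$category)))
  expect_equal(sum(table(lab$category)), nrow(cb$cohort))
  # adding a measurement outside (0, 365] changes nothing
  extra <- dplyr::bind_rows(ser,
    make_series(lab$patient_id[1], c(-40, 380), c(-50, -50)))
  lab2 <- classify_response(extra)
  expect_equal(lab2[order(lab2$patient_id), ], lab[order(lab$patient_id), ])
  # ... as does row order
  set.seed(2)
  lab3 <- classify_response(ser[sample(nrow(ser)), ])
  expect_equal(lab3[order(lab3$patient_id), ], lab[order(lab$patient_id), ])
})

test_that("window aggregation computes patient-level means, SEM and n by
           hand-checkable arithmetic", {
  # patients A (-10) and B (-20) in one window: mean -15, sem = sd/sqrt(2) = 5
  s <- make_series(c("A", "B"), c(30, 32), c(-10, -20))
  cur <- aggregate_windows(s, grid = 30)
  expect_equal(cur$mean_value, -15)
  expect_equal(cur$sem, stats::sd(c(-10, -20)) / sqrt(2))
  expect_equal(cur$sem, 5)
  expect_equal(cur$n, 2L)
  # a patient with two measurements contributes one patient-level mean
  s2 <- make_series(c("A", "A", "B"), c(28, 32, 30), c(-8, -12, -20))
  cur2 <- aggregate_windows(s2, grid = 30)
  expect_equal(cur2$mean_value, mean(c(-10, -20)))
  expect_equal(cur2$n, 2L)
  # single-patient window: sem 0 and flagged
  cur3 <- aggregate_windows(make_series("A", 30, -10), grid = 30)
  expect_equal(cur3$sem, 0)
  expect_true(cur3$sem_flagged)
})

test_that("half-open windows assign each measurement to exactly one default
           window", {
  grid <- seq(0, 360, by = 30)
  t_all <- seq(-14.5, 374.5, by = 0.5)
  hits <- sapply(t_all, function(tm)
    sum(tm >= grid - 15 & tm < grid + 15))
  expect_true(all(hits == 1))
})

test_that("Savitzky-Golay smoothing reproduces cubics and matches the
           central-coefficient oracle", {
  t <- 0:12
  cubic <- 1 - 2 * t + 0.5 * t^2 - 0.02 * t^3
  expect_lt(max(abs(savgol_smooth(cubic) - cubic)), 1e-9)
  expect_equal(savgol_smooth(rep(3.5, 8)), rep(3.5, 8))
  # independent oracle: solve the 5-point order-3 least-squares projection
  x <- -2:2
  V <- outer(x, 0:3, `^`)
  H <- V %*% solve(crossprod(V)) %*% t(V)
  centre_coef <- H[3, ]
  expect_equal(centre_coef, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
  set.seed(4)
  y <- stats::rnorm(9)
  sm <- savgol_smooth(y)
  for (i in 3:7)
    expect_equal(sm[i], sum(centre_coef * y[(i - 2):(i + 2)]),
                 tolerance = 1e-10)
  # degree-1 mean preservation over interior points
  lin <- 2 + 3 * (1:11)
  expect_equal(savgol_smooth(lin), lin)
})

test_that("short or gappy series are handled: pass-through below window
           length, interpolation and re-masking of suppressed windows", {
  expect_warning(out <- savgol_smooth(c(1, 2, 3)), "shorter")
  expect_equal(out, c(1, 2, 3))
  gap <- c(0, 1, NA, 9, 16, 25, 36)   # quadratic with a hole
  sm <- savgol_smooth(gap)
  expect_true(is.na(sm[3]))           # re-masked
  expect_false(anyNA(sm[-3]))
})

test_that("historical curve recovers a planted linear drift and suppresses
           sparse windows", {
  # noise-free drift: +1%/yr of baseline going back 20 years
  set.seed(6)
  n_pat <- 60
  rows <- lapply(seq_len(n_pat), function(i) {
    t <- sort(-sample.int(7300, 40))
    make_series(sprintf("h%02d", i), t, -1 * t / 365)  # pct = +1%/yr back
  })
  s <- dplyr::bind_rows(rows)
  hc <- historical_curve(s, n_floor = 5)
  ok <- !is.na(hc$mean_value)
  fit <- stats::lm(hc$mean_value[ok] ~ hc$t_days[ok])
  expect_equal(unname(stats::coef(fit)[2]) * -365, 1, tolerance = 0.02)
  # n-floor: a window with fewer patients than the floor is suppressed
  s19 <- make_series(sprintf("q%02d", 1:19), rep(-300, 19), rnorm(19))
  hc19 <- suppressWarnings(historical_curve(s19, grid = -300, n_floor = 20))
  expect_true(is.na(hc19$mean_value))
  hc19b <- suppressWarnings(historical_curve(s19, grid = -300, n_floor = 19))
  expect_false(is.na(hc19b$mean_value))
})

test_that("restoration lookback returns the earliest qualifying window", {
  # monotone pre-index gain crossing the post mean exactly at -10 y
  grid <- seq(-7300, -30, by = 365)
  hc <- tibble::tibble(t_days = grid,
                       mean_value = 100 - 1 * grid / 365,  # kg, +1 kg/yr back
                       sem = 0, n = 50, sem_flagged = FALSE, smoothed = NA)
  expect_equal(restoration_lookback(hc, post_mean_kg = 110, tolerance_kg = 0.5),
               10)
  # flat curve above post mean + tolerance -> none
  hc$mean_value <- 120
  expect_true(is.na(restoration_lookback(hc, 100, tolerance_kg = 1)))
})

test_that("percent-change quantities are invariant to uniform weight
           scaling", {
  tab <- generate_population(small_config(n = 120, seed = 23, pre_years = 2))
  cb <- suppressWarnings(build_cohort(tab))
  w <- normalize_weights(tab$weights)
  s1 <- pct_change_series(w, cb$cohort)
  w2 <- w; w2$weight_kg <- w2$weight_kg * 1.7
  ch2 <- cb$cohort; ch2$baseline_weight_kg <- ch2$baseline_weight_kg * 1.7
  s2 <- pct_change_series(w2, ch2)
  expect_equal(s2$pct_change, s1$pct_change)
  expect_equal(classify_response(s2), classify_response(s1))
})
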