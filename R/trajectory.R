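#' Per-patient percent weight-change series
#'
#' Expresses every weight measurement as a percent change from the patient's
#' baseline weight, `100 * (w - baseline) / baseline` (negative = loss), with
#' time measured in days from the index date.
#'
#' @param weights normalized weights (`patient_id`, `date`, `weight_kg`).
#' @param cohort indexed cohort (`patient_id`, `index_date`,
#'   `baseline_weight_kg`), e.g. from [derive_index()].
#' @return Tibble `patient_id`, `t_days`, `pct_change`, `weight_kg`.
#' @export
pct_change_series <- function(weights, cohort) {
  if (any(cohort$baseline_weight_kg <= 0))
    stop("baseline weight must be positive", call. = FALSE)
  weights |>
    dplyr::inner_join(
      cohort[c("patient_id", "index_date", "baseline_weight_kg")],
      by = "patient_id") |>
    dplyr::transmute(
      patient_id,
      t_days = as.numeric(date - index_date),
      pct_change = 100 * (weight_kg - baseline_weight_kg) / baseline_weight_kg,
      weight_kg)
}

#' Classify first-year weight-loss response
#'
#' Assigns each patient one of four response categories from the maximum
#' weight loss among measurements in `(0, 365]` days after the index date:
#' super responders (maximum loss >= 15% of baseline), moderate responders
#' (5-15%), minimal weight-loss (< 5%), and weight regainers (an initial
#' >= 5% loss followed by a regain of >= 5 percentage points of baseline
#' between the nadir and the last first-year observation). Regain takes
#' precedence, so the four categories partition the cohort. The nadir is the
#' earliest measurement attaining the minimum.
#'
#' @param series percent-change series from [pct_change_series()].
#' @param super_threshold,moderate_threshold,regain_threshold category cut
#'   points in percent of baseline (defaults 15 / 5 / 5).
#' @param super_comparator `">="` (default) or `">"` for the super boundary.
#' @param regain_mode `"last"` (default: regain measured at the last
#'   first-year observation) or `"any"` (any post-nadir observation regaining
#'   >= threshold).
#' @return Tibble `patient_id`, `category`, `max_loss_pct`, `nadir_t`,
#'   `regain_pct`; `category` is a factor over
#'   `super, moderate, minimal, regainer`.
#' @export
classify_response <- function(series, super_threshold = 15,
                              moderate_threshold = 5, regain_threshold = 5,
                              super_comparator = c(">=", ">"),
                              regain_mode = c("last", "any")) {
  super_comparator <- match.arg(super_comparator)
  regain_mode <- match.arg(regain_mode)
  s <- series |> dplyr::filter(t_days > 0, t_days <= 365)
  if (nrow(s) == 0)
    stop("no post-index measurements within (0, 365] days", call. = FALSE)
  per <- s |>
    dplyr::arrange(patient_id, t_days, pct_change) |>
    dplyr::summarise(
      min_pct = min(pct_change),
      nadir_t = t_days[which.min(pct_change)],
      regain_pct = if (regain_mode == "last")
        pct_change[dplyr::n()] - min(pct_change)
      else max(0, max(pct_change[t_days >= t_days[which.min(pct_change)]]) -
                 min(pct_change)),
      .by = patient_id)
  is_super <- if (super_comparator == ">=")
    -per$min_pct >= super_threshold else -per$min_pct > super_threshold
  per |>
    dplyr::mutate(
      max_loss_pct = -min_pct,
      category = factor(dplyr::case_when(
        max_loss_pct >= regain_threshold & regain_pct >= regain_threshold ~
          "regainer",
        is_super ~ "super",
        max_loss_pct >= moderate_threshold ~ "moderate",
        TRUE ~ "minimal"
      ), levels = response_classes)) |>
    dplyr::select(patient_id, category, max_loss_pct, nadir_t, regain_pct)
}

#' Aggregate a series into 30-day windows
#'
#' For every grid time `t` the half-open window `[t - halfwidth, t +
#' halfwidth)` collects measurements; each patient contributes the mean of
#' their own measurements in the window (so no patient is counted twice),
#' and the curve value is the mean of those patient-level means. Uncertainty
#' is the standard error of the mean, `SEM = sd / sqrt(n)` over patient
#' means (sample sd, `n - 1` denominator); windows with a single patient get
#' `sem = 0` and are flagged, and windows with fewer than `n_floor` patients
#' are suppressed (value `NA`).
#'
#' @param series tibble with `patient_id`, `t_days` and the value column.
#' @param grid ordered vector of window centres (days from index).
#' @param halfwidth window half width in days (default 15).
#' @param value value column to aggregate (default `pct_change`).
#' @param n_floor minimum patients per window (default 1).
#' @return Tibble `t_days`, `mean_value`, `sem`, `n`, `sem_flagged`.
#' @export
aggregate_windows <- function(series, grid = seq(0, 360, by = 30),
                              halfwidth = 15, value = "pct_change",
                              n_floor = 1L) {
  stopifnot(all(diff(grid) > 0))
  v <- series[[value]]
  rows <- purrr::map(seq_along(grid), function(i) {
    t0 <- grid[i]
    in_w <- series$t_days >= t0 - halfwidth & series$t_days < t0 + halfwidth
    if (!any(in_w))
      return(tibble::tibble(t_days = t0, mean_value = NA_real_, sem = NA_real_,
                            n = 0L, sem_flagged = FALSE))
    pm <- tapply(v[in_w], series$patient_id[in_w], mean)
    n <- length(pm)
    tibble::tibble(
      t_days = t0,
      mean_value = mean(pm),
      sem = if (n > 1) stats::sd(pm) / sqrt(n) else 0,
      n = n,
      sem_flagged = n == 1L)
  })
  out <- dplyr::bind_rows(rows)
  out$mean_value[out$n < n_floor] <- NA_real_
  out$sem[out$n < n_floor] <- NA_real_
  out
}

#' Savitzky-Golay smoothing of a windowed curve
#'
#' Least-squares polynomial smoothing with window length 5 and polynomial
#' order 3 by default; interior points use the central convolution
#' coefficients and edge points come from the polynomial fit to the nearest
#' five points evaluated at the edge position, so a cubic series is
#' reproduced exactly. Interior `NA`s (suppressed windows) are linearly
#' interpolated before filtering and re-masked afterwards so the filter sees
#' an equally spaced complete series. Series shorter than the window are
#' returned unchanged with a warning.
#'
#' @param x numeric vector, equally spaced.
#' @param window odd filter length (default 5).
#' @param order polynomial order (default 3).
#' @return Smoothed numeric vector, same length as `x`.
#' @export
savgol_smooth <- function(x, window = 5L, order = 3L) {
  n_obs <- sum(!is.na(x))
  if (n_obs < window) {
    warning("series shorter than the smoothing window; returning raw values")
    return(x)
  }
  na_mask <- is.na(x)
  xi <- x
  if (any(na_mask)) {
    obs <- which(!na_mask)
    xi <- stats::approx(obs, x[obs], xout = seq_along(x), rule = 2)$y
  }
  sm <- signal::sgolayfilt(xi, p = order, n = window)
  sm[na_mask] <- NA_real_
  sm
}

#' Population trajectory curve over the first treatment year
#'
#' Windowed mean percent-change curve with SEM and per-window n, smoothed
#' with the Savitzky-Golay filter (window 5, order 3).
#'
#' @inheritParams aggregate_windows
#' @return Tibble `t_days`, `mean_pct`, `sem`, `n`, `smoothed_pct`.
#' @export
window_aggregate <- function(series, grid = seq(0, 360, by = 30),
                             halfwidth = 15, n_floor = 1L) {
  cur <- aggregate_windows(series, grid, halfwidth, "pct_change", n_floor)
  tibble::tibble(
    t_days = cur$t_days,
    mean_pct = cur$mean_value,
    sem = cur$sem,
    n = cur$n,
    smoothed_pct = savgol_smooth(cur$mean_value))
}

#' Multi-decade pre-treatment trajectory curve
#'
#' Same aggregation as [window_aggregate()] over a pre-index grid (default
#' back to 20 years), with sparse windows suppressed below a configurable
#' patient floor. Aggregates either percent change or absolute weight.
#'
#' @inheritParams aggregate_windows
#' @param n_floor minimum patients per window (default 20).
#' @param value `"pct_change"` or `"weight_kg"`.
#' @return Tibble `t_days`, `mean_value`, `sem`, `n`, `smoothed`.
#' @export
historical_curve <- function(series, grid = seq(-7300, 0, by = 30),
                             halfwidth = 15, n_floor = 20L,
                             value = c("pct_change", "weight_kg")) {
  value <- match.arg(value)
  cur <- aggregate_windows(series, grid, halfwidth, value, n_floor)
  cur$smoothed <- savgol_smooth(cur$mean_value)
  cur
}

#' Years of weight history restored by treatment
#'
#' Finds how far back one must go for the population's historical mean
#' weight to match its post-treatment mean weight: returns the earliest
#' (most distant) pre-index time whose window mean lies within
#' `tolerance_kg` of `post_mean_kg`, in years before index, or `NA` when no
#' window qualifies.
#'
#' @param hist_curve historical curve in absolute kg (from
#'   [historical_curve()] with `value = "weight_kg"`).
#' @param post_mean_kg post-treatment mean weight (kg) to match.
#' @param tolerance_kg matching tolerance (default 1 kg).
#' @return Years before index (positive scalar) or `NA`.
#' @export
restoration_lookback <- function(hist_curve, post_mean_kg, tolerance_kg = 1) {
  stopifnot(nrow(hist_curve) > 0)
  ok <- !is.na(hist_curve$mean_value) &
    abs(hist_curve$mean_value - post_mean_kg) <= tolerance_kg &
    hist_curve$t_days < 0
  if (!any(ok)) return(NA_real_)
  -min(hist_curve$t_days[ok]) / 365
}
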