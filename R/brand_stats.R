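#' Wilson score interval for a binomial proportion
#'
#' The score-test inversion interval: centre `(k + z^2/2) / (n + z^2)` and
#' half width `z * sqrt(k (n - k) / n + z^2 / 4) / (n + z^2)`. Preferred
#' over the Wald interval for proportions near 0 or 1. Vectorised over `k`
#' and `n`.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (> 0).
#' @param conf confidence level (default 0.95).
#' @return Tibble `k`, `n`, `proportion`, `ci_low`, `ci_high`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  centre <- (k + z^2 / 2) / (n + z^2)
  half <- z * sqrt(k * (n - k) / n + z^2 / 4) / (n + z^2)
  tibble::tibble(k = k, n = n, proportion = k / n,
                 ci_low = pmax(0, centre - half),
                 ci_high = pmin(1, centre + half))
}

#' Odds ratio with Wald confidence interval and test
#'
#' For a 2x2 table with cells `a, b` (cohort 1: outcome yes/no) and `c, d`
#' (cohort 2), computes `OR = (a d) / (b c)`, the log-scale standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`, the Wald interval
#' `exp(log OR +/- z SE)`, and the two-sided p-value from the Wald z
#' statistic on the log odds ratio. Any zero cell triggers the
#' Haldane-Anscombe correction (0.5 added to all cells), recorded in
#' `continuity_applied`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param conf confidence level (default 0.95).
#' @return Tibble `or_value`, `ci_low`, `ci_high`, `p_value`,
#'   `continuity_applied`.
#' @export
odds_ratio <- function(a, b, c, d, conf = 0.95) {
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4, all(cells >= 0))
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("odds ratio undefined: a zero row or column total", call. = FALSE)
  continuity <- any(cells == 0)
  if (continuity) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  wald_z <- log(or) / se
  tibble::tibble(
    or_value = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    p_value = 2 * stats::pnorm(-abs(wald_z)),
    continuity_applied = continuity)
}

#' Brand-by-category contingency table with Wilson intervals
#'
#' Counts, within-brand percentages and Wilson 95% intervals per brand x
#' response category, mirroring the brand-stratification heatmap. Empty
#' brand cohorts are omitted with a warning.
#'
#' @param labels tibble `patient_id`, `category` (see [classify_response()]).
#' @param strata tibble `patient_id`, `brand_exclusive` (see
#'   [brand_exclusive_strata()]); patients with `NA` (switchers) are
#'   excluded.
#' @param conf confidence level for the Wilson intervals.
#' @return Tibble `brand`, `category`, `count`, `brand_total`, `pct`,
#'   `ci_low`, `ci_high` (percent scale).
#' @export
category_table <- function(labels, strata, conf = 0.95) {
  df <- labels |>
    dplyr::inner_join(strata, by = "patient_id") |>
    dplyr::filter(!is.na(brand_exclusive))
  if (nrow(df) == 0) {
    warning("no brand-exclusive patients with labels")
    return(tibble::tibble())
  }
  counts <- df |>
    dplyr::count(brand = brand_exclusive, category, .drop = FALSE) |>
    dplyr::mutate(brand_total = sum(n), .by = brand) |>
    dplyr::filter(brand_total > 0)
  ci <- wilson_ci(counts$n, counts$brand_total, conf)
  counts |>
    dplyr::transmute(brand, category, count = n, brand_total,
                     pct = 100 * count / brand_total,
                     ci_low = 100 * ci$ci_low, ci_high = 100 * ci$ci_high)
}

#' Pairwise brand odds ratios per response category
#'
#' For each category and each ordered brand pair, builds the outcome-vs-rest
#' 2x2 table within the two brand-exclusive cohorts and applies
#' [odds_ratio()].
#'
#' @param cat_table output of [category_table()].
#' @param brand_pairs optional list of `c(brand_a, brand_b)` pairs; default
#'   all ordered pairs.
#' @return Tibble `brand_a`, `brand_b`, `category`, `or`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
pairwise_brand_or <- function(cat_table, brand_pairs = NULL) {
  brands <- unique(cat_table$brand)
  if (is.null(brand_pairs)) {
    brand_pairs <- list()
    for (i in brands) for (j in brands) if (i != j)
      brand_pairs <- c(brand_pairs, list(c(i, j)))
  }
  purrr::map_dfr(brand_pairs, function(pr) {
    purrr::map_dfr(unique(as.character(cat_table$category)), function(cat) {
      ra <- cat_table[cat_table$brand == pr[1] & cat_table$category == cat, ]
      rb <- cat_table[cat_table$brand == pr[2] & cat_table$category == cat, ]
      if (nrow(ra) == 0 || nrow(rb) == 0) return(NULL)
      # a category absent from both cohorts has no defined OR; skip it
      o <- tryCatch(
        odds_ratio(ra$count, ra$brand_total - ra$count,
                   rb$count, rb$brand_total - rb$count),
        error = function(e) NULL)
      if (is.null(o)) return(NULL)
      tibble::tibble(brand_a = pr[1], brand_b = pr[2], category = cat,
                     or = o$or_value, ci_low = o$ci_low, ci_high = o$ci_high,
                     p_value = o$p_value)
    })
  })
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson chi-square on an r x c count table (no Yates
#' continuity correction by default, matching large-sample EHR practice).
#' All-zero rows and columns are dropped with a warning; a table degenerate
#' after dropping (fewer than 2 rows or columns) returns `NA` with a
#' warning.
#'
#' @param tab matrix of counts.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return Scalar p-value (or `NA` for degenerate tables).
#' @export
chisq_independence <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping all-zero row(s)/column(s) before testing")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("degenerate table after dropping zero margins; test skipped")
    return(NA_real_)
  }
  suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
}
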