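#' Pipeline run configuration
#'
#' Bundles every stage's settings: either a generator configuration (the
#' default demo mode) or a directory of external input tables; the
#' trajectory grids; the matching caliper; FDR family mode; and the global
#' seed. The global seed fans out to per-stage streams by fixed additive
#' offsets (generator: seed; de-identification export: seed + 1) so stages
#' can be re-run in isolation reproducibly.
#'
#' @param generator a [generator_config()], or `NULL` in external-table mode.
#' @param input_dir directory with the four input CSVs (external-table
#'   mode); exactly one of `generator` / `input_dir` must be set.
#' @param post_grid,pre_grid trajectory window centres (days from index).
#' @param historical_n_floor minimum patients per historical window.
#' @param caliper matching caliper on the propensity-score scale.
#' @param fdr_family `"per_comparison"` (default) or `"global"`.
#' @param screen_window pre-treatment screen window, days before index.
#' @param seed global integer seed.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_dir = NULL,
                            post_grid = seq(0, 360, by = 30),
                            pre_grid = seq(-7300, 0, by = 30),
                            historical_n_floor = 20L,
                            caliper = 0.1,
                            fdr_family = c("per_comparison", "global"),
                            screen_window = c(365, 30),
                            seed = 1L) {
  if (is.null(generator) == is.null(input_dir))
    stop("exactly one of generator / input_dir must be given", call. = FALSE)
  structure(list(generator = generator, input_dir = input_dir,
                 post_grid = post_grid, pre_grid = pre_grid,
                 historical_n_floor = as.integer(historical_n_floor),
                 caliper = caliper,
                 fdr_family = match.arg(fdr_family),
                 screen_window = screen_window,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes generate (or load) -> cohort funnel -> trajectory classification
#' and curves -> brand-stratified statistics -> propensity matching ->
#' phenome screen, writing every stage's output as CSV plus a JSON manifest
#' (config hash, seed, funnel counts, stage row counts). Re-running with the
#' same configuration and seed reproduces the CSVs byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (!is.null(config$generator)) {
    gen_cfg <- config$generator
    gen_cfg$seed <- config$seed
    tables <- generate_population(gen_cfg)
    write_ehr_tables(tables, file.path(out_dir, "tables"))
  } else {
    tables <- read_ehr_tables(config$input_dir)
  }
  tables$weights <- normalize_weights(tables$weights)

  cb <- build_cohort(tables)
  cohort <- cb$cohort
  readr::write_csv(cohort, file.path(out_dir, "cohort.csv"))
  readr::write_csv(cb$funnel, file.path(out_dir, "funnel.csv"))

  series <- pct_change_series(tables$weights, cohort)
  labels <- classify_response(series)
  readr::write_csv(labels, file.path(out_dir, "response_labels.csv"))

  labelled <- dplyr::inner_join(cohort, labels, by = "patient_id")
  curves <- labels |>
    dplyr::distinct(category) |>
    dplyr::pull(category) |>
    as.character() |>
    purrr::set_names() |>
    purrr::map_dfr(function(cat) {
      ids <- labels$patient_id[labels$category == cat]
      window_aggregate(series[series$patient_id %in% ids, ],
                       grid = config$post_grid) |>
        dplyr::mutate(category = cat, .before = 1)
    })
  readr::write_csv(curves, file.path(out_dir, "trajectory_curves.csv"))

  hist_curves <- purrr::map_dfr(
    purrr::set_names(unique(as.character(labels$category))), function(cat) {
      ids <- labels$patient_id[labels$category == cat]
      historical_curve(series[series$patient_id %in% ids, ],
                       grid = config$pre_grid,
                       n_floor = config$historical_n_floor,
                       value = "weight_kg") |>
        dplyr::mutate(category = cat, .before = 1)
    })
  readr::write_csv(hist_curves, file.path(out_dir, "historical_curves.csv"))

  cat_tab <- category_table(labels,
                            cohort[c("patient_id", "brand_exclusive")])
  readr::write_csv(cat_tab, file.path(out_dir, "brand_category_table.csv"))
  or_tab <- pairwise_brand_or(cat_tab)
  readr::write_csv(or_tab, file.path(out_dir, "brand_odds_ratios.csv"))

  # per-drug matched comparisons: super vs minimal and super vs moderate
  drugs <- stats::na.omit(unique(labelled$brand_exclusive))
  comparisons <- list()
  screens <- list()
  for (drug in drugs) {
    for (comp in c("minimal", "moderate")) {
      sub <- labelled[!is.na(labelled$brand_exclusive) &
                        labelled$brand_exclusive == drug &
                        labelled$category %in% c("super", comp), ]
      if (sum(sub$category == "super") < 25 ||
          sum(sub$category == comp) < 25) next
      key <- paste(drug, "super_vs", comp, sep = "_")
      mc <- match_response_cohorts(sub, treated_category = "super",
                                   control_category = comp,
                                   caliper = config$caliper)
      comparisons[[key]] <- mc
      scr <- screen_phenotypes(
        tables$phenotypes,
        mc$matched$pairs$treated_id, mc$matched$pairs$control_id,
        cohort, window = config$screen_window)
      scr$drug <- drug
      scr$comparison <- paste0("super_vs_", comp)
      screens[[key]] <- scr
    }
  }
  if (length(screens)) {
    if (config$fdr_family == "global") {
      allscr <- dplyr::bind_rows(screens)
      allscr$fdr_p <- bh_adjust(allscr$p_value)
      screens <- split(allscr, interaction(allscr$drug, allscr$comparison,
                                           drop = TRUE))
    }
    screen_all <- dplyr::bind_rows(screens)
    readr::write_csv(screen_all, file.path(out_dir, "phenome_screen.csv"))
    sv_min <- screens[grepl("minimal", names(screens))]
    if (length(sv_min)) {
      names(sv_min) <- sub("_super_vs_minimal", "", names(sv_min))
      hm <- select_heatmap_features(sv_min)
      if (nrow(hm$matrix)) {
        readr::write_csv(hm$matrix, file.path(out_dir, "heatmap_matrix.csv"))
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("glp1traj")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    funnel = cb$funnel,
    rows = list(cohort = nrow(cohort), labels = nrow(labels),
                curves = nrow(curves),
                screens = if (length(screens))
                  nrow(dplyr::bind_rows(screens)) else 0L)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "columns", digits = NA)

  invisible(list(tables = tables, cohort = cohort, funnel = cb$funnel,
                 labels = labels, curves = curves, hist_curves = hist_curves,
                 category_table = cat_tab, odds_ratios = or_tab,
                 matches = comparisons, screens = screens))
}

#' Match two response cohorts on age and gender
#'
#' Fits the age + gender propensity model for treated-category membership
#' within a labelled cohort and applies greedy 1:1 caliper matching, with
#' balance diagnostics before and after.
#'
#' @param labelled cohort tibble with `patient_id`, `category`,
#'   `age_at_index`, `gender`.
#' @param treated_category,control_category category names forming the two
#'   arms (default super vs minimal).
#' @param caliper matching caliper (default 0.1).
#' @return List with `model` ([fit_propensity()] result), `matched`
#'   ([greedy_match()] result), `balance_pre`, `balance_post`.
#' @export
match_response_cohorts <- function(labelled, treated_category = "super",
                                   control_category = "minimal",
                                   caliper = 0.1) {
  sub <- labelled[labelled$category %in%
                    c(treated_category, control_category), ]
  sub$group <- sub$category == treated_category
  model <- fit_propensity(sub, group = "group", age = "age_at_index",
                          gender = "gender")
  ok <- !is.na(sub$age_at_index) & !is.na(sub$gender)
  sub <- sub[ok, ]
  sub$score <- unname(model$scores)
  treated <- sub[sub$group, c("patient_id", "score")]
  control <- sub[!sub$group, c("patient_id", "score")]
  matched <- greedy_match(treated, control, caliper)
  covs <- c("age_at_index", "gender")
  pre <- purrr::map_dfr(covs, function(cv) {
    xt <- sub[[cv]][sub$group]; xc <- sub[[cv]][!sub$group]
    if (!is.numeric(xt)) {
      xt <- as.numeric(xt == "male"); xc <- as.numeric(xc == "male")
      cv <- paste0(cv, "_male")
    }
    s <- smd(xt, xc)
    tibble::tibble(covariate = cv, mean_treated = mean(xt),
                   mean_control = mean(xc), smd = s$smd, zero_sd = s$zero_sd)
  })
  post <- if (nrow(matched$pairs) >= 2)
    balance_diagnostics(matched, sub, covs) else NULL
  list(model = model, matched = matched,
       balance_pre = pre, balance_post = post)
}

#' Plot population trajectory curves
#'
#' Mean percent-change curves per response category with a +/- 1 SEM
#' ribbon, in the style of the first-year trajectory figure. Requires
#' ggplot2.
#'
#' @param curves tibble from [run_pipeline()] (`curves` element) with
#'   columns `category`, `t_days`, `mean_pct`, `sem`, `smoothed_pct`.
#' @return A ggplot object.
#' @export
plot_trajectory_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = t_days, y = smoothed_pct,
                               colour = category, fill = category)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = smoothed_pct - sem,
                                      ymax = smoothed_pct + sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Days from first GLP-1RA prescription",
                  y = "Weight change (% of baseline)",
                  colour = "Response", fill = "Response") +
    ggplot2::theme_minimal()
}
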