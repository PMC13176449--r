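#' De-identification export transform
#'
#' Applies the standard privacy-preserving export transforms to a set of EHR
#' tables: every event date of a patient is shifted backward by one
#' patient-specific uniform offset in 1..31 days (the same offset for all of
#' that patient's events, so all within-patient intervals are preserved
#' exactly), and extreme quasi-identifying values are thresholded — exported
#' age labels are censored at "89+" and exported BMI labels at "40+". The
#' numeric columns used internally by the analysis are left untouched; the
#' censored values are added as export-only label columns on the patients
#' table.
#'
#' @param tables an `ehr_tables` list (see [generate_population()]); only the
#'   four input tables are transformed, any truth sidecar is dropped from the
#'   export.
#' @param seed integer seed for the per-patient offsets.
#' @return An `ehr_tables` list with shifted dates and label columns
#'   `age_label` and `bmi_label` on `patients`.
#' @export
apply_deid_export <- function(tables, seed = 1L) {
  stopifnot(inherits(tables, "ehr_tables") || is.list(tables))
  set.seed(as.integer(seed))
  ids <- tables$patients$patient_id
  offset <- tibble::tibble(patient_id = ids,
                           .offset = sample.int(31L, length(ids), replace = TRUE))
  shift <- function(df) {
    if (is.null(df) || !"date" %in% names(df)) return(df)
    df |>
      dplyr::left_join(offset, by = "patient_id") |>
      dplyr::mutate(date = date - .offset) |>
      dplyr::select(-.offset)
  }
  out <- tables
  out$prescriptions <- shift(tables$prescriptions)
  out$weights <- shift(tables$weights)
  out$phenotypes <- shift(tables$phenotypes)
  out$truth <- NULL
  out$truth_diseases <- NULL

  last_event <- dplyr::bind_rows(
    out$prescriptions[c("patient_id", "date")],
    out$weights[c("patient_id", "date")]
  ) |>
    dplyr::summarise(last_date = max(date), .by = patient_id)
  med_weight <- out$weights |>
    dplyr::summarise(w = stats::median(weight), .by = patient_id)
  pat <- tables$patients |>
    dplyr::left_join(last_event, by = "patient_id") |>
    dplyr::left_join(med_weight, by = "patient_id") |>
    dplyr::mutate(
      .age = floor(as.numeric(last_date - birth_date) / 365.25),
      age_label = dplyr::if_else(.age >= 89, "89+", as.character(.age)),
      .bmi = w / (height_cm / 100)^2,
      bmi_label = dplyr::if_else(.bmi > 40, "40+",
                                 formatC(.bmi, digits = 1, format = "f"))
    ) |>
    dplyr::select(-last_date, -w, -.age, -.bmi)
  out$patients <- pat
  out
}

#' Write / read the four pipeline input tables as CSV
#'
#' `write_ehr_tables()` writes `patients.csv`, `prescriptions.csv`,
#' `weights.csv` and `phenotypes.csv` (ISO-8601 dates) into a directory,
#' plus, when present, the ground-truth sidecar as `truth.json` so the latent
#' labels stay physically separate from the pipeline inputs.
#' `read_ehr_tables()` reads them back with schema validation.
#'
#' @param tables an `ehr_tables` list.
#' @param dir output / input directory.
#' @return `write_ehr_tables()` returns `dir` invisibly; `read_ehr_tables()`
#'   returns an `ehr_tables` list (without truth, which is never read back
#'   into the pipeline).
#' @export
write_ehr_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(tables$patients, file.path(dir, "patients.csv"))
  readr::write_csv(tables$prescriptions, file.path(dir, "prescriptions.csv"))
  readr::write_csv(tables$weights, file.path(dir, "weights.csv"))
  readr::write_csv(tables$phenotypes, file.path(dir, "phenotypes.csv"))
  if (!is.null(tables$truth)) {
    truth <- list(patients = tables$truth,
                  diseases = tables$truth_diseases)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         dataframe = "columns", Date = "ISO8601")
  }
  invisible(dir)
}

#' @rdname write_ehr_tables
#' @export
read_ehr_tables <- function(dir) {
  need <- c("patients.csv", "prescriptions.csv", "weights.csv", "phenotypes.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing input table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  pat <- readr::read_csv(file.path(dir, "patients.csv"),
                         show_col_types = FALSE)
  rx <- readr::read_csv(file.path(dir, "prescriptions.csv"),
                        show_col_types = FALSE)
  wt <- readr::read_csv(file.path(dir, "weights.csv"), show_col_types = FALSE)
  ph <- readr::read_csv(file.path(dir, "phenotypes.csv"),
                        show_col_types = FALSE)
  check_schema(pat, c("patient_id", "birth_date", "gender", "race",
                      "bariatric_history"), "patients.csv")
  check_schema(rx, c("patient_id", "date", "ingredient", "brand"),
               "prescriptions.csv")
  check_schema(wt, c("patient_id", "date", "weight"), "weights.csv")
  check_schema(ph, c("patient_id", "date", "concept", "source", "subject",
                     "temporality", "certainty"), "phenotypes.csv")
  structure(list(patients = pat, prescriptions = rx, weights = wt,
                 phenotypes = ph), class = "ehr_tables")
}

check_schema <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s",
                 file, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}
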