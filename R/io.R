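# Three-table CSV interchange format shared by every pipeline stage.
# All event times are hours relative to ICU admission (t = 0); negative
# times are pre-ICU (e.g. emergency department) events. One row per ICU
# stay; booleans encoded 0/1; missing numerics as empty cells.

.patient_numeric <- c("age", "height_cm", "weight_kg", "severity_score",
                      "comorbidity_score", "death_or_discharge_time_h")
.patient_bool <- c("sepsis", "bleeding_dx", "rrt", "received_blood_products",
                   "excess_other_output", "reliable_fluid_data",
                   "died_in_hospital")

.patient_cols <- c("patient_id", "age", "sex", "height_cm", "weight_kg",
                   "sepsis", "bleeding_dx", "rrt", "received_blood_products",
                   "excess_other_output", "reliable_fluid_data",
                   "severity_score", "comorbidity_score", "died_in_hospital",
                   "death_or_discharge_time_h")
.hct_cols <- c("patient_id", "time_h", "hct_pct")
.fluid_cols <- c("patient_id", "time_h", "volume_ml", "direction")
.directions <- c("intake", "urine_output", "other_output")

.read_table <- function(path, cols) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  unknown <- setdiff(names(df), cols)
  if (length(unknown))
    stop(basename(path), ": unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(basename(path), ": missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df[, cols, drop = FALSE]
}

.parse_num <- function(x, col, path) {
  x[!nzchar(x)] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(basename(path), ": column '", col,
         "' has unparseable numeric values at data row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  out
}

.parse_bool <- function(x, col, path) {
  x[!nzchar(x)] <- NA_character_
  map <- c("0" = 0L, "1" = 1L, "TRUE" = 1L, "FALSE" = 0L,
           "true" = 1L, "false" = 0L)
  out <- unname(map[x])
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(basename(path), ": column '", col,
         "' must be 0/1; bad values at data row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  out
}

#' Read a three-table ICU dataset
#'
#' Reads and validates the CSV interchange format: a patients table (one row
#' per ICU stay with demographics, exclusion flags, severity/comorbidity
#' scores and outcomes), a hematocrit table and a fluid-event table, all
#' keyed by `patient_id` on an ICU-admission-relative clock in hours.
#'
#' Validation is fatal for structural problems: missing files, unknown or
#' missing columns, unparseable numerics (reported with row indices),
#' duplicate patient ids, events referencing unknown patients, hematocrit
#' values outside the open interval (0, 100), negative volumes, and
#' directions outside `intake` / `urine_output` / `other_output`.
#' Implausible demographics (e.g. non-positive height) are *not* rejected
#' here; the cohort exclusion cascade counts and removes them.
#'
#' @param patients_path,hct_path,fluids_path paths to the three CSV files.
#' @return an object of class `vli_dataset`: a list with data frames
#'   `patients`, `hct`, `fluids`.
#' @seealso [write_dataset()], [derive_features()], [select_cohorts()]
#' @export
read_dataset <- function(patients_path, hct_path, fluids_path) {
  p <- .read_table(patients_path, .patient_cols)
  for (col in .patient_numeric) p[[col]] <- .parse_num(p[[col]], col, patients_path)
  for (col in .patient_bool) p[[col]] <- .parse_bool(p[[col]], col, patients_path)

  h <- .read_table(hct_path, .hct_cols)
  h$time_h <- .parse_num(h$time_h, "time_h", hct_path)
  h$hct_pct <- .parse_num(h$hct_pct, "hct_pct", hct_path)

  f <- .read_table(fluids_path, .fluid_cols)
  f$time_h <- .parse_num(f$time_h, "time_h", fluids_path)
  f$volume_ml <- .parse_num(f$volume_ml, "volume_ml", fluids_path)

  validate_dataset(new_dataset(p, h, f))
}

#' Construct a `vli_dataset` from in-memory tables
#'
#' @param patients,hct,fluids data frames in the documented column layout.
#' @return a `vli_dataset` (unvalidated; see [validate_dataset()]).
#' @export
new_dataset <- function(patients, hct, fluids) {
  structure(list(patients = patients, hct = hct, fluids = fluids),
            class = "vli_dataset")
}

#' Validate a `vli_dataset` against the typed invariants
#'
#' @param dataset a `vli_dataset`.
#' @return the dataset, invisibly unchanged, or an error describing every
#'   violated invariant class with offending rows/ids.
#' @export
validate_dataset <- function(dataset) {
  p <- dataset$patients; h <- dataset$hct; f <- dataset$fluids
  probs <- character()

  dup <- unique(p$patient_id[duplicated(p$patient_id)])
  if (length(dup))
    probs <- c(probs, paste0("duplicate patient_id: ",
                             paste(utils::head(dup, 10), collapse = ", ")))
  bad_sex <- which(!p$sex %in% c("male", "female"))
  if (length(bad_sex))
    probs <- c(probs, paste0("patients: sex must be male/female at row(s) ",
                             paste(utils::head(bad_sex, 10), collapse = ", ")))
  bad_age <- which(!is.na(p$age) & (p$age < 0 | !is.finite(p$age)))
  if (length(bad_age))
    probs <- c(probs, paste0("patients: negative/non-finite age at row(s) ",
                             paste(utils::head(bad_age, 10), collapse = ", ")))

  bad_hct <- which(is.na(h$hct_pct) | h$hct_pct <= 0 | h$hct_pct >= 100)
  if (length(bad_hct))
    probs <- c(probs, paste0("hct: hct_pct must lie strictly in (0, 100) at row(s) ",
                             paste(utils::head(bad_hct, 10), collapse = ", ")))
  bad_t <- which(!is.finite(h$time_h))
  if (length(bad_t))
    probs <- c(probs, paste0("hct: non-finite time_h at row(s) ",
                             paste(utils::head(bad_t, 10), collapse = ", ")))

  bad_v <- which(is.na(f$volume_ml) | f$volume_ml < 0)
  if (length(bad_v))
    probs <- c(probs, paste0("fluids: volume_ml must be >= 0 at row(s) ",
                             paste(utils::head(bad_v, 10), collapse = ", ")))
  bad_d <- which(!f$direction %in% .directions)
  if (length(bad_d))
    probs <- c(probs, paste0("fluids: unknown direction at row(s) ",
                             paste(utils::head(bad_d, 10), collapse = ", ")))
  bad_ft <- which(!is.finite(f$time_h))
  if (length(bad_ft))
    probs <- c(probs, paste0("fluids: non-finite time_h at row(s) ",
                             paste(utils::head(bad_ft, 10), collapse = ", ")))

  orphans <- unique(c(setdiff(h$patient_id, p$patient_id),
                      setdiff(f$patient_id, p$patient_id)))
  if (length(orphans))
    probs <- c(probs, paste0("events reference unknown patient_id(s): ",
                             paste(utils::head(orphans, 10), collapse = ", ")))

  if (length(probs))
    stop("dataset validation failed:\n  ",
         paste(probs, collapse = "\n  "), call. = FALSE)
  invisible(dataset)
}

#' @export
print.vli_dataset <- function(x, ...) {
  cat("<vli_dataset> ", nrow(x$patients), " patients, ",
      nrow(x$hct), " hematocrit measurements, ",
      nrow(x$fluids), " fluid events\n", sep = "")
  invisible(x)
}

# Full-precision numeric formatting so read(write(x)) round-trips doubles.
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

.write_mixed_csv <- function(df, path, numeric_cols, integer_cols = character()) {
  out <- df
  for (col in numeric_cols) out[[col]] <- .fmt_num(df[[col]])
  for (col in integer_cols) {
    v <- df[[col]]
    out[[col]] <- ifelse(is.na(v), "", as.character(as.integer(v)))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a `vli_dataset` to the three-CSV interchange format
#'
#' @param dataset a `vli_dataset`.
#' @param dir output directory (created if absent).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             hct = file.path(dir, "hct.csv"),
             fluids = file.path(dir, "fluids.csv"))
  .write_mixed_csv(dataset$patients, paths["patients"],
                   numeric_cols = .patient_numeric,
                   integer_cols = .patient_bool)
  .write_mixed_csv(dataset$hct, paths["hct"],
                   numeric_cols = c("time_h", "hct_pct"))
  .write_mixed_csv(dataset$fluids, paths["fluids"],
                   numeric_cols = c("time_h", "volume_ml"))
  invisible(paths)
}

#' Write analysis-ready cohort rows to CSV
#'
#' One row per patient with every derived quantity (hematocrits, net
#' balance, BSA, VLI, quartile) plus covariates and outcomes, in a stable
#' column order and at full float precision so that [read_cohort()] returns
#' bit-identical values.
#'
#' @param rows a cohort-row data frame from [build_cohort_rows()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0)
    stop("cannot write an empty cohort", call. = FALSE)
  num <- names(rows)[vapply(rows, is.numeric, logical(1))]
  out <- rows
  for (col in num) out[[col]] <- .fmt_num(as.numeric(rows[[col]]))
  for (col in names(out)) {
    if (is.logical(rows[[col]])) out[[col]] <- as.integer(rows[[col]])
    if (is.factor(rows[[col]])) out[[col]] <- as.character(rows[[col]])
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("failed to write cohort to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#' @param path CSV path.
#' @return data frame with numerics restored at full precision.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  char_cols <- c("patient_id", "sex", "vli_quartile")
  for (col in setdiff(names(df), char_cols))
    df[[col]] <- .parse_num(df[[col]], col, path)
  if ("vli_quartile" %in% names(df))
    df$vli_quartile <- factor(df$vli_quartile, levels = paste0("Q", 1:4))
  if ("vli_imputed" %in% names(df)) df$vli_imputed <- df$vli_imputed == 1
  for (col in intersect(c("died_in_hospital"), names(df)))
    df[[col]] <- as.integer(df[[col]])
  df
}
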