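# Cohort construction: the inclusion/exclusion cascade with attrition
# accounting. Sepsis is the inclusion criterion; exclusions apply in a
# fixed order with first-match-wins attribution, so per-filter removal
# counts are additive and sum to (initial - final).

.death_filters <- function(df) list(
  bleeding_or_blood_products =
    df$bleeding_dx == 1 | df$received_blood_products == 1,
  excess_other_output = df$excess_other_output == 1,
  rrt = df$rrt == 1,
  erroneous_demographics =
    (!is.na(df$age) & df$age < 16) |
    (!is.na(df$height_cm) & (df$height_cm <= 100 | df$height_cm >= 250)) |
    (!is.na(df$weight_kg) & (df$weight_kg <= 20 | df$weight_kg >= 350)),
  unreliable_fluid_data = df$reliable_fluid_data == 0,
  missing_vli_data =
    is.na(df$hct_initial) | is.na(df$hct_final) |
    is.na(df$height_cm) | is.na(df$weight_kg) | is.na(df$bsa_m2) |
    is.na(df$net_balance_ml),
  nonpositive_balance =
    !is.na(df$net_balance_ml) & df$net_balance_ml <= 0
)

.fluid_filters <- function(df) list(
  death_before_84h =
    df$died_in_hospital == 1 &
    !is.na(df$death_or_discharge_time_h) &
    df$death_or_discharge_time_h < 84,
  missing_outcome_balance = is.na(df$outcome_balance_ml)
)

.run_cascade <- function(df, filters_fn) {
  remaining <- df
  rows <- list()
  for (nm in names(filters_fn(df))) {
    hit <- filters_fn(remaining)[[nm]]
    hit[is.na(hit)] <- FALSE
    rows[[nm]] <- data.frame(filter = nm,
                             n_removed = sum(hit),
                             n_remaining = nrow(remaining) - sum(hit),
                             stringsAsFactors = FALSE)
    remaining <- remaining[!hit, , drop = FALSE]
  }
  att <- do.call(rbind, rows)
  rownames(att) <- NULL
  class(att) <- c("vli_attrition", "data.frame")
  list(ids = remaining$patient_id, attrition = att)
}

#' Select the in-hospital-death analysis cohort
#'
#' Keeps sepsis patients and removes, in this fixed order with
#' first-match-wins counting: (1) bleeding diagnosis or blood products,
#' (2) excess other fluid output, (3) renal replacement therapy,
#' (4) erroneous demographics (age < 16, height outside (100, 250) cm or
#' weight outside (20, 350) kg), (5) unreliable fluid data, (6) any missing
#' VLI ingredient (initial/final hematocrit, height, weight, BSA, fluid
#' balance), (7) non-positive net fluid balance (strictly positive balance
#' required). Non-sepsis patients never appear in any attrition row.
#'
#' @param dataset a `vli_dataset`.
#' @param features per-patient feature table from [derive_features()].
#' @return list with `ids` (character vector of retained patients) and
#'   `attrition` (a `vli_attrition` data frame: filter, n_removed,
#'   n_remaining), plus `n_sepsis`, the inclusion count.
#' @export
select_death_cohort <- function(dataset, features) {
  df <- merge(dataset$patients, features, by = "patient_id", sort = FALSE)
  df <- df[df$sepsis == 1, , drop = FALSE]
  res <- .run_cascade(df, .death_filters)
  if (length(res$ids) == 0)
    warning("death cohort is empty after exclusions", call. = FALSE)
  res$n_sepsis <- nrow(df)
  res
}

#' Select the 36-84 h fluid-balance cohort from the death cohort
#'
#' Removes (a) patients who died in hospital strictly before 84 h (a death
#' at exactly 84.0 h is retained) and (b) patients whose 36-84 h fluid
#' balance is missing (no intake or urine events in the window).
#'
#' @param death_ids patient ids retained by [select_death_cohort()].
#' @inheritParams select_death_cohort
#' @return list with `ids` and `attrition` as in [select_death_cohort()].
#' @export
select_fluid_cohort <- function(death_ids, dataset, features) {
  df <- merge(dataset$patients, features, by = "patient_id", sort = FALSE)
  df <- df[df$patient_id %in% death_ids, , drop = FALSE]
  res <- .run_cascade(df, .fluid_filters)
  if (length(res$ids) == 0 && length(death_ids) > 0)
    warning("fluid-balance cohort is empty after exclusions", call. = FALSE)
  res
}

#' Build both analysis cohorts with attrition tables
#'
#' @inheritParams select_death_cohort
#' @param config a [run_config()] (passed to feature derivation when
#'   `features` is `NULL`).
#' @param features optional precomputed [derive_features()] table.
#' @return object of class `vli_cohorts`: `death_ids`, `fluid_ids`,
#'   `attrition_death`, `attrition_fluid`, `n_sepsis`.
#' @export
select_cohorts <- function(dataset, config = run_config(), features = NULL) {
  if (is.null(features)) features <- derive_features(dataset, config)
  d <- select_death_cohort(dataset, features)
  f <- select_fluid_cohort(d$ids, dataset, features)
  structure(list(death_ids = d$ids, fluid_ids = f$ids,
                 attrition_death = d$attrition, attrition_fluid = f$attrition,
                 n_sepsis = d$n_sepsis),
            class = "vli_cohorts")
}

#' @export
print.vli_attrition <- function(x, ...) {
  cat("Attrition (first matching filter wins):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-28s removed %6d  remaining %6d\n",
                x$filter[i], x$n_removed[i], x$n_remaining[i]))
  invisible(x)
}

#' @export
print.vli_cohorts <- function(x, ...) {
  cat("<vli_cohorts> sepsis patients:", x$n_sepsis, "\n")
  cat("In-hospital-death cohort:", length(x$death_ids), "\n")
  print(x$attrition_death)
  cat("36-84 h fluid-balance cohort:", length(x$fluid_ids), "\n")
  print(x$attrition_fluid)
  invisible(x)
}

#' Write an attrition table to CSV
#' @param attrition a `vli_attrition`.
#' @param path output path.
#' @export
write_attrition <- function(attrition, path) {
  utils::write.csv(as.data.frame(attrition), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
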