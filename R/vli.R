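# The vascular leak index and its distributional post-processing.
#
#   VLI = ((Hct_final - Hct_initial) / net fluid balance) * BSA * 1000
#
# with hematocrit in percent points, balance in ml (strictly positive by
# cohort construction) and BSA in m^2; the factor 1000 puts the index on
# an interpretable unit scale. Negative values mean the hematocrit fell
# as fluid accumulated (fluid retained intravascularly, hemodilution);
# values near zero or positive mean administered fluid left the
# vasculature — more leak.

#' Compute the vascular leak index
#'
#' @param hct_initial,hct_final hematocrit in percent, each in (0, 100).
#' @param net_balance_ml net fluid balance in ml; must be strictly
#'   positive (the cohort cascade removes non-positive balances).
#' @param bsa_m2 body surface area in m^2 (> 0).
#' @return the dimensionless index (vectorized).
#' @export
#' @examples
#' compute_vli(36, 30, 3000, 1.9)  # -3.8
compute_vli <- function(hct_initial, hct_final, net_balance_ml, bsa_m2) {
  if (any(!is.finite(net_balance_ml) | net_balance_ml <= 0))
    stop("net_balance_ml must be strictly positive; ",
         "non-positive balances must be excluded upstream", call. = FALSE)
  if (any(hct_initial <= 0 | hct_initial >= 100 |
          hct_final <= 0 | hct_final >= 100, na.rm = TRUE))
    stop("hematocrit values must lie strictly in (0, 100)", call. = FALSE)
  if (any(!is.finite(bsa_m2) | bsa_m2 <= 0))
    stop("bsa_m2 must be positive", call. = FALSE)
  ((hct_final - hct_initial) / net_balance_ml) * bsa_m2 * 1000
}

#' Median-impute the distribution tails of the index
#'
#' Values strictly below the 5th or strictly above the 95th empirical
#' percentile (linear-interpolation quantiles, R type 7) are replaced by
#' the median of the original vector; boundary-equal values are retained.
#' This guards the index against the gross fluid-charting errors that
#' dominate its extreme tails. With fewer than 20 values both tails may be
#' empty at 5%, so the vector is returned unimputed with a warning.
#'
#' @param x numeric vector of index values.
#' @param tail tail mass on each side, default 0.05.
#' @return list: `values` (imputed vector), `imputed` (logical mask),
#'   `bounds` (the two percentile cut points), `median`.
#' @export
impute_tails <- function(x, tail = 0.05) {
  stopifnot(is.numeric(x), tail >= 0, tail <= 0.25)
  if (length(x) < 20) {
    warning("fewer than 20 values; tail imputation skipped", call. = FALSE)
    return(list(values = x, imputed = rep(FALSE, length(x)),
                bounds = c(NA_real_, NA_real_),
                median = stats::median(x)))
  }
  q <- stats::quantile(x, c(tail, 1 - tail), type = 7, names = FALSE)
  m <- stats::median(x)
  mask <- x < q[1] | x > q[2]
  x[mask] <- m
  list(values = x, imputed = mask, bounds = q, median = m)
}

#' Assign VLI quartile labels
#'
#' Cuts at the 25th/50th/75th linear-interpolation percentiles of the
#' (already imputed) vector; intervals are right-closed, so a value equal
#' to a cut point falls in the lower quartile. Q1 holds the lowest
#' (most negative) indices, Q4 the highest — the most-leak group.
#'
#' @param x numeric vector.
#' @return factor with levels `Q1`-`Q4`, same length as `x`.
#' @export
assign_quartiles <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  idx <- 1L + (x > q[1]) + (x > q[2]) + (x > q[3])
  factor(paste0("Q", idx), levels = paste0("Q", 1:4))
}

#' Assemble analysis-ready cohort rows
#'
#' Joins patient covariates with derived features for the selected cohort,
#' computes the index, applies tail imputation *within this cohort* (the
#' two analysis populations are post-processed separately), and assigns
#' quartiles on the imputed values.
#'
#' @param dataset a `vli_dataset`.
#' @param features [derive_features()] output.
#' @param ids patient ids of the selected cohort.
#' @param config a [run_config()] (tail fraction).
#' @return data frame, one row per patient: identifiers, ingredients
#'   (`hct_initial`, `hct_final`, `net_balance_ml`, `bsa_m2`), `vli_raw`,
#'   `vli` (post-imputation), `vli_imputed`, `vli_quartile`, covariates
#'   (`age`, `sex`, `severity_score`, `comorbidity_score`) and outcomes
#'   (`died_in_hospital`, `death_or_discharge_time_h`,
#'   `outcome_balance_ml`).
#' @export
build_cohort_rows <- function(dataset, features, ids, config = run_config()) {
  df <- merge(dataset$patients, features, by = "patient_id", sort = FALSE)
  df <- df[match(ids, df$patient_id), , drop = FALSE]
  if (nrow(df) == 0) stop("empty cohort: no rows to build", call. = FALSE)

  vli_raw <- compute_vli(df$hct_initial, df$hct_final,
                         df$net_balance_ml, df$bsa_m2)
  imp <- impute_tails(vli_raw, config$tail_fraction)

  data.frame(patient_id = df$patient_id,
             hct_initial = df$hct_initial,
             hct_final = df$hct_final,
             net_balance_ml = df$net_balance_ml,
             bsa_m2 = df$bsa_m2,
             vli_raw = vli_raw,
             vli = imp$values,
             vli_imputed = imp$imputed,
             vli_quartile = assign_quartiles(imp$values),
             age = df$age,
             sex = df$sex,
             severity_score = df$severity_score,
             comorbidity_score = df$comorbidity_score,
             died_in_hospital = df$died_in_hospital,
             death_or_discharge_time_h = df$death_or_discharge_time_h,
             outcome_balance_ml = df$outcome_balance_ml,
             stringsAsFactors = FALSE)
}
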