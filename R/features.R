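# Time-windowed derived quantities feeding the leak index.
#
# Window conventions (hours from ICU admission):
#   initial hematocrit  [-12, 18]  closed    — earliest measurement wins
#   final hematocrit    (18, 36]   half-open — mean of all measurements
#   net fluid balance   [-6, 36]   closed    — intake minus urine output
#   outcome balance     (36, 84]   half-open — intake minus urine output
# The half-open conventions guarantee a t = 18 measurement and a t = 36
# fluid event each contribute to exactly one window.

#' Body surface area
#'
#' Du Bois (default): 0.007184 * kg^0.425 * cm^0.725. Mosteller:
#' sqrt(cm * kg / 3600). Vectorized; both in m^2.
#'
#' @param height_cm height in centimetres (> 0).
#' @param weight_kg weight in kilograms (> 0).
#' @param formula `"dubois"` or `"mosteller"`.
#' @return BSA in m^2.
#' @export
#' @examples
#' compute_bsa(170, 70)            # 1.810 m^2
#' compute_bsa(170, 70, "mosteller")
compute_bsa <- function(height_cm, weight_kg, formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  if (any(!is.finite(height_cm) | height_cm <= 0) ||
      any(!is.finite(weight_kg) | weight_kg <= 0))
    stop("height_cm and weight_kg must be positive and finite", call. = FALSE)
  switch(formula,
         dubois = 0.007184 * weight_kg^0.425 * height_cm^0.725,
         mosteller = sqrt(height_cm * weight_kg / 3600))
}

#' Initial hematocrit: earliest measurement in a closed window
#'
#' The first hematocrit measured between 12 h before and 18 h after ICU
#' admission (both endpoints included) is taken as the initial value.
#' Multiple measurements sharing the identical earliest timestamp are
#' averaged (deterministic tie-break).
#'
#' @param time_h,hct_pct parallel vectors of measurement times (h) and
#'   values (%).
#' @param window length-2 numeric, closed interval; default `c(-12, 18)`.
#' @return the initial hematocrit, or `NA_real_` if no measurement falls in
#'   the window.
#' @export
extract_initial_hct <- function(time_h, hct_pct, window = c(-12, 18)) {
  keep <- time_h >= window[1] & time_h <= window[2]
  if (!any(keep)) return(NA_real_)
  t0 <- min(time_h[keep])
  mean(hct_pct[keep & time_h == t0])
}

#' Final hematocrit: mean over a half-open window
#'
#' Arithmetic mean of all hematocrit values measured in `(18, 36]` hours
#' (left endpoint excluded — a t = 18 measurement belongs to the initial
#' window).
#'
#' @inheritParams extract_initial_hct
#' @param window length-2 numeric, half-open `(lo, hi]`; default `c(18, 36)`.
#' @return mean hematocrit (%), or `NA_real_` if the window is empty.
#' @export
extract_final_hct <- function(time_h, hct_pct, window = c(18, 36)) {
  keep <- time_h > window[1] & time_h <= window[2]
  if (!any(keep)) return(NA_real_)
  mean(hct_pct[keep])
}

#' Net fluid balance over the resuscitation window
#'
#' Total intake minus total urine output over the closed window from 6 h
#' before ICU admission through 36 h. `other_output` events are ignored in
#' the balance (they only drive an exclusion flag upstream). No events in
#' the window yields 0 ml (such patients are removed downstream by the
#' positive-balance rule).
#'
#' @param fluids data frame with `time_h`, `volume_ml`, `direction`.
#' @param window length-2 numeric, closed interval; default `c(-6, 36)`.
#' @return net balance in ml.
#' @export
compute_net_balance <- function(fluids, window = c(-6, 36)) {
  keep <- fluids$time_h >= window[1] & fluids$time_h <= window[2]
  sum(fluids$volume_ml[keep & fluids$direction == "intake"]) -
    sum(fluids$volume_ml[keep & fluids$direction == "urine_output"])
}

#' Post-resuscitation (outcome) fluid balance
#'
#' Intake minus urine output over `(36, 84]` hours. Returns `NA_real_` when
#' the window contains neither intake nor urine events, marking the outcome
#' as missing; a t = 36 event belongs to the first balance window.
#'
#' @inheritParams compute_net_balance
#' @param window length-2 numeric, half-open `(lo, hi]`; default `c(36, 84)`.
#' @return balance in ml or `NA_real_`.
#' @export
compute_outcome_balance <- function(fluids, window = c(36, 84)) {
  keep <- fluids$time_h > window[1] & fluids$time_h <= window[2] &
    fluids$direction %in% c("intake", "urine_output")
  if (!any(keep)) return(NA_real_)
  sum(fluids$volume_ml[keep & fluids$direction == "intake"]) -
    sum(fluids$volume_ml[keep & fluids$direction == "urine_output"])
}

#' Derive per-patient features for the whole dataset
#'
#' Applies the four windowed extractors and the BSA formula to every
#' patient, returning one row per patient in the patients-table order.
#' BSA is `NA` (not an error) when height or weight is missing or
#' non-positive; the cohort cascade accounts for those patients.
#'
#' @param dataset a `vli_dataset`.
#' @param config a [run_config()] list (windows and BSA formula).
#' @return data frame: `patient_id`, `hct_initial`, `hct_final`,
#'   `net_balance_ml`, `outcome_balance_ml`, `bsa_m2`.
#' @export
derive_features <- function(dataset, config = run_config()) {
  p <- dataset$patients
  ids <- p$patient_id
  w <- config$windows
  hct_by <- split(dataset$hct, factor(dataset$hct$patient_id, levels = ids))
  fl_by <- split(dataset$fluids, factor(dataset$fluids$patient_id, levels = ids))

  hct_initial <- vapply(hct_by, function(h)
    extract_initial_hct(h$time_h, h$hct_pct, w$initial_hct), numeric(1))
  hct_final <- vapply(hct_by, function(h)
    extract_final_hct(h$time_h, h$hct_pct, w$final_hct), numeric(1))
  net_balance <- vapply(fl_by, function(f)
    compute_net_balance(f, w$net_balance), numeric(1))
  outcome_balance <- vapply(fl_by, function(f)
    compute_outcome_balance(f, w$outcome_balance), numeric(1))

  ok <- is.finite(p$height_cm) & p$height_cm > 0 &
    is.finite(p$weight_kg) & p$weight_kg > 0
  bsa <- rep(NA_real_, length(ids))
  if (any(ok))
    bsa[ok] <- compute_bsa(p$height_cm[ok], p$weight_kg[ok], config$bsa_formula)

  data.frame(patient_id = ids,
             hct_initial = unname(hct_initial),
             hct_final = unname(hct_final),
             net_balance_ml = unname(net_balance),
             outcome_balance_ml = unname(outcome_balance),
             bsa_m2 = bsa,
             stringsAsFactors = FALSE)
}
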