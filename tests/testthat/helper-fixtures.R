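# Fixtures built in code: a tiny well-formed dataset and a hand-enumerated
# ten-patient cohort-cascade fixture.

make_patient_row <- function(patient_id, age = 60, sex = "male",
                             height_cm = 170, weight_kg = 70, sepsis = 1,
                             bleeding_dx = 0, rrt = 0,
                             received_blood_products = 0,
                             excess_other_output = 0, reliable_fluid_data = 1,
                             severity_score = 50, comorbidity_score = 3,
                             died_in_hospital = 0,
                             death_or_discharge_time_h = 200) {
  data.frame(patient_id = patient_id, age = age, sex = sex,
             height_cm = height_cm, weight_kg = weight_kg, sepsis = sepsis,
             bleeding_dx = bleeding_dx, rrt = rrt,
             received_blood_products = received_blood_products,
             excess_other_output = excess_other_output,
             reliable_fluid_data = reliable_fluid_data,
             severity_score = severity_score,
             comorbidity_score = comorbidity_score,
             died_in_hospital = died_in_hospital,
             death_or_discharge_time_h = death_or_discharge_time_h,
             stringsAsFactors = FALSE)
}

make_toy_dataset <- function() {
  patients <- rbind(make_patient_row("A"), make_patient_row("B", sex = "female"))
  hct <- data.frame(
    patient_id = c("A", "A", "A", "B", "B", "B"),
    time_h = c(0, 24, 30, -3, 20, 36),
    hct_pct = c(36, 31, 33, 40, 35, 34))
  fluids <- data.frame(
    patient_id = c("A", "A", "A", "A", "B", "B", "B", "B"),
    time_h = c(1, 10, 40, 50, 2, 12, 45, 60),
    volume_ml = c(3000, 1000, 1500, 600, 2500, 800, 1200, 500),
    direction = c("intake", "urine_output", "intake", "urine_output",
                  "intake", "urine_output", "intake", "urine_output"),
    stringsAsFactors = FALSE)
  new_dataset(patients, hct, fluids)
}

write_toy_csvs <- function(ds, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_dataset(ds, dir)
  dir
}

# Hand-enumerated cascade fixture: 10 sepsis patients, pre-computed ledger.
#   P01, P02  rrt = 1                      -> removed at 'rrt' (2)
#   P03       age 15                       -> removed at 'erroneous_demographics' (1)
#   P04       no hct in [-12, 18]          -> removed at 'missing_vli_data' (1)
#   P05       net balance -400 ml          -> removed at 'nonpositive_balance' (1)
#   P06..P10  clean, positive balance      -> death cohort of 5
#   P06 died at 60 h                       -> removed from fluid cohort (death_before_84h)
#   P07 no fluid events in (36, 84]        -> removed from fluid cohort (missing outcome)
#   fluid cohort: P08, P09, P10
make_cascade_fixture <- function() {
  ids <- sprintf("P%02d", 1:10)
  patients <- do.call(rbind, lapply(ids, function(id) make_patient_row(id)))
  patients$rrt[patients$patient_id %in% c("P01", "P02")] <- 1
  patients$age[patients$patient_id == "P03"] <- 15
  patients$died_in_hospital[patients$patient_id == "P06"] <- 1
  patients$death_or_discharge_time_h[patients$patient_id == "P06"] <- 60

  hct <- do.call(rbind, lapply(ids, function(id) {
    tt <- if (id == "P04") c(20, 30) else c(0, 24, 30)
    vv <- if (id == "P04") c(31, 33) else c(36, 31, 33)
    data.frame(patient_id = id, time_h = tt, hct_pct = vv,
               stringsAsFactors = FALSE)
  }))

  fluids <- do.call(rbind, lapply(ids, function(id) {
    if (id == "P05") {
      data.frame(patient_id = id, time_h = c(1, 5),
                 volume_ml = c(500, 900),
                 direction = c("intake", "urine_output"),
                 stringsAsFactors = FALSE)
    } else if (id == "P07") {
      data.frame(patient_id = id, time_h = c(2, 10),
                 volume_ml = c(3000, 1000),
                 direction = c("intake", "urine_output"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = id, time_h = c(2, 10, 40, 50),
                 volume_ml = c(3000, 1000, 1500, 600),
                 direction = c("intake", "urine_output", "intake",
                               "urine_output"),
                 stringsAsFactors = FALSE)
    }
  }))
  new_dataset(patients, hct, fluids)
}

# Synthetic cohort rows drawn directly from the outcome-model layer, for
# model-level tests: left-skewed index, covariates, and outcomes whose
# dependence on the index is controlled by the caller.
make_model_rows <- function(n, beta_vli = 0, beta_sev = 0.5,
                            balance_slope = 0, balance_sd = 1500,
                            intercept = -1.8, balance_intercept = 800) {
  vli <- 1.5 - stats::rgamma(n, shape = 2.5, scale = 1.8)
  sev <- stats::rnorm(n, 70, 25)
  age <- stats::rnorm(n, 65, 15)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  z_sev <- (sev - 70) / 25
  p <- stats::plogis(intercept + beta_vli * vli + beta_sev * z_sev)
  died <- stats::rbinom(n, 1, p)
  bal <- balance_intercept + balance_slope * vli + beta_sev * 200 * z_sev +
    stats::rnorm(n, 0, balance_sd)
  data.frame(patient_id = sprintf("S%05d", seq_len(n)), vli = vli,
             vli_quartile = assign_quartiles(vli), age = age, sex = sex,
             severity_score = sev, comorbidity_score = NA_real_,
             died_in_hospital = died, outcome_balance_ml = bal,
             stringsAsFactors = FALSE)
}

# Full pipeline on an in-memory dataset; returns rows + cohorts + truth.
run_pipeline <- function(sim, config = run_config()) {
  ds <- sim$dataset
  feats <- derive_features(ds, config)
  sel <- select_cohorts(ds, config, feats)
  rows_death <- build_cohort_rows(ds, feats, sel$death_ids, config)
  rows_fluid <- build_cohort_rows(ds, feats, sel$fluid_ids, config)
  list(sel = sel, rows_death = rows_death, rows_fluid = rows_fluid,
       truth = sim$truth, features = feats)
}
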