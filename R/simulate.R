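# Synthetic ICU data generator with a known per-patient leak fraction.
#
# Physiology: each patient starts with a total blood volume BV0 from the
# sex-specific Nadler formulas and a red-cell volume RCV = BV0 * Hct0/100.
# A fraction lambda of every infusion leaks out of the vasculature
# instantly; urine leaves it entirely. The intravascular volume after
# each event is V <- V + (1 - lambda) * intake - output, and the
# noise-free hematocrit at any time is 100 * RCV / V(t): red-cell volume
# is conserved exactly, so hemodilution is the only mechanism moving the
# hematocrit. High-leak patients dilute little — or, when urine outpaces
# retained intake, hemoconcentrate, producing the positive tail of the
# index.
#
# Reproducibility: each patient draws from a private substream seeded
# deterministically from (top seed, patient index), so patient i's course
# is invariant to n_patients and a fixed seed gives byte-identical files.

#' Nadler total blood volume
#'
#' Sex-specific blood volume in litres: males
#' `0.3669 h^3 + 0.03219 w + 0.6041`, females
#' `0.3561 h^3 + 0.03308 w + 0.1833`, height in metres, weight in kg.
#' Used only by the simulator — the analysis index normalizes by BSA, so
#' simulator physiology and index stay independent.
#'
#' @param height_cm height in cm; `weight_kg` in kg; `sex` "male"/"female".
#' @param weight_kg,sex see above.
#' @return blood volume in litres.
#' @export
nadler_blood_volume <- function(height_cm, weight_kg, sex) {
  h <- height_cm / 100
  ifelse(sex == "male",
         0.3669 * h^3 + 0.03219 * weight_kg + 0.6041,
         0.3561 * h^3 + 0.03308 * weight_kg + 0.1833)
}

#' Simulation configuration
#'
#' Default parameters define the generator's study conditions: an
#' eICU-like sepsis ICU population (age ~ 65 +/- 16, ~52% male,
#' APACHE-like severity 74 +/- 26), baseline hematocrit 36.5 +/- 5%,
#' leak fraction lambda ~ Beta(3.2, 3.8), ~15 infusion events over
#' [-6, 36] h averaging 450 ml, urine returning a (1 - lambda)-modulated
#' fraction of intake, hematocrit charted every 6 h with 1.2%-point
#' noise, in-hospital mortality near 14% rising in lambda, and a 36-84 h
#' balance with a 1200 ml/unit-lambda slope and right-skewed noise.
#'
#' @param n_patients number of patients.
#' @param seed integer top-level seed.
#' @param ... named overrides of any default component (partial lists are
#'   merged recursively).
#' @return a list of class `vli_sim_config`.
#' @export
sim_config <- function(n_patients = 5000, seed = 1L, ...) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    demographics = list(
      age_mean = 65, age_sd = 16, age_range = c(18, 95), prop_male = 0.52,
      height_male = c(175, 7), height_female = c(162, 7),
      weight_male = c(85, 17), weight_female = c(70, 15),
      height_range = c(140, 210), weight_range = c(35, 200)),
    sepsis_prevalence = 0.95,
    hct0 = list(mean = 36.5, sd = 5, range = c(18, 55)),
    leak = list(alpha = 2.2, beta = 2.6),
    fluids = list(rate_per_h = 0.35, volume_mean_ml = 450, volume_shape = 4,
                  ed_fraction = 0.02),
    urine = list(frac_base = 0.15, frac_leak = 0.25, cv = 0.15),
    hct_schedule = list(times = seq(0, 84, by = 6), pre_icu_prob = 0.4,
                        pre_icu_time = -3, noise_sd = 1.0),
    outcome_balance = list(intercept = 200, slope = 1200,
                           noise_shape = 2, noise_scale = 600,
                           urine_range = c(500, 2500), n_events = 6),
    death = list(intercept = -2.6, beta_lambda = 1.6, beta_severity = 0.4,
                 beta_age = 0.25, time_range = c(12, 240),
                 discharge_range = c(48, 400)),
    severity = list(mean = 74, sd = 26),
    comorbidity = list(mean = 4.3, sd = 2.9),
    flags = list(bleeding = 0.05, blood_products = 0.04, rrt = 0.05,
                 excess_output = 0.01, unreliable_fluid = 0.05)
  )
  over <- list(...)
  cfg <- utils::modifyList(cfg, over)
  validate_sim_config(cfg)
  structure(cfg, class = c("vli_sim_config", "list"))
}

#' Validate a simulation configuration
#' @param cfg a configuration list.
#' @return the config invisibly, or an error naming offending fields.
#' @export
validate_sim_config <- function(cfg) {
  bad <- character()
  if (cfg$n_patients < 0) bad <- c(bad, "n_patients must be >= 0")
  if (cfg$leak$alpha <= 0 || cfg$leak$beta <= 0)
    bad <- c(bad, "leak alpha/beta must be > 0")
  sds <- c(cfg$demographics$age_sd, cfg$hct0$sd, cfg$hct_schedule$noise_sd,
           cfg$severity$sd, cfg$comorbidity$sd)
  if (any(sds < 0)) bad <- c(bad, "all SDs must be >= 0")
  pr <- c(cfg$sepsis_prevalence, cfg$demographics$prop_male,
          cfg$hct_schedule$pre_icu_prob, unlist(cfg$flags))
  if (any(pr < 0 | pr > 1)) bad <- c(bad, "probabilities must lie in [0, 1]")
  if (length(bad))
    stop("invalid simulation config:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(cfg)
}

.patient_seed <- function(seed, i) {
  (abs(seed) * 48271 + i * 100003) %% 2147483629 + 1
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Noise-free hematocrit trajectory under the leak model
#'
#' Deterministic engine shared by the generator: given an explicit fluid
#' event table, the intravascular volume after each event changes by
#' `(1 - lambda) * intake - urine - other output`, and the hematocrit at
#' time t is `100 * RCV / V(t)` with RCV fixed at `BV0 * Hct0 / 100`
#' (red-cell volume is conserved).
#'
#' @param times times (h) at which to evaluate the hematocrit.
#' @param fluids data frame with `time_h`, `volume_ml`, `direction`;
#'   events strictly after an evaluation time do not affect it.
#' @param bv0_l baseline blood volume (L).
#' @param hct0_pct baseline hematocrit (%).
#' @param lambda leak fraction in \[0, 1\].
#' @return hematocrit (%) at each requested time.
#' @export
#' @examples
#' inf <- data.frame(time_h = 1, volume_ml = 2000, direction = "intake")
#' hct_trajectory(c(0, 2), inf, bv0_l = 5, hct0_pct = 40, lambda = 0)
#' # 40.00 and 100 * 2 / 7 = 28.57
hct_trajectory <- function(times, fluids, bv0_l, hct0_pct, lambda) {
  stopifnot(lambda >= 0, lambda <= 1, bv0_l > 0,
            hct0_pct > 0, hct0_pct < 100)
  v0 <- bv0_l * 1000
  rcv <- v0 * hct0_pct / 100
  if (nrow(fluids) == 0) return(rep(hct0_pct, length(times)))
  ord <- order(fluids$time_h)
  t_ev <- fluids$time_h[ord]
  dv <- ifelse(fluids$direction[ord] == "intake",
               (1 - lambda) * fluids$volume_ml[ord],
               -fluids$volume_ml[ord])
  cum <- cumsum(dv)
  idx <- findInterval(times, t_ev)
  v <- v0 + ifelse(idx == 0, 0, cum[pmax(idx, 1)])
  100 * rcv / v
}

# Drop output events that would push the hematocrit above hct_max (blood
# volume approaching the red-cell volume); returns the thinned event table
# and the number of rejections.
.enforce_volume_floor <- function(fluids, bv0_l, hct0_pct, lambda,
                                  hct_max = 65) {
  if (nrow(fluids) == 0) return(list(fluids = fluids, n_rejected = 0L))
  v_floor <- bv0_l * 1000 * hct0_pct / hct_max
  ord <- order(fluids$time_h)
  fluids <- fluids[ord, , drop = FALSE]
  dvs <- ifelse(fluids$direction == "intake",
                (1 - lambda) * fluids$volume_ml, -fluids$volume_ml)
  # fast path: no event can breach the floor
  if (min(bv0_l * 1000 + cumsum(dvs)) > v_floor)
    return(list(fluids = fluids, n_rejected = 0L))
  v <- bv0_l * 1000
  keep <- rep(TRUE, length(dvs))
  for (j in seq_along(dvs)) {
    if (v + dvs[j] <= v_floor) keep[j] <- FALSE else v <- v + dvs[j]
  }
  list(fluids = fluids[keep, , drop = FALSE], n_rejected = sum(!keep))
}

#' Simulate one patient's measurement and fluid-event course
#'
#' Draws infusion events over \[-6, 36\] h, urine output whose total is a
#' `(1 - lambda)`-modulated fraction of intake, 36-84 h events realizing
#' a target balance `a + b * lambda + skewed noise`, and scheduled
#' hematocrit measurements with additive Gaussian noise, all under the
#' conserved-red-cell-volume dilution model of [hct_trajectory()].
#' Consumes the current RNG stream.
#'
#' @param bv0_l baseline blood volume (L); `hct0_pct` baseline hematocrit.
#' @param hct0_pct,lambda see above; `lambda` is the true leak fraction.
#' @param config a [sim_config()].
#' @param t_end truncation time (death or discharge), hours; events and
#'   measurements after it are dropped.
#' @return list with data frames `hct` (`time_h`, `hct_pct`) and `fluids`
#'   (`time_h`, `volume_ml`, `direction`), plus `n_rejected` output events
#'   dropped by the blood-volume floor.
#' @export
simulate_patient_course <- function(bv0_l, hct0_pct, lambda, config,
                                    t_end = Inf) {
  fl <- config$fluids
  n_int <- stats::rpois(1, fl$rate_per_h * 42)
  # a small emergency-department fraction precedes ICU admission; the bulk
  # of resuscitation volume is charted after t = 0
  pre <- stats::runif(n_int) < fl$ed_fraction
  t_int <- sort(ifelse(pre, stats::runif(n_int, -6, 0),
                       stats::runif(n_int, 0, 36)))
  v_int <- stats::rgamma(n_int, shape = fl$volume_shape,
                         scale = fl$volume_mean_ml / fl$volume_shape)
  total_int <- sum(v_int)

  ur <- config$urine
  frac <- (ur$frac_base + ur$frac_leak * (1 - lambda)) *
    exp(stats::rnorm(1, 0, ur$cv) - ur$cv^2 / 2)
  frac <- .clamp(frac, 0, 0.95)
  t_ur <- seq(0.5, 35.5, by = 1)
  v_ur <- rep(frac * total_int / length(t_ur), length(t_ur))

  ob <- config$outcome_balance
  eps <- stats::rgamma(1, shape = ob$noise_shape, scale = ob$noise_scale) -
    ob$noise_shape * ob$noise_scale
  target <- ob$intercept + ob$slope * lambda + eps
  ur_out_total <- stats::runif(1, ob$urine_range[1], ob$urine_range[2])
  int_out_total <- target + ur_out_total
  if (int_out_total < 0) {
    int_out_total <- 0
    ur_out_total <- max(0, -target)
  }
  n_oev <- max(1L, stats::rpois(1, ob$n_events))
  t_oint <- sort(stats::runif(n_oev, 36, 84))
  t_oint[t_oint == 36] <- 36 + 1e-6
  w <- stats::rgamma(n_oev, 1); w <- w / sum(w)
  v_oint <- int_out_total * w
  t_our <- seq(36.5, 83.5, by = 1)
  v_our <- rep(ur_out_total / length(t_our), length(t_our))

  fluids <- data.frame(
    time_h = c(t_int, t_ur, t_oint, t_our),
    volume_ml = c(v_int, v_ur, v_oint, v_our),
    direction = c(rep("intake", n_int), rep("urine_output", length(t_ur)),
                  rep("intake", n_oev), rep("urine_output", length(t_our))),
    stringsAsFactors = FALSE)
  fluids <- fluids[fluids$volume_ml > 0, , drop = FALSE]
  guarded <- .enforce_volume_floor(fluids, bv0_l, hct0_pct, lambda)
  fluids <- guarded$fluids

  hs <- config$hct_schedule
  t_meas <- hs$times
  if (stats::runif(1) < hs$pre_icu_prob)
    t_meas <- c(hs$pre_icu_time, t_meas)
  hct_true <- hct_trajectory(t_meas, fluids, bv0_l, hct0_pct, lambda)
  hct_obs <- .clamp(hct_true + stats::rnorm(length(t_meas), 0, hs$noise_sd),
                    5, 70)

  keep_m <- t_meas <= t_end
  keep_f <- fluids$time_h <= t_end
  list(hct = data.frame(time_h = t_meas[keep_m], hct_pct = hct_obs[keep_m]),
       fluids = fluids[keep_f, , drop = FALSE],
       n_rejected = guarded$n_rejected)
}

#' Simulate death and discharge outcomes for one patient
#'
#' Death is Bernoulli on the logit scale in the true leak fraction,
#' standardized severity and standardized age; death times are uniform
#' over the configured range, discharge times likewise for survivors.
#' Consumes the current RNG stream.
#'
#' @param lambda,severity,age patient-level inputs.
#' @param config a [sim_config()].
#' @return list: `died` (0/1), `event_time_h` (death or discharge time).
#' @export
simulate_outcomes <- function(lambda, severity, age, config) {
  d <- config$death
  z_sev <- (severity - config$severity$mean) / config$severity$sd
  z_age <- (age - config$demographics$age_mean) / config$demographics$age_sd
  p <- stats::plogis(d$intercept + d$beta_lambda * lambda +
                       d$beta_severity * z_sev + d$beta_age * z_age)
  died <- stats::rbinom(1, 1, p)
  t <- if (died == 1)
    stats::runif(1, d$time_range[1], d$time_range[2])
  else
    stats::runif(1, d$discharge_range[1], d$discharge_range[2])
  list(died = died, event_time_h = t)
}

#' Generate a complete synthetic ICU dataset with ground truth
#'
#' Draws every patient from a private, deterministic RNG substream, so a
#' fixed seed reproduces the dataset byte-for-byte and patient i's course
#' does not depend on `n_patients`.
#'
#' @param config a [sim_config()].
#' @return list: `dataset` (a `vli_dataset`) and `truth` (data frame
#'   `patient_id`, `lambda`, `bv0_l`, `rcv_l`).
#' @export
generate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  n <- config$n_patients
  de <- config$demographics
  pats <- vector("list", n)
  hcts <- vector("list", n)
  flds <- vector("list", n)
  tru <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(.patient_seed(config$seed, i))
    pid <- sprintf("P%06d", i)
    sex <- if (stats::runif(1) < de$prop_male) "male" else "female"
    age <- .clamp(stats::rnorm(1, de$age_mean, de$age_sd),
                  de$age_range[1], de$age_range[2])
    hp <- if (sex == "male") de$height_male else de$height_female
    wp <- if (sex == "male") de$weight_male else de$weight_female
    height <- .clamp(stats::rnorm(1, hp[1], hp[2]),
                     de$height_range[1], de$height_range[2])
    weight <- .clamp(stats::rnorm(1, wp[1], wp[2]),
                     de$weight_range[1], de$weight_range[2])
    severity <- max(1, stats::rnorm(1, config$severity$mean, config$severity$sd))
    comorb <- max(0, stats::rnorm(1, config$comorbidity$mean,
                                  config$comorbidity$sd))
    lambda <- stats::rbeta(1, config$leak$alpha, config$leak$beta)
    hct0 <- .clamp(stats::rnorm(1, config$hct0$mean, config$hct0$sd),
                   config$hct0$range[1], config$hct0$range[2])
    bv0 <- nadler_blood_volume(height, weight, sex)

    fg <- config$flags
    sepsis <- as.integer(stats::runif(1) < config$sepsis_prevalence)
    bleeding <- as.integer(stats::runif(1) < fg$bleeding)
    blood_prod <- as.integer(stats::runif(1) < fg$blood_products)
    rrt <- as.integer(stats::runif(1) < fg$rrt)
    excess <- as.integer(stats::runif(1) < fg$excess_output)
    reliable <- as.integer(stats::runif(1) >= fg$unreliable_fluid)

    oc <- simulate_outcomes(lambda, severity, age, config)
    course <- simulate_patient_course(bv0, hct0, lambda, config,
                                      t_end = oc$event_time_h)

    pats[[i]] <- data.frame(
      patient_id = pid, age = age, sex = sex, height_cm = height,
      weight_kg = weight, sepsis = sepsis, bleeding_dx = bleeding,
      rrt = rrt, received_blood_products = blood_prod,
      excess_other_output = excess, reliable_fluid_data = reliable,
      severity_score = severity, comorbidity_score = comorb,
      died_in_hospital = oc$died,
      death_or_discharge_time_h = oc$event_time_h,
      stringsAsFactors = FALSE)
    if (nrow(course$hct))
      hcts[[i]] <- cbind(patient_id = pid, course$hct,
                         stringsAsFactors = FALSE)
    if (nrow(course$fluids))
      flds[[i]] <- cbind(patient_id = pid, course$fluids,
                         stringsAsFactors = FALSE)
    tru[[i]] <- data.frame(patient_id = pid, lambda = lambda, bv0_l = bv0,
                           rcv_l = bv0 * hct0 / 100,
                           stringsAsFactors = FALSE)
  }

  empty_p <- data.frame(matrix(nrow = 0, ncol = length(.patient_cols),
                               dimnames = list(NULL, .patient_cols)))
  empty_h <- data.frame(patient_id = character(), time_h = numeric(),
                        hct_pct = numeric())
  empty_f <- data.frame(patient_id = character(), time_h = numeric(),
                        volume_ml = numeric(), direction = character())
  patients <- if (n) do.call(rbind, pats) else empty_p
  hct <- if (length(hcts) && any(!vapply(hcts, is.null, logical(1))))
    do.call(rbind, hcts[!vapply(hcts, is.null, logical(1))]) else empty_h
  fluids <- if (length(flds) && any(!vapply(flds, is.null, logical(1))))
    do.call(rbind, flds[!vapply(flds, is.null, logical(1))]) else empty_f
  truth <- if (n) do.call(rbind, tru) else
    data.frame(patient_id = character(), lambda = numeric(),
               bv0_l = numeric(), rcv_l = numeric())
  rownames(patients) <- rownames(hct) <- rownames(fluids) <- NULL

  list(dataset = new_dataset(patients, hct, fluids), truth = truth)
}
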