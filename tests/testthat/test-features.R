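# Brute-force oracles for the windowed extractors: plain loops written
# against the documented window semantics, independent of the package's
# vectorized code paths.

oracle_initial <- function(time_h, hct, lo, hi) {
  best_t <- Inf; vals <- c()
  for (i in seq_along(time_h)) {
    if (time_h[i] >= lo && time_h[i] <= hi) {
      if (time_h[i] < best_t) { best_t <- time_h[i]; vals <- hct[i] }
      else if (time_h[i] == best_t) vals <- c(vals, hct[i])
    }
  }
  if (is.infinite(best_t)) NA_real_ else mean(vals)
}

oracle_final <- function(time_h, hct, lo, hi) {
  vals <- c()
  for (i in seq_along(time_h))
    if (time_h[i] > lo && time_h[i] <= hi) vals <- c(vals, hct[i])
  if (!length(vals)) NA_real_ else mean(vals)
}

oracle_balance <- function(fl, lo, hi, closed_left) {
  tot <- 0; seen <- FALSE
  for (i in seq_len(nrow(fl))) {
    t <- fl$time_h[i]
    inw <- if (closed_left) t >= lo && t <= hi else t > lo && t <= hi
    if (!inw) next
    if (fl$direction[i] == "intake") { tot <- tot + fl$volume_ml[i]; seen <- TRUE }
    if (fl$direction[i] == "urine_output") { tot <- tot - fl$volume_ml[i]; seen <- TRUE }
  }
  list(total = tot, seen = seen)
}

rand_stream <- function(n_hct = 8, n_fl = 15) {
  boundary <- c(-12, -6, 18, 36, 84)
  ht <- c(runif(n_hct, -15, 90), sample(boundary, 2))
  hv <- runif(length(ht), 20, 50)
  ft <- c(runif(n_fl, -10, 90), sample(boundary, 3))
  fl <- data.frame(time_h = ft,
                   volume_ml = round(runif(length(ft), 0, 2000)),
                   direction = sample(c("intake", "urine_output",
                                        "other_output"),
                                      length(ft), replace = TRUE),
                   stringsAsFactors = FALSE)
  list(ht = ht, hv = hv, fl = fl)
}

test_that("windowed extractors match a brute-force scan on random streams", {
  set.seed(202)
  for (rep in 1:300) {
    s <- rand_stream()
    expect_identical(extract_initial_hct(s$ht, s$hv),
                     oracle_initial(s$ht, s$hv, -12, 18))
    expect_identical(extract_final_hct(s$ht, s$hv),
                     oracle_final(s$ht, s$hv, 18, 36))
    expect_identical(compute_net_balance(s$fl),
                     oracle_balance(s$fl, -6, 36, TRUE)$total)
    ob <- oracle_balance(s$fl, 36, 84, FALSE)
    expect_identical(compute_outcome_balance(s$fl),
                     if (ob$seen) ob$total else NA_real_)
  }
})

test_that("shifting all times and windows together leaves features unchanged", {
  set.seed(203)
  for (rep in 1:50) {
    s <- rand_stream()
    delta <- runif(1, -40, 40)
    expect_equal(extract_initial_hct(s$ht + delta, s$hv, c(-12, 18) + delta),
                 extract_initial_hct(s$ht, s$hv))
    expect_equal(extract_final_hct(s$ht + delta, s$hv, c(18, 36) + delta),
                 extract_final_hct(s$ht, s$hv))
    fl2 <- s$fl; fl2$time_h <- fl2$time_h + delta
    expect_equal(compute_net_balance(fl2, c(-6, 36) + delta),
                 compute_net_balance(s$fl))
    expect_equal(compute_outcome_balance(fl2, c(36, 84) + delta),
                 compute_outcome_balance(s$fl))
  }
})

test_that("window boundary semantics are as documented", {
  # earliest wins; t = 18 belongs to the initial window, not the final
  expect_equal(extract_initial_hct(c(-3, 2), c(35, 33)), 35)
  expect_equal(extract_initial_hct(18, 28), 28)
  expect_true(is.na(extract_initial_hct(c(19, 25), c(30, 31))))
  expect_equal(extract_final_hct(c(20, 30), c(30, 32)), 31)
  expect_equal(extract_final_hct(36, 28), 28)
  expect_true(is.na(extract_final_hct(18, 28)))
  # ties at the earliest timestamp are averaged
  expect_equal(extract_initial_hct(c(0, 0, 5), c(30, 34, 40)), 32)

  # t = 36 counted once, in the first balance window; t = -6 included
  fl <- data.frame(time_h = c(-6, 36, 36.0001),
                   volume_ml = c(1000, 500, 200),
                   direction = rep("intake", 3))
  expect_equal(compute_net_balance(fl), 1500)
  expect_equal(compute_outcome_balance(fl), 200)
  fl7 <- data.frame(time_h = -7, volume_ml = 1000, direction = "intake")
  expect_equal(compute_net_balance(fl7), 0)
  # other_output never enters a balance
  flo <- data.frame(time_h = c(1, 2), volume_ml = c(2000, 700),
                    direction = c("intake", "other_output"))
  expect_equal(compute_net_balance(flo), 2000)
  # empty window: 0 for net balance, missing for the outcome balance
  none <- data.frame(time_h = numeric(), volume_ml = numeric(),
                     direction = character())
  expect_equal(compute_net_balance(none), 0)
  expect_true(is.na(compute_outcome_balance(none)))
})

test_that("BSA formulas evaluate correctly and reject bad input", {
  expect_equal(round(compute_bsa(170, 70), 3), 1.810)
  expect_equal(compute_bsa(170, 70),
               0.007184 * 70^0.425 * 170^0.725, tolerance = 1e-15)
  expect_equal(compute_bsa(180, 80, "mosteller"), sqrt(180 * 80 / 3600))
  # population means of an eICU-like cohort land near the reported mean BSA
  bsa <- compute_bsa(168.37, 81.07)
  expect_equal(round(bsa, 2), 1.91)
  expect_lt(abs(bsa - 1.93), 0.05)
  expect_error(compute_bsa(170, 0), "positive")
  expect_error(compute_bsa(-1, 70), "positive")
})

test_that("derive_features agrees with per-patient extraction", {
  ds <- make_toy_dataset()
  f <- derive_features(ds)
  expect_equal(f$patient_id, c("A", "B"))
  expect_equal(f$hct_initial, c(36, 40))   # earliest in window per patient
  expect_equal(f$hct_final, c(32, 34.5))   # means over (18, 36]
  expect_equal(f$net_balance_ml, c(2000, 1700))
  expect_equal(f$outcome_balance_ml, c(900, 700))
  expect_equal(f$bsa_m2, compute_bsa(c(170, 170), c(70, 70)))

  # a patient with no events gets 0 net balance and missing hct/outcome
  ds$patients <- rbind(ds$patients, make_patient_row("C"))
  f2 <- derive_features(ds)
  expect_true(is.na(f2$hct_initial[3]))
  expect_equal(f2$net_balance_ml[3], 0)
  expect_true(is.na(f2$outcome_balance_ml[3]))
})
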