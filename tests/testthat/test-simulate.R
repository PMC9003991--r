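test_that("hemodilution follows the closed-form arithmetic", {
  inf <- data.frame(time_h = 1, volume_ml = 2000, direction = "intake")
  # lambda = 0: 2 L retained on 5 L, RCV = 2 L -> hct = 100 * 2 / 7
  h <- hct_trajectory(c(0, 2), inf, bv0_l = 5, hct0_pct = 40, lambda = 0)
  expect_equal(h, c(40, 100 * 2 / 7))

  # lambda = 1: infusions never enter the vasculature
  many <- data.frame(time_h = c(1, 5, 10), volume_ml = c(2000, 1000, 3000),
                     direction = "intake")
  expect_equal(hct_trajectory(c(0, 2, 6, 20), many, 5, 40, 1), rep(40, 4))

  # lambda = 1 with urine: volume falls, hct rises despite infusions
  mix <- rbind(many, data.frame(time_h = 12, volume_ml = 800,
                                direction = "urine_output"))
  h2 <- hct_trajectory(c(11, 13), mix, 5, 40, 1)
  expect_equal(h2[1], 40)
  expect_gt(h2[2], 40)
  expect_equal(h2[2], 100 * 2 / 4.2)
})

test_that("red-cell volume is conserved along any trajectory", {
  set.seed(501)
  for (rep in 1:20) {
    n <- 30
    fl <- data.frame(time_h = sort(runif(n, -6, 84)),
                     volume_ml = runif(n, 50, 800),
                     direction = sample(c("intake", "urine_output"), n,
                                        replace = TRUE, prob = c(.6, .4)))
    lam <- runif(1)
    bv0 <- runif(1, 4, 6); hct0 <- runif(1, 30, 45)
    times <- sort(runif(10, -6, 90))
    h <- hct_trajectory(times, fl, bv0, hct0, lam)
    # independent volume bookkeeping
    v <- vapply(times, function(t) {
      keep <- fl$time_h <= t
      bv0 * 1000 + sum(ifelse(fl$direction[keep] == "intake",
                              (1 - lam) * fl$volume_ml[keep],
                              -fl$volume_ml[keep]))
    }, numeric(1))
    rcv <- h * v / 100  # implied red-cell volume at each time
    expect_equal(rcv, rep(bv0 * 1000 * hct0 / 100, length(times)),
                 tolerance = 1e-12)
  }
})

test_that("noise-free index increases with the leak fraction in a fixed stratum", {
  cfg <- sim_config(n_patients = 1, seed = 1)
  lams <- seq(0, 1, by = 0.05)
  vli <- vapply(lams, function(lam) {
    fl <- data.frame(time_h = c(2, 10, 20), volume_ml = c(2000, 1500, 1500),
                     direction = "intake")  # no urine
    h <- hct_trajectory(c(0, 24, 30, 36), fl, 5, 40, lam)
    compute_vli(h[1], mean(h[2:4]), compute_net_balance(fl), 1.9)
  }, numeric(1))
  expect_true(all(diff(vli) > 0))
})

test_that("generation is deterministic and patient courses are invariant to n", {
  cfg <- sim_config(n_patients = 40, seed = 77)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)

  big <- generate_dataset(sim_config(n_patients = 60, seed = 77))
  ids <- a$dataset$patients$patient_id
  expect_identical(a$dataset$patients,
                   big$dataset$patients[big$dataset$patients$patient_id %in% ids, ])
  h_small <- a$dataset$hct
  h_big <- big$dataset$hct[big$dataset$hct$patient_id %in% ids, ]
  rownames(h_big) <- NULL
  expect_identical(h_small, h_big)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cmd_simulate(d1, cfg); cmd_simulate(d2, cfg)
  for (f in c("patients.csv", "hct.csv", "fluids.csv", "ground_truth.csv",
              "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("an empty simulation yields valid empty tables with headers", {
  sim <- generate_dataset(sim_config(n_patients = 0, seed = 1))
  expect_equal(nrow(sim$dataset$patients), 0)
  expect_equal(nrow(sim$truth), 0)
  dir <- withr::local_tempdir()
  cmd_simulate(dir, sim_config(n_patients = 0, seed = 1))
  p <- readLines(file.path(dir, "patients.csv"))
  expect_equal(length(p), 1)
  expect_match(p, "^patient_id,")
})

test_that("generated data satisfy the interchange invariants", {
  set.seed(502)
  sim <- generate_dataset(sim_config(n_patients = 250, seed = 502))
  expect_silent(validate_dataset(sim$dataset))
  expect_true(all(sim$truth$lambda >= 0 & sim$truth$lambda <= 1))
  expect_true(all(sim$truth$bv0_l > 0 & sim$truth$rcv_l > 0))
  expect_true(all(sim$dataset$hct$hct_pct > 0 & sim$dataset$hct$hct_pct < 100))
  expect_true(all(sim$dataset$fluids$volume_ml >= 0))
})

test_that("default calibration matches the intended ICU population", {
  sim <- generate_dataset(sim_config(n_patients = 2500, seed = 503))
  pl <- run_pipeline(sim)
  rows <- pl$rows_death
  # loose (+/-20%) sanity targets for the generator's study conditions
  expect_lt(abs(mean(rows$hct_initial) - 35.8) / 35.8, 0.2)
  expect_lt(abs(mean(rows$hct_final) - 31.1) / 31.1, 0.2)
  expect_lt(abs(median(rows$vli) - (-2.79)) / 2.79, 0.2)
  mort <- 100 * mean(rows$died_in_hospital)
  expect_gt(mort, 10); expect_lt(mort, 21)
  # left-skewed index with a small positive tail
  expect_lt(median(rows$vli_raw), 0)
  expect_lt(mean(rows$vli_raw > 0), 0.2)
  expect_gt(mean(rows$vli_raw > 0), 0)
  skew <- mean((rows$vli_raw - mean(rows$vli_raw))^3) / sd(rows$vli_raw)^3
  expect_lt(skew, 0)
  # positively skewed realized fluid balances
  bal <- pl$rows_fluid$outcome_balance_ml
  expect_gt(mean((bal - mean(bal))^3) / sd(bal)^3, 0)
})

test_that("outcome model obeys the law of large numbers under a null leak effect", {
  cfg <- sim_config(n_patients = 1, seed = 1,
                    death = list(beta_lambda = 0, beta_severity = 0,
                                 beta_age = 0))
  set.seed(504)
  n <- 10000
  died <- vapply(seq_len(n), function(i)
    simulate_outcomes(runif(1), 74, 65, cfg)$died, numeric(1))
  p0 <- plogis(cfg$death$intercept)
  expect_lt(abs(mean(died) - p0), 3 * sqrt(p0 * (1 - p0) / n))

  # b = 0: realized 36-84 h balance uncorrelated with lambda
  cfg2 <- sim_config(n_patients = 800, seed = 505,
                     outcome_balance = list(slope = 0))
  sim <- generate_dataset(cfg2)
  pl <- run_pipeline(sim)
  m <- merge(pl$rows_fluid, sim$truth, by = "patient_id")
  expect_lt(abs(cor(m$lambda, m$outcome_balance_ml)), 0.1)
})
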