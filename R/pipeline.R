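# End-to-end drivers: simulate -> analyze -> report, with a JSON run
# configuration. All numeric artifacts are written at full precision and
# contain no timestamps, so identical inputs and config give
# byte-identical outputs.

#' Analysis run configuration
#'
#' @param windows list of the four analysis windows (hours): `initial_hct`
#'   (closed), `final_hct` (half-open `(lo, hi]`), `net_balance` (closed),
#'   `outcome_balance` (half-open).
#' @param bsa_formula `"dubois"` (default) or `"mosteller"`.
#' @param tail_fraction tail mass median-imputed on each side of the index
#'   distribution; must lie in \[0, 0.25\].
#' @param spline_k basis dimension of the penalized cubic regression
#'   spline for the index smooth.
#' @param smoothing mgcv smoothness-selection criterion, default `"REML"`.
#' @param ci_level confidence level for all intervals, in (0.5, 1).
#' @param seed optional integer seed recorded in manifests.
#' @return a validated list of class `vli_run_config`.
#' @export
run_config <- function(windows = list(initial_hct = c(-12, 18),
                                      final_hct = c(18, 36),
                                      net_balance = c(-6, 36),
                                      outcome_balance = c(36, 84)),
                       bsa_formula = c("dubois", "mosteller"),
                       tail_fraction = 0.05,
                       spline_k = 10,
                       smoothing = "REML",
                       ci_level = 0.95,
                       seed = NULL) {
  bsa_formula <- match.arg(bsa_formula)
  cfg <- list(windows = windows, bsa_formula = bsa_formula,
              tail_fraction = tail_fraction, spline_k = spline_k,
              smoothing = smoothing, ci_level = ci_level, seed = seed)
  validate_run_config(cfg)
  structure(cfg, class = c("vli_run_config", "list"))
}

#' Validate a run configuration
#' @param cfg a configuration list.
#' @return the config invisibly, or an error listing offending fields.
#' @export
validate_run_config <- function(cfg) {
  bad <- character()
  need <- c("initial_hct", "final_hct", "net_balance", "outcome_balance")
  if (!all(need %in% names(cfg$windows)))
    bad <- c(bad, paste("windows must define:", paste(need, collapse = ", ")))
  for (w in intersect(need, names(cfg$windows))) {
    v <- cfg$windows[[w]]
    if (length(v) != 2 || !is.numeric(v) || v[1] >= v[2])
      bad <- c(bad, paste0("window '", w, "' must be numeric (lo, hi) with lo < hi"))
  }
  if (!is.numeric(cfg$tail_fraction) || cfg$tail_fraction < 0 ||
      cfg$tail_fraction > 0.25)
    bad <- c(bad, "tail_fraction must lie in [0, 0.25]")
  if (!is.numeric(cfg$ci_level) || cfg$ci_level <= 0.5 || cfg$ci_level >= 1)
    bad <- c(bad, "ci_level must lie in (0.5, 1)")
  if (!is.numeric(cfg$spline_k) || cfg$spline_k < 3)
    bad <- c(bad, "spline_k must be >= 3")
  if (!cfg$bsa_formula %in% c("dubois", "mosteller"))
    bad <- c(bad, "bsa_formula must be 'dubois' or 'mosteller'")
  if (length(bad))
    stop("invalid run config:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(cfg)
}

#' Load a run or simulation configuration from JSON
#'
#' Partial configs are merged over the defaults.
#'
#' @param path JSON file.
#' @param kind `"run"` or `"sim"`.
#' @return a validated config list.
#' @export
load_config <- function(path, kind = c("run", "sim")) {
  kind <- match.arg(kind)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (kind == "run") {
    cfg <- utils::modifyList(run_config(), user)
    validate_run_config(cfg)
    structure(cfg, class = c("vli_run_config", "list"))
  } else {
    do.call(sim_config, user)
  }
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Simulate a synthetic dataset to disk
#'
#' Writes `patients.csv`, `hct.csv`, `fluids.csv`, `ground_truth.csv` and
#' a `manifest.json` recording the seed, size and a config fingerprint.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()]; ignored when `config_path` is given.
#' @param config_path optional JSON config merged over the defaults.
#' @return named vector of written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = sim_config(), config_path = NULL) {
  if (!is.null(config_path)) config <- load_config(config_path, "sim")
  validate_sim_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- generate_dataset(config)
  paths <- write_dataset(sim$dataset, out_dir)
  gt <- file.path(out_dir, "ground_truth.csv")
  .write_mixed_csv(sim$truth, gt, numeric_cols = c("lambda", "bv0_l", "rcv_l"))
  manifest <- list(seed = config$seed, n_patients = config$n_patients,
                   config_hash = .config_hash(unclass(config)),
                   files = basename(c(paths, ground_truth = gt)))
  mf <- file.path(out_dir, "manifest.json")
  .write_json(manifest, mf)
  invisible(c(paths, ground_truth = gt, manifest = mf))
}

.gam_summary_list <- function(g, quartiles, curve) {
  co <- stats::coef(g$fit)
  list(outcome_kind = g$outcome_kind,
       n = g$n,
       covariates = g$covariates,
       smooth_edf = g$edf,
       smooth_p_value = g$smooth_p_value,
       parametric_coefficients = as.list(co[!grepl("^s\\(", names(co))]),
       quartile_effects = as.data.frame(quartiles))
}

#' Run the full analysis on a dataset directory
#'
#' Reads the three-table dataset, derives features, applies the exclusion
#' cascade for both cohorts, computes the index with tail imputation and
#' quartiles per cohort, fits the death and balance models, and writes:
#' cohort CSVs, attrition CSVs, `models.json`, partial-effect curve CSVs
#' and a run log.
#'
#' @param data_dir directory holding `patients.csv`, `hct.csv`,
#'   `fluids.csv`.
#' @param out_dir artifact directory (created if needed).
#' @param config a [run_config()]; or `config_path` to load one.
#' @param config_path optional JSON run config.
#' @return list with cohorts, fits and artifact paths, invisibly.
#' @export
cmd_analyze <- function(data_dir, out_dir, config = run_config(),
                        config_path = NULL) {
  if (!is.null(config_path)) config <- load_config(config_path, "run")
  validate_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  ds <- read_dataset(file.path(data_dir, "patients.csv"),
                     file.path(data_dir, "hct.csv"),
                     file.path(data_dir, "fluids.csv"))
  say("read dataset: ", nrow(ds$patients), " patients, ",
      nrow(ds$hct), " hct rows, ", nrow(ds$fluids), " fluid events")

  feats <- derive_features(ds, config)
  sel <- select_cohorts(ds, config, feats)
  say("sepsis patients: ", sel$n_sepsis,
      "; death cohort: ", length(sel$death_ids),
      "; fluid cohort: ", length(sel$fluid_ids))
  write_attrition(sel$attrition_death, file.path(out_dir, "attrition_death.csv"))
  write_attrition(sel$attrition_fluid, file.path(out_dir, "attrition_fluid.csv"))

  if (length(sel$death_ids) == 0) {
    print(sel$attrition_death)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    stop("death cohort is empty after exclusions; see attrition table",
         call. = FALSE)
  }

  rows_death <- build_cohort_rows(ds, feats, sel$death_ids, config)
  rows_fluid <- build_cohort_rows(ds, feats, sel$fluid_ids, config)
  write_cohort(rows_death, file.path(out_dir, "cohort_death.csv"))
  write_cohort(rows_fluid, file.path(out_dir, "cohort_fluid.csv"))

  gam_death <- fit_death_gam(rows_death, config)
  gam_balance <- fit_balance_gam(rows_fluid, config)
  q_death <- fit_quartile_model(rows_death, "binary_death",
                                ci_level = config$ci_level)
  q_balance <- fit_quartile_model(rows_fluid, "continuous_balance",
                                  ci_level = config$ci_level)
  say("death model: smooth p = ", format(gam_death$smooth_p_value),
      ", edf = ", format(round(gam_death$edf, 2)))
  say("balance model: smooth p = ", format(gam_balance$smooth_p_value),
      ", edf = ", format(round(gam_balance$edf, 2)))

  curve_death <- predict_partial_effect(gam_death)
  curve_balance <- predict_partial_effect(gam_balance)
  .write_mixed_csv(as.data.frame(curve_death),
                   file.path(out_dir, "curve_death.csv"),
                   numeric_cols = c("vli", "fit", "lo", "hi"))
  .write_mixed_csv(as.data.frame(curve_balance),
                   file.path(out_dir, "curve_balance.csv"),
                   numeric_cols = c("vli", "fit", "lo", "hi"))

  .write_json(list(death = .gam_summary_list(gam_death, q_death, curve_death),
                   balance = .gam_summary_list(gam_balance, q_balance,
                                               curve_balance)),
              file.path(out_dir, "models.json"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(cohorts = sel, rows_death = rows_death,
                 rows_fluid = rows_fluid, gam_death = gam_death,
                 gam_balance = gam_balance, quartiles_death = q_death,
                 quartiles_balance = q_balance, out_dir = out_dir))
}

#' Render a human-readable analysis report
#'
#' Summarizes the artifacts written by [cmd_analyze()] into
#' `report.md`: cohort sizes, the index distribution (median and IQR),
#' quartile contrasts and smooth-term p-values. Every number is
#' recomputed from the emitted CSV/JSON artifacts.
#'
#' @param out_dir directory holding [cmd_analyze()] artifacts.
#' @return the report path, invisibly.
#' @export
cmd_report <- function(out_dir) {
  need <- c("cohort_death.csv", "cohort_fluid.csv", "attrition_death.csv",
            "attrition_fluid.csv", "models.json")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing))
    stop("missing analysis artifact(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  rows_death <- read_cohort(file.path(out_dir, "cohort_death.csv"))
  rows_fluid <- read_cohort(file.path(out_dir, "cohort_fluid.csv"))
  models <- jsonlite::read_json(file.path(out_dir, "models.json"),
                                simplifyVector = TRUE)

  qd <- models$death$quartile_effects
  qb <- models$balance$quartile_effects
  fmt_q <- function(q, unit) {
    apply(q, 1, function(r) {
      est <- as.numeric(r[["estimate"]])
      if (r[["quartile"]] == "Q1")
        sprintf("| %s | %s | (reference) | |", r[["quartile"]],
                format(round(est, 2)))
      else
        sprintf("| %s | %.2f | %.2f to %.2f | %s |", r[["quartile"]], est,
                as.numeric(r[["conf_lo"]]), as.numeric(r[["conf_hi"]]),
                format.pval(as.numeric(r[["p_value"]]), digits = 2))
    })
  }
  iqr <- stats::quantile(rows_death$vli, c(0.25, 0.5, 0.75), type = 7)

  lines <- c(
    "# Vascular leak index analysis report", "",
    sprintf("- In-hospital-death cohort: %d patients (%d deaths, %.1f%%)",
            nrow(rows_death), sum(rows_death$died_in_hospital),
            100 * mean(rows_death$died_in_hospital)),
    sprintf("- 36-84 h fluid-balance cohort: %d patients", nrow(rows_fluid)),
    sprintf("- VLI, death cohort: median %.2f [IQR %.2f, %.2f]",
            iqr[2], iqr[1], iqr[3]), "",
    "## In-hospital death (adjusted odds ratios vs Q1)", "",
    "| Quartile | OR | 95% CI | p |", "|---|---|---|---|",
    fmt_q(qd, "OR"), "",
    sprintf("Smooth term: edf %.2f, p = %s",
            models$death$smooth_edf,
            format.pval(models$death$smooth_p_value, digits = 3)), "",
    "## 36-84 h fluid balance (adjusted mean differences vs Q1, ml)", "",
    "| Quartile | Difference (ml) | 95% CI | p |", "|---|---|---|---|",
    fmt_q(qb, "ml"), "",
    sprintf("Smooth term: edf %.2f, p = %s",
            models$balance$smooth_edf,
            format.pval(models$balance$smooth_p_value, digits = 3)), "")
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
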