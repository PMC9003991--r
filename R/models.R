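# Association models: penalized-spline additive fits of each outcome on
# the continuous index, and categorical quartile GLMs yielding odds
# ratios / mean differences against Q1.
#
# Spline choices (the analysis-facing defaults): cubic regression spline
# basis, dimension k = 10, smoothness selected by REML. Significance of
# the smooth is the approximate test reported by mgcv's summary (an
# ANOVA-type test of the fitted smooth against zero). Confidence
# intervals are Wald on the link scale, exponentiated for odds ratios.

.model_covariates <- c("severity_score", "comorbidity_score", "age", "sex")

# Resolve the covariate set actually usable on these rows: comorbidity is
# dropped when unavailable ("if available" covariate); sex is dropped if
# constant; rows with missing severity are dropped with a warning.
.prepare_model_rows <- function(rows, outcome_col, covariates) {
  rows <- rows[!is.na(rows[[outcome_col]]), , drop = FALSE]
  covs <- intersect(covariates, names(rows))
  if ("comorbidity_score" %in% covs && all(is.na(rows$comorbidity_score)))
    covs <- setdiff(covs, "comorbidity_score")
  if ("severity_score" %in% covs) {
    drop <- is.na(rows$severity_score)
    if (any(drop)) {
      warning(sum(drop), " row(s) with missing severity_score dropped",
              call. = FALSE)
      rows <- rows[!drop, , drop = FALSE]
    }
  }
  if ("comorbidity_score" %in% covs) {
    drop <- is.na(rows$comorbidity_score)
    if (any(drop)) {
      warning(sum(drop), " row(s) with missing comorbidity_score dropped",
              call. = FALSE)
      rows <- rows[!drop, , drop = FALSE]
    }
  }
  if ("sex" %in% covs) {
    rows$sex <- factor(rows$sex, levels = c("female", "male"))
    if (length(unique(rows$sex)) < 2) covs <- setdiff(covs, "sex")
  }
  list(rows = rows, covariates = covs)
}

.reference_covariates <- function(rows, covs) {
  ref <- list()
  for (cv in covs) {
    v <- rows[[cv]]
    ref[[cv]] <- if (is.numeric(v)) mean(v) else {
      tab <- table(v)
      factor(names(tab)[which.max(tab)], levels = levels(v))
    }
  }
  ref
}

.fit_gam <- function(rows, outcome_kind, config) {
  outcome_col <- switch(outcome_kind,
                        binary_death = "died_in_hospital",
                        continuous_balance = "outcome_balance_ml")
  prep <- .prepare_model_rows(rows, outcome_col, .model_covariates)
  rows <- prep$rows; covs <- prep$covariates
  if (nrow(rows) < 30)
    stop("too few rows (", nrow(rows), ") to fit a spline model",
         call. = FALSE)
  if (nrow(rows) < 200)
    warning("fewer than 200 rows; spline fit may be unstable", call. = FALSE)

  fam <- switch(outcome_kind,
                binary_death = stats::binomial(),
                continuous_balance = stats::gaussian())
  rhs <- c(sprintf("s(vli, k = %d, bs = \"cr\")", config$spline_k), covs)
  form <- stats::as.formula(paste(outcome_col, "~", paste(rhs, collapse = " + ")))
  fit <- mgcv::gam(form, family = fam, data = rows, method = config$smoothing)

  if (!fit$converged)
    stop("GAM did not converge for outcome ", outcome_kind, call. = FALSE)
  co <- stats::coef(fit)
  par_co <- co[!grepl("^s\\(", names(co))]
  if (outcome_kind == "binary_death" && any(abs(par_co) > 20)) {
    worst <- names(par_co)[which.max(abs(par_co))]
    stop("possible separation: extreme coefficient for '", worst, "'",
         call. = FALSE)
  }

  sm <- summary(fit)$s.table
  structure(list(fit = fit,
                 outcome_kind = outcome_kind,
                 n = nrow(rows),
                 covariates = covs,
                 smooth_p_value = unname(sm[1, "p-value"]),
                 edf = unname(sm[1, "edf"]),
                 vli_range = range(rows$vli),
                 reference = .reference_covariates(rows, covs),
                 ci_level = config$ci_level),
            class = "vli_gam")
}

#' Fit the in-hospital-death additive model
#'
#' Logistic additive model `death ~ s(VLI) + severity + comorbidity (if
#' available) + age + sex` with a penalized cubic regression spline for
#' the index. The smooth-term p-value is mgcv's approximate significance
#' test of the fitted smooth.
#'
#' @param rows cohort rows from [build_cohort_rows()] (death cohort).
#' @param config a [run_config()]; `spline_k`, `smoothing`, `ci_level`.
#' @return object of class `vli_gam` with elements `fit` (the mgcv fit),
#'   `smooth_p_value`, `edf`, `n`, `covariates`, `vli_range`, `reference`.
#' @export
fit_death_gam <- function(rows, config = run_config()) {
  .fit_gam(rows, "binary_death", config)
}

#' Fit the 36-84 h fluid-balance additive model
#'
#' Identity-link additive model of the outcome balance (ml) with the same
#' smooth and covariate structure as [fit_death_gam()].
#'
#' @inheritParams fit_death_gam
#' @return a `vli_gam`.
#' @export
fit_balance_gam <- function(rows, config = run_config()) {
  .fit_gam(rows, "continuous_balance", config)
}

#' @export
print.vli_gam <- function(x, ...) {
  cat("<vli_gam> outcome:", x$outcome_kind, " n =", x$n, "\n")
  cat("  smooth term: edf =", round(x$edf, 2),
      " p =", format.pval(x$smooth_p_value, digits = 3), "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Quartile-contrast model (Q1 reference)
#'
#' Generalized linear model with the VLI quartile as a 4-level factor plus
#' the adjustment covariates: logit link for in-hospital death (effects
#' exponentiated to odds ratios with Wald confidence intervals), identity
#' link for the 36-84 h balance (mean differences in ml +/- SE).
#'
#' @param rows cohort rows with `vli_quartile` assigned.
#' @param outcome_kind `"binary_death"` or `"continuous_balance"`.
#' @param covariates character vector of adjustment covariates; use
#'   `character(0)` for an unadjusted contrast.
#' @param ci_level confidence level, default 0.95.
#' @return object of class `vli_quartile_effects`: a data frame with one
#'   row per quartile (`estimate` is an OR for death — Q1 fixed at 1 — or
#'   a mean difference in ml — Q1 fixed at 0), `conf_lo`, `conf_hi`, `se`
#'   (link scale), `p_value`, plus the underlying `glm` in
#'   `attr(, "model")`.
#' @export
fit_quartile_model <- function(rows, outcome_kind = c("binary_death",
                                                      "continuous_balance"),
                               covariates = .model_covariates,
                               ci_level = 0.95) {
  outcome_kind <- match.arg(outcome_kind)
  outcome_col <- switch(outcome_kind,
                        binary_death = "died_in_hospital",
                        continuous_balance = "outcome_balance_ml")
  prep <- .prepare_model_rows(rows, outcome_col, covariates)
  rows <- prep$rows; covs <- prep$covariates
  rows$vli_quartile <- droplevels(rows$vli_quartile)
  qlev <- levels(rows$vli_quartile)
  if (qlev[1] != "Q1")
    stop("Q1 must be present as the reference quartile", call. = FALSE)

  if (outcome_kind == "binary_death") {
    ev <- tapply(rows[[outcome_col]], rows$vli_quartile, sum)
    tot <- table(rows$vli_quartile)
    if (any(ev == 0) || any(ev == tot)) {
      bad <- qlev[ev == 0 | ev == tot]
      stop("quartile(s) ", paste(bad, collapse = ", "),
           " have all-or-none events; Wald intervals are undefined ",
           "(exact methods required)", call. = FALSE)
    }
  }

  fam <- switch(outcome_kind,
                binary_death = stats::binomial(),
                continuous_balance = stats::gaussian())
  rhs <- c("vli_quartile", covs)
  form <- stats::as.formula(paste(outcome_col, "~", paste(rhs, collapse = " + ")))
  fit <- stats::glm(form, family = fam, data = rows,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))

  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  sm <- summary(fit)$coefficients
  out <- lapply(qlev, function(q) {
    if (q == qlev[1]) {
      est <- if (outcome_kind == "binary_death") 1 else 0
      return(data.frame(quartile = q, estimate = est, conf_lo = NA_real_,
                        conf_hi = NA_real_, se = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    nm <- paste0("vli_quartile", q)
    b <- sm[nm, "Estimate"]; se <- sm[nm, "Std. Error"]
    p <- sm[nm, 4]
    if (outcome_kind == "binary_death")
      data.frame(quartile = q, estimate = exp(b), conf_lo = exp(b - z * se),
                 conf_hi = exp(b + z * se), se = se, p_value = p,
                 stringsAsFactors = FALSE)
    else
      data.frame(quartile = q, estimate = b, conf_lo = b - z * se,
                 conf_hi = b + z * se, se = se, p_value = p,
                 stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "model") <- fit
  attr(res, "outcome_kind") <- outcome_kind
  attr(res, "ci_level") <- ci_level
  class(res) <- c("vli_quartile_effects", "data.frame")
  res
}

#' @export
print.vli_quartile_effects <- function(x, ...) {
  kind <- attr(x, "outcome_kind")
  lab <- if (kind == "binary_death") "odds ratio" else "mean difference (ml)"
  cat("Quartile contrasts vs Q1 (", lab, "):\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Partial-effect curve of the fitted smooth
#'
#' Evaluates the fitted outcome over an evenly spaced grid of index values
#' with covariates held at reference (numeric means, modal sex), with a
#' pointwise Wald confidence band computed on the link scale and mapped to
#' the response scale (so death-probability bands stay inside \[0, 1\]).
#' Grid points outside the observed index range are clipped with a
#' warning.
#'
#' @param object a `vli_gam`.
#' @param n_grid number of grid points (ignored when `grid` given).
#' @param grid optional explicit grid of index values.
#' @param ci_level confidence level; defaults to the fit's.
#' @return data frame of class `vli_partial_effect`: `vli`, `fit`, `lo`,
#'   `hi` on the response scale.
#' @export
predict_partial_effect <- function(object, n_grid = 100, grid = NULL,
                                   ci_level = NULL) {
  stopifnot(inherits(object, "vli_gam"))
  if (is.null(ci_level)) ci_level <- object$ci_level
  rng <- object$vli_range
  if (is.null(grid)) {
    grid <- seq(rng[1], rng[2], length.out = n_grid)
  } else if (any(grid < rng[1] | grid > rng[2])) {
    warning("grid values outside the observed VLI range were clipped",
            call. = FALSE)
    grid <- pmin(pmax(grid, rng[1]), rng[2])
  }
  nd <- data.frame(vli = grid)
  for (cv in names(object$reference)) nd[[cv]] <- object$reference[[cv]]
  pr <- mgcv::predict.gam(object$fit, newdata = nd, type = "link",
                          se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  inv <- object$fit$family$linkinv
  out <- data.frame(vli = grid,
                    fit = inv(pr$fit),
                    lo = inv(pr$fit - z * pr$se.fit),
                    hi = inv(pr$fit + z * pr$se.fit))
  class(out) <- c("vli_partial_effect", "data.frame")
  attr(out, "outcome_kind") <- object$outcome_kind
  out
}

#' Plot a partial-effect curve with its confidence band
#'
#' @param x a `vli_partial_effect`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vli_partial_effect <- function(x, ...) {
  kind <- attr(x, "outcome_kind")
  ylab <- if (identical(kind, "binary_death"))
    "Probability of in-hospital death" else "36-84 h fluid balance (ml)"
  graphics::plot(x$vli, x$fit, type = "n", xlab = "Vascular leak index",
                 ylab = ylab, ylim = range(c(x$lo, x$hi)), ...)
  graphics::polygon(c(x$vli, rev(x$vli)), c(x$lo, rev(x$hi)),
                    col = grDevices::adjustcolor("grey40", alpha.f = 0.3),
                    border = NA)
  graphics::lines(x$vli, x$fit, col = "steelblue4", lwd = 2)
  invisible(x)
}
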