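#' Default covariate adjustment set
#'
#' The full multivariable adjustment used throughout the analyses: age,
#' sex, race, smoking, drinking, BMI, physical activity (MET), Townsend
#' deprivation index, healthy-diet group, hypertension, supplement and
#' medication use, and baseline CVD, cancer, diabetes and respiratory
#' disease.
#'
#' @return Character vector of cohort column names.
#' @export
default_adjustment <- function() {
  c("age_baseline", "sex", "race_british", "smoking", "drinking", "bmi",
    "met_minutes", "townsend", "healthy_diet_flag", "hypertension",
    "mineral_supp", "vitamin_supp", "nsaid", "chol_med",
    "cvd", "cancer", "diabetes", "respiratory")
}

.check_model_cols <- function(data, cols, covariates = cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("model column(s) not found: ", paste(miss, collapse = ", "))
  for (cl in intersect(covariates, cols)) {
    x <- data[[cl]]
    if (length(unique(x[!is.na(x)])) < 2)
      stop("covariate '", cl, "' is constant; drop it from the model")
  }
}

.cox_formula <- function(time, event, terms) {
  stats::as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                           paste(terms, collapse = " + ")))
}

#' Fit a Cox proportional-hazards model for a grouped exposure
#'
#' Maximises the partial likelihood (Efron tie correction by default) for
#' an exposure factor (reference = first level, conventionally Q1) plus an
#' adjustment set, and reports hazard ratios with Wald 95% CIs
#' (`exp(beta +/- 1.96 se)`) for each non-reference exposure level.
#'
#' @param data Cohort data frame.
#' @param time,event Column names of follow-up time (years) and the 0/1
#'   event indicator.
#' @param exposure Column name of the exposure; coerced to factor.
#' @param adjust Character vector of adjustment covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `infla_cox`: list with the underlying
#'   `coxph` fit, an `estimates` data frame (one row per exposure level
#'   incl. the reference), `n_events`, `n_total`.
#' @export
cox_fit <- function(data, time, event, exposure, adjust = character(),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .check_model_cols(data, c(time, event, exposure, adjust),
                    covariates = c(exposure, adjust))
  data <- data[stats::complete.cases(data[c(time, event, exposure, adjust)]), ,
               drop = FALSE]
  if (!is.factor(data[[exposure]])) data[[exposure]] <- factor(data[[exposure]])
  data[[exposure]] <- droplevels(data[[exposure]])
  n_events <- sum(data[[event]])
  if (n_events < 1) stop("no events in the analysis data")
  fit <- survival::coxph(.cox_formula(time, event, c(exposure, adjust)),
                         data = data, ties = ties, model = TRUE)
  levs <- levels(data[[exposure]])
  terms <- paste0(exposure, levs[-1])
  beta <- stats::coef(fit)[terms]
  if (any(is.na(beta)))
    stop("inestimable exposure level(s) (possible separation): ",
         paste(levs[-1][is.na(beta)], collapse = ", "))
  se <- sqrt(diag(fit$var))[match(terms, names(stats::coef(fit)))]
  est <- data.frame(
    level = levs,
    hr = c(1, exp(beta)),
    ci_low = c(NA, exp(beta - 1.96 * se)),
    ci_high = c(NA, exp(beta + 1.96 * se)),
    log_hr_se = c(NA, se),
    p = c(NA, 2 * stats::pnorm(-abs(beta / se))),
    n = as.vector(table(data[[exposure]])),
    events = as.vector(tapply(data[[event]], data[[exposure]], sum)),
    row.names = NULL)
  structure(list(fit = fit, estimates = est, exposure = exposure,
                 adjust = adjust, ties = ties,
                 n_events = n_events, n_total = nrow(data)),
            class = "infla_cox")
}

#' @export
print.infla_cox <- function(x, digits = 3, ...) {
  cat("Cox model (", x$ties, " ties): ", x$exposure, ", ",
      x$n_events, "/", x$n_total, " events/participants\n", sep = "")
  est <- x$estimates
  est$hr <- round(est$hr, digits)
  est$ci_low <- round(est$ci_low, digits)
  est$ci_high <- round(est$ci_high, digits)
  print.data.frame(est[c("level", "n", "events", "hr", "ci_low", "ci_high")],
                   row.names = FALSE)
  invisible(x)
}

#' @export
coef.infla_cox <- function(object, ...) stats::coef(object$fit)

#' @export
summary.infla_cox <- function(object, ...) summary(object$fit, ...)

#' Trend test across ordered exposure groups
#'
#' Refits the model with the exposure coded as a single ordinal term
#' (1..k across groups) and reports the Wald p-value for that coefficient
#' ("P for trend").
#'
#' @inheritParams cox_fit
#' @return List with `p_trend`, `coef` (log-hazard per one-group step) and
#'   `se`.
#' @export
trend_test <- function(data, time, event, exposure, adjust = character(),
                       ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .check_model_cols(data, c(time, event, exposure, adjust),
                    covariates = c(exposure, adjust))
  x <- data[[exposure]]
  if (!is.factor(x)) x <- factor(x)
  if (nlevels(droplevels(x)) < 2)
    stop("trend test needs at least two exposure groups")
  data$.trend <- as.integer(droplevels(x))
  keep <- stats::complete.cases(data[c(time, event, ".trend", adjust)])
  fit <- survival::coxph(.cox_formula(time, event, c(".trend", adjust)),
                         data = data[keep, , drop = FALSE], ties = ties)
  b <- stats::coef(fit)[".trend"]
  se <- sqrt(fit$var[1, 1])
  list(p_trend = unname(2 * stats::pnorm(-abs(b / se))),
       coef = unname(b), se = se)
}

#' Restricted cubic spline dose-response curve
#'
#' Fits the continuous exposure through a natural (restricted) cubic
#' spline basis in a Cox model; by default 4 knots placed at the 5th, 35th,
#' 65th and 95th percentiles (outer knots as boundary knots, so the fitted
#' log-hazard is linear beyond them). The hazard-ratio curve is referenced
#' to the exposure median (HR = 1 there), and departure from linearity is
#' tested by a likelihood-ratio test of the nonlinear spline terms against
#' a model linear in the exposure.
#'
#' @inheritParams cox_fit
#' @param score Column name of the continuous exposure.
#' @param knot_quantiles Knot placement quantiles (first and last are
#'   boundary knots); must give distinct knot values.
#' @param grid_n Number of points in the reported curve.
#' @return Object of class `rcs_curve`: list with `curve` (data frame
#'   `score`, `hr`, `ci_low`, `ci_high`), `p_nonlinearity`, `knots`,
#'   `ref` (reference score value) and the spline `fit`.
#' @export
rcs_curve <- function(data, score, time, event, adjust = character(),
                      knot_quantiles = c(0.05, 0.35, 0.65, 0.95),
                      grid_n = 100, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .check_model_cols(data, c(time, event, score, adjust),
                    covariates = c(score, adjust))
  data <- data[stats::complete.cases(data[c(time, event, score, adjust)]), ,
               drop = FALSE]
  x <- data[[score]]
  knots <- stats::quantile(x, probs = knot_quantiles, names = FALSE, type = 7)
  if (any(diff(knots) <= 0))
    stop("spline knots are not distinct; choose other quantiles")
  inner <- knots[-c(1, length(knots))]
  bound <- knots[c(1, length(knots))]
  basis <- splines::ns(x, knots = inner, Boundary.knots = bound)
  df <- ncol(basis)
  bn <- paste0(".rcs", seq_len(df))
  data[bn] <- as.data.frame(unclass(basis))
  fit_s <- survival::coxph(.cox_formula(time, event, c(bn, adjust)),
                           data = data, ties = ties)
  fit_l <- survival::coxph(.cox_formula(time, event, c(score, adjust)),
                           data = data, ties = ties)
  lrt <- 2 * (fit_s$loglik[2] - fit_l$loglik[2])
  p_nl <- stats::pchisq(max(lrt, 0), df = df - 1, lower.tail = FALSE)
  ref <- stats::median(x)
  grid <- sort(unique(c(seq(min(x), max(x), length.out = grid_n), ref)))
  B <- stats::predict(basis, grid)
  Bref <- stats::predict(basis, ref)
  D <- sweep(B, 2, Bref)
  beta <- stats::coef(fit_s)[bn]
  V <- fit_s$var[seq_len(df), seq_len(df), drop = FALSE]
  lp <- drop(D %*% beta)
  se <- sqrt(pmax(rowSums((D %*% V) * D), 0))
  structure(list(curve = data.frame(score = grid, hr = exp(lp),
                                    ci_low = exp(lp - 1.96 * se),
                                    ci_high = exp(lp + 1.96 * se)),
                 p_nonlinearity = p_nl, knots = knots, ref = ref,
                 fit = fit_s),
            class = "rcs_curve")
}

#' @export
print.rcs_curve <- function(x, ...) {
  cat("Restricted cubic spline curve: ", length(x$knots), " knots at ",
      paste(signif(x$knots, 4), collapse = ", "),
      "; reference ", signif(x$ref, 4), "\n",
      "P for non-linearity = ", format.pval(x$p_nonlinearity, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.rcs_curve <- function(x, xlab = "score", ylab = "Hazard ratio", ...) {
  cv <- x$curve
  graphics::plot(cv$score, cv$hr, type = "l", log = "y",
                 ylim = range(cv$ci_low, cv$ci_high), xlab = xlab,
                 ylab = ylab, ...)
  graphics::lines(cv$score, cv$ci_low, lty = 2)
  graphics::lines(cv$score, cv$ci_high, lty = 2)
  graphics::abline(h = 1, col = "grey")
  graphics::rug(x$knots)
  invisible(x)
}

#' Proportional-hazards smoke check
#'
#' Schoenfeld-residual test of the proportional-hazards assumption for a
#' fitted model — a smoke check, not a diagnostic suite.
#'
#' @param fit An `infla_cox` object from [cox_fit()].
#' @return The `survival::cox.zph` table (`chisq`, `df`, `p` per term).
#' @export
ph_check <- function(fit) {
  if (!inherits(fit, "infla_cox")) stop("fit must be an infla_cox object")
  survival::cox.zph(fit$fit)$table
}

#' Subgroup (stratified) analysis runner
#'
#' Fits the exposure model independently within each level of a
#' stratifying variable, with the stratifier removed from the adjustment
#' set. Strata in which the model is inestimable (e.g. no events) are
#' reported with `NA` estimates rather than aborting the run.
#'
#' @inheritParams cox_fit
#' @param by Column name of the stratifying variable.
#' @return Data frame of per-level estimates with a `stratum` column, plus
#'   a `p_trend` per stratum.
#' @export
subgroup_run <- function(data, by, time, event, exposure,
                         adjust = default_adjustment(),
                         ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!by %in% names(data)) stop("unknown stratifier: ", by)
  adj <- setdiff(adjust, by)
  g <- factor(data[[by]])
  out <- lapply(levels(g), function(lv) {
    sub <- data[!is.na(g) & g == lv, , drop = FALSE]
    res <- tryCatch({
      f <- cox_fit(sub, time, event, exposure, adj, ties)
      tt <- trend_test(sub, time, event, exposure, adj, ties)
      cbind(stratum = lv, f$estimates, p_trend = tt$p_trend)
    }, error = function(e) {
      levs <- levels(factor(data[[exposure]]))
      data.frame(stratum = lv, level = levs, hr = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, log_hr_se = NA_real_,
                 p = NA_real_, n = NA_integer_, events = NA_integer_,
                 p_trend = NA_real_)
    })
    res
  })
  do.call(rbind, out)
}

#' Sensitivity analysis runner
#'
#' Three pre-specified sensitivity analyses: (1) exclude participants with
#' prevalent CVD, cancer, diabetes or respiratory disease at baseline;
#' (2) re-divide the exposure score into quintiles and refit; (3) exclude
#' participants with follow-up shorter than two years.
#'
#' @inheritParams cox_fit
#' @param which 1, 2 or 3.
#' @param score_col Continuous score column used for re-binning (analysis
#'   2 only).
#' @return List with `which`, `n_retained`, the refitted `fit`
#'   (`infla_cox`) and its `estimates`.
#' @export
sensitivity_run <- function(data, which, time, event, exposure,
                            adjust = default_adjustment(),
                            score_col = "infla_score",
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(which %in% 1:3)
  if (which == 1) {
    flags <- c("cvd", "cancer", "diabetes", "respiratory")
    miss <- setdiff(flags, names(data))
    if (length(miss)) stop("missing disease flag column(s): ",
                           paste(miss, collapse = ", "))
    keep <- rowSums(data[flags] == 1, na.rm = TRUE) == 0
    data <- data[keep, , drop = FALSE]
  } else if (which == 3) {
    data <- data[!is.na(data[[time]]) & data[[time]] >= 2, , drop = FALSE]
  }
  if (nrow(data) == 0) stop("sensitivity filter removed every participant")
  if (which == 2) {
    if (!score_col %in% names(data)) stop("missing score column: ", score_col)
    data$.quintile <- bin_exposure(data[[score_col]], k = 5)
    exposure <- ".quintile"
  }
  fit <- cox_fit(data, time, event, exposure, adjust, ties)
  list(which = which, n_retained = nrow(data), fit = fit,
       estimates = fit$estimates)
}
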