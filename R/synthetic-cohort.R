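#' Default biomarker distribution parameters
#'
#' Marginal moments matched to the overall column of the cohort
#' characteristics the generator emulates: CRP 2.59 +/- 4.34 mg/L
#' (right-skewed, log-normal), platelet 253 +/- 60, neutrophil
#' 4.22 +/- 1.41 and lymphocyte 1.96 +/- 1.13 (10^9 cells/L,
#' gamma-distributed for positivity). White blood cell count is derived as
#' neutrophils + lymphocytes + a residual granulocyte/monocyte component
#' (`wbc_other`), so the differential is internally consistent and the WBC
#' mean matches 6.88. Caps are clinically plausible truncation points.
#'
#' @return Named list of per-marker `list(dist, mean, sd, cap)`.
#' @export
default_biomarker_params <- function() {
  list(crp = list(dist = "lognormal", mean = 2.59, sd = 4.34, cap = 80),
       plt = list(dist = "gamma", mean = 253, sd = 60, cap = 1000),
       neut = list(dist = "gamma", mean = 4.22, sd = 1.41, cap = 25),
       lymph = list(dist = "gamma", mean = 1.96, sd = 1.13, cap = 12),
       wbc_other = list(dist = "gamma", mean = 0.70, sd = 0.60, cap = 10))
}

#' Default covariate prevalences
#'
#' Binary-flag prevalences matched to the emulated cohort: hypertension
#' 27%, CVD 38%, cancer 2.4%, diabetes 6.5%, respiratory disease 9.1%,
#' mineral supplements 43%, vitamin supplements 32%, NSAID use 44%,
#' cholesterol/blood-pressure/diabetes medication 17%, British ancestry
#' 88%; smoking never/previous/current 55/35/10% and drinking 5/3/92%.
#'
#' @return Named list of fractions (and multinomial probability vectors).
#' @export
default_covariate_prevalences <- function() {
  list(hypertension = 0.27, cvd = 0.38, cancer = 0.024, diabetes = 0.065,
       respiratory = 0.091, mineral_supp = 0.43, vitamin_supp = 0.32,
       nsaid = 0.44, chol_med = 0.17, race_british = 0.88,
       smoking = c(never = 0.55, previous = 0.35, current = 0.10),
       drinking = c(never = 0.05, previous = 0.03, current = 0.92))
}

#' Default dietary component distributions
#'
#' Gamma marginals (mean, sd) for food-group intakes, with the direction
#' in which the shared latent lifestyle factor loads: +1 components rise
#' in healthier lifestyles, -1 components fall, 0 components are
#' uncorrelated with it.
#'
#' @return Data frame with columns `column`, `mean`, `sd`, `direction`.
#' @export
default_diet_params <- function() {
  data.frame(
    column = c("red_meat_wk", "vegetables_day", "fruit_day",
               "whole_fruit_day", "fish_wk", "grains_wk", "whole_grains_day",
               "refined_grains_day", "greens_beans_day", "legumes_day",
               "nuts_day", "dairy_day", "lowfat_dairy_day", "protein_day",
               "seafood_plant_day", "fa_ratio", "mufa_sfa_ratio",
               "alcohol_g_day", "sodium_mg_day", "urinary_na",
               "sweet_beverages_day", "added_sugar_pct_energy",
               "sat_fat_pct_energy", "energy_kcal"),
    mean = c(2.5, 4.0, 2.5, 0.8, 2.0, 6.0, 1.0, 2.0, 0.3, 0.4, 0.5, 1.5,
             0.8, 5.5, 0.7, 1.8, 1.1, 14, 2500, 77, 0.8, 12, 11, 2100),
    sd = c(1.5, 2.5, 1.5, 0.5, 1.5, 3.0, 0.8, 1.0, 0.25, 0.35, 0.5, 0.8,
           0.6, 1.8, 0.5, 0.5, 0.3, 14, 800, 27, 0.8, 5, 3, 500),
    direction = c(-1, 1, 1, 1, 1, 1, 1, -1, 1, 1, 1, 0, 1, 0, 1, 1, 1, 0,
                  -1, -1, -1, -1, -1, 0))
}

.check_fraction <- function(x, nm) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("'", nm, "' must be a fraction in [0, 1]")
}

#' Synthetic cohort configuration
#'
#' Bundles and validates every knob of the synthetic cohort generator:
#' demographics, biomarker and diet marginals, dependence structure, the
#' proportional-hazards event process (Weibull age increment; exponential
#' when `shape = 1`), loss to follow-up, and the administrative censoring
#' horizon. Identical `(config, seed)` pairs yield byte-identical cohorts.
#'
#' @param n_participants Cohort size (>= 0).
#' @param seed Integer RNG seed.
#' @param prop_male Fraction of men (default 0.54).
#' @param age_mean,age_sd,age_range Baseline age law (normal, truncated to
#'   the recruitment window 40-70 years).
#' @param biomarker_params See [default_biomarker_params()].
#' @param biomarker_correlation Latent exchangeable correlation among the
#'   blood markers (free parameter; the emulated study does not report
#'   cross-marker correlations). Default 0.3.
#' @param lifestyle_loading Loading of the shared latent lifestyle factor
#'   that induces the diet-inflammation correlation needed by the joint
#'   analyses. Default 0.3.
#' @param covariate_prevalences See [default_covariate_prevalences()].
#' @param diet_component_params See [default_diet_params()].
#' @param true_log_hrs Named log hazard ratios for premature death by
#'   INFLA-Score quartile (Q1 is the reference and must be 0).
#' @param hosp_log_hrs Same, for the age-related hospitalization process.
#' @param covariate_log_hrs Log hazard ratios for `age` (per year,
#'   centred at 57) and `man`, applied to both processes.
#' @param diet_log_hrs Named log hazard ratios for the MED-score tertile
#'   main effect (applied to both processes; T1 reference). The default
#'   gives a modest protective gradient so joint diet-by-inflammation
#'   cells carry their own signal.
#' @param tertile_attenuation Multiplier on the quartile log hazard ratios
#'   by MED-score tertile (effect-modification truth; default no
#'   attenuation).
#' @param baseline_hazard List: Weibull `shape` and `scale` (years) of the
#'   death process and exponential `hosp_rate` (events/person-year) of the
#'   hospitalization process. Defaults give roughly 5% premature deaths
#'   and 25% age-related hospitalizations over the ~13-year follow-up.
#' @param recruit_start,recruit_end Baseline date window (uniform).
#' @param admin_censor_date Administrative censoring date; with the default
#'   recruitment window this yields a median follow-up close to 12.65
#'   years once loss to follow-up is applied.
#' @param loss_to_followup_rate Per-year loss rate (exponential,
#'   independent of the event process).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 10000, seed = 1L,
                          prop_male = 0.54,
                          age_mean = 57, age_sd = 8, age_range = c(40, 70),
                          biomarker_params = default_biomarker_params(),
                          biomarker_correlation = 0.3,
                          lifestyle_loading = 0.3,
                          covariate_prevalences = default_covariate_prevalences(),
                          diet_component_params = default_diet_params(),
                          true_log_hrs = c(Q1 = 0, Q2 = log(1.1),
                                           Q3 = log(1.25), Q4 = log(1.6)),
                          hosp_log_hrs = c(Q1 = 0, Q2 = log(1.04),
                                           Q3 = log(1.09), Q4 = log(1.2)),
                          covariate_log_hrs = c(age = 0.09, man = 0.45),
                          diet_log_hrs = c(T1 = 0, T2 = -0.08, T3 = -0.15),
                          tertile_attenuation = c(T1 = 1, T2 = 1, T3 = 1),
                          baseline_hazard = list(shape = 1.1, scale = 180,
                                                 hosp_rate = 0.02),
                          recruit_start = "2006-03-13",
                          recruit_end = "2010-10-01",
                          admin_censor_date = "2022-02-01",
                          loss_to_followup_rate = 0.01) {
  if (!is.numeric(n_participants) || n_participants < 0 ||
      n_participants != round(n_participants))
    stop("n_participants must be a non-negative integer")
  .check_fraction(prop_male, "prop_male")
  .check_fraction(biomarker_correlation, "biomarker_correlation")
  .check_fraction(lifestyle_loading, "lifestyle_loading")
  if (age_sd <= 0) stop("age_sd must be > 0")
  for (nm in names(biomarker_params)) {
    p <- biomarker_params[[nm]]
    if (p$mean <= 0 || p$sd <= 0)
      stop("biomarker '", nm, "' must have positive mean and sd")
  }
  if (any(diet_component_params$mean <= 0) ||
      any(diet_component_params$sd <= 0))
    stop("diet component distributions must have positive mean and sd")
  for (nm in c("hypertension", "cvd", "cancer", "diabetes", "respiratory",
               "mineral_supp", "vitamin_supp", "nsaid", "chol_med",
               "race_british"))
    .check_fraction(covariate_prevalences[[nm]], nm)
  if (true_log_hrs[["Q1"]] != 0)
    stop("true_log_hrs must have Q1 = 0 (reference)")
  if (diet_log_hrs[["T1"]] != 0)
    stop("diet_log_hrs must have T1 = 0 (reference)")
  if (baseline_hazard$shape <= 0 || baseline_hazard$scale <= 0 ||
      baseline_hazard$hosp_rate < 0)
    stop("baseline_hazard shape/scale must be > 0 and hosp_rate >= 0")
  if (loss_to_followup_rate < 0) stop("loss_to_followup_rate must be >= 0")
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed), prop_male = prop_male,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 biomarker_params = biomarker_params,
                 biomarker_correlation = biomarker_correlation,
                 lifestyle_loading = lifestyle_loading,
                 covariate_prevalences = covariate_prevalences,
                 diet_component_params = diet_component_params,
                 true_log_hrs = true_log_hrs, hosp_log_hrs = hosp_log_hrs,
                 covariate_log_hrs = covariate_log_hrs,
                 diet_log_hrs = diet_log_hrs,
                 tertile_attenuation = tertile_attenuation,
                 baseline_hazard = baseline_hazard,
                 recruit_start = as.Date(recruit_start),
                 recruit_end = as.Date(recruit_end),
                 admin_censor_date = as.Date(admin_censor_date),
                 loss_to_followup_rate = loss_to_followup_rate),
            class = "cohort_config")
}

# marginal quantile transform of a standard-normal latent
.marginal_from_latent <- function(z, p) {
  u <- stats::pnorm(z)
  x <- switch(p$dist,
    lognormal = {
      sdlog <- sqrt(log(1 + (p$sd / p$mean)^2))
      stats::qlnorm(u, meanlog = log(p$mean) - sdlog^2 / 2, sdlog = sdlog)
    },
    gamma = {
      shape <- (p$mean / p$sd)^2
      stats::qgamma(u, shape = shape, scale = p$sd^2 / p$mean)
    },
    stop("unknown marginal distribution: ", p$dist))
  if (!is.null(p$cap)) x <- pmin(x, p$cap)
  x
}

.empty_cohort <- function(cfg) {
  g <- generate_cohort(cohort_config(
    n_participants = 2, seed = 1L,
    biomarker_params = cfg$biomarker_params,
    diet_component_params = cfg$diet_component_params))
  g[0, , drop = FALSE]
}

#' Generate a synthetic UK-Biobank-like cohort
#'
#' Draws a participant table with correlated blood inflammatory markers
#' (Gaussian copula with a shared latent lifestyle factor that also drives
#' dietary intakes), demographics and covariate flags, dietary components,
#' and follow-up: death times from a Weibull proportional-hazards process
#' on the age scale whose log hazard is the participant's (eventual)
#' INFLA-Score quartile effect -- optionally attenuated by MED-score
#' tertile -- plus age and sex terms; an independent exponential
#' age-related hospitalization process; exponential loss to follow-up; and
#' administrative censoring at a fixed calendar date. Deaths receive an
#' ICD-10 cause code, hospitalizations a code from the aging-disease list.
#'
#' The generator computes the INFLA-Score and MED tertile internally (on
#' the generated cohort itself) only to assign the true effects; the truth
#' is exposed in `true_infla_q` / `true_med_t` for parameter-recovery
#' studies, while analysis columns are recomputed by the scoring modules.
#'
#' @param config A [cohort_config()].
#' @return Data frame, one row per participant; zero-row with full schema
#'   when `n_participants = 0`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("config must be a cohort_config object")
  if (config$n_participants == 0) return(.empty_cohort(config))
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(config$seed)
  n <- config$n_participants
  cp <- config$covariate_prevalences

  # demographics
  sex <- ifelse(stats::runif(n) < config$prop_male, "man", "woman")
  plo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  phi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- stats::qnorm(stats::runif(n, plo, phi), config$age_mean,
                      config$age_sd)
  # recruitment ramped up over the window, so draw dates with a late skew;
  # with censoring at 2022-02-01 this gives a median follow-up near 12.65 y
  baseline_date <- config$recruit_start +
    floor(sqrt(stats::runif(n)) * as.numeric(config$recruit_end -
                                               config$recruit_start + 1))

  # latent structure: lifestyle factor L (higher = less healthy), shared
  # biomarker factor f, idiosyncratic noise
  L <- stats::rnorm(n)
  f <- stats::rnorm(n)
  lam <- config$lifestyle_loading
  rho <- config$biomarker_correlation
  bm <- config$biomarker_params
  draw_marker <- function(p) {
    u <- sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n)
    .marginal_from_latent(sqrt(1 - lam^2) * u + lam * L, p)
  }
  crp <- draw_marker(bm$crp)
  plt <- draw_marker(bm$plt)
  neut <- draw_marker(bm$neut)
  lymph <- pmax(draw_marker(bm$lymph), 0.05) # NLR must be defined
  wbc <- neut + lymph + draw_marker(bm$wbc_other)

  # covariates
  rmult <- function(p) {
    u <- stats::runif(n)
    names(p)[1L + (u > p[1]) + (u > p[1] + p[2])]
  }
  covs <- data.frame(
    bmi = pmin(pmax(stats::rnorm(n, 27.4, 4.8), 15), 60),
    met_minutes = .marginal_from_latent(stats::rnorm(n),
                                        list(dist = "gamma", mean = 2000,
                                             sd = 1800)),
    townsend = stats::rnorm(n, -1.32, 3.08),
    smoking = rmult(cp$smoking), drinking = rmult(cp$drinking))
  for (nm in c("hypertension", "cvd", "cancer", "diabetes", "respiratory",
               "mineral_supp", "vitamin_supp", "nsaid", "chol_med",
               "race_british"))
    covs[[nm]] <- as.integer(stats::runif(n) < cp[[nm]])

  # dietary components: gamma marginals tied to the lifestyle factor
  dp <- config$diet_component_params
  diet <- as.data.frame(lapply(seq_len(nrow(dp)), function(i) {
    z <- sqrt(1 - lam^2) * stats::rnorm(n) - dp$direction[i] * lam * L
    .marginal_from_latent(z, list(dist = "gamma", mean = dp$mean[i],
                                  sd = dp$sd[i]))
  }))
  names(diet) <- dp$column
  diet$n_recalls <- sample(1:5, n, replace = TRUE)

  cohort <- data.frame(id = seq_len(n), sex = sex, age_baseline = age,
                       baseline_date = baseline_date,
                       crp = crp, wbc = wbc, plt = plt, neut = neut,
                       lymph = lymph, covs, diet)

  # truth assignment: INFLA quartile and MED tertile on this cohort
  cohort$nlr <- compute_nlr(cohort$neut, cohort$lymph)
  qok <- tryCatch({
    map <- fit_decile_map(cohort)
    sc <- compute_infla_score(cohort, map)$infla_score
    cohort$true_infla_q <- bin_exposure(sc, k = 4)
    TRUE
  }, error = function(e) FALSE)
  if (!qok) cohort$true_infla_q <- factor(rep("Q1", n),
                                          levels = paste0("Q", 1:4))
  tok <- tryCatch({
    cohort$true_med_t <- bin_tertiles(med_score(cohort))
    TRUE
  }, error = function(e) FALSE)
  if (!tok) cohort$true_med_t <- factor(rep("T2", n),
                                        levels = c("T1", "T2", "T3"))

  # event processes
  clh <- config$covariate_log_hrs
  lp_cov <- clh[["age"]] * (cohort$age_baseline - 57) +
    clh[["man"]] * (cohort$sex == "man")
  att <- config$tertile_attenuation[as.character(cohort$true_med_t)]
  lp_diet <- config$diet_log_hrs[as.character(cohort$true_med_t)]
  lp_death <- config$true_log_hrs[as.character(cohort$true_infla_q)] * att +
    lp_diet + lp_cov
  bh <- config$baseline_hazard
  t_death <- bh$scale * (-log(stats::runif(n)) / exp(lp_death))^(1 / bh$shape)
  lp_hosp <- config$hosp_log_hrs[as.character(cohort$true_infla_q)] * att +
    lp_diet + 0.5 * lp_cov
  t_hosp <- if (bh$hosp_rate > 0)
    stats::rexp(n) / (bh$hosp_rate * exp(lp_hosp)) else rep(Inf, n)
  t_loss <- if (config$loss_to_followup_rate > 0)
    stats::rexp(n, config$loss_to_followup_rate) else rep(Inf, n)
  t_admin <- as.numeric(config$admin_censor_date - baseline_date) / 365.25

  observed_death <- t_death <= pmin(t_loss, t_admin)
  observed_loss <- !observed_death & t_loss < t_admin
  t_end <- pmin(t_death, t_loss, t_admin)

  cohort$death_date <- as.Date(ifelse(observed_death,
    baseline_date + round(t_death * 365.25), NA), origin = "1970-01-01")
  cohort$loss_date <- as.Date(ifelse(observed_loss,
    baseline_date + round(t_loss * 365.25), NA), origin = "1970-01-01")

  # cause of death
  cause_codes <- list(
    chd = c("I21", "I25"), stroke = c("I61", "I63", "I64"),
    cancer = c("C18", "C34", "C50", "C61", "C25"),
    respiratory = c("J18", "J44", "J84"), diabetes = c("E11", "E14"),
    other = c("G31", "K72", "N19", "X59"))
  cause_prob <- c(chd = 0.15, stroke = 0.05, cancer = 0.45,
                  respiratory = 0.07, diabetes = 0.02, other = 0.26)
  cohort$death_cause_icd10 <- NA_character_
  nd <- sum(observed_death)
  if (nd > 0) {
    grp <- sample(names(cause_prob), nd, replace = TRUE, prob = cause_prob)
    cohort$death_cause_icd10[observed_death] <-
      vapply(grp, function(g) sample(cause_codes[[g]], 1), character(1))
  }

  # hospitalizations: first age-related admission (if before exit)
  aging_codes <- read_icd10_codes(system.file(
    "extdata", "aging_disease_codes_example.txt", package = "inflascore",
    mustWork = TRUE))
  has_hosp <- t_hosp < t_end
  cohort$hosp_codes <- NA_character_
  cohort$hosp_dates <- NA_character_
  nh <- sum(has_hosp)
  if (nh > 0) {
    cohort$hosp_codes[has_hosp] <- sample(aging_codes, nh, replace = TRUE)
    cohort$hosp_dates[has_hosp] <- format(
      as.Date(baseline_date[has_hosp] + round(t_hosp[has_hosp] * 365.25),
              origin = "1970-01-01"))
  }
  rownames(cohort) <- NULL
  cohort
}

#' Table-1-style cohort summary
#'
#' Per-variable mean +/- SD (continuous) or count (percent) (categorical),
#' overall and -- when a `premature_death` column is present -- stratified
#' by premature-death status.
#'
#' @param cohort Non-empty cohort data frame.
#' @param variables Columns to summarise (default: a standard Table-1
#'   panel of those present).
#' @return Long data frame: `variable`, `level`, `stratum`, `n`, `mean`,
#'   `sd`, `pct`, `formatted`.
#' @export
cohort_summary <- function(cohort, variables = NULL) {
  if (nrow(cohort) == 0)
    stop("empty cohort: nothing to summarise")
  if (is.null(variables)) {
    std <- c("age_baseline", "sex", "race_british", "smoking", "drinking",
             "bmi", "met_minutes", "townsend", "hypertension",
             "mineral_supp", "vitamin_supp", "nsaid", "chol_med", "cvd",
             "cancer", "diabetes", "respiratory", "crp", "wbc", "plt",
             "neut", "lymph")
    variables <- intersect(std, names(cohort))
  }
  strata <- list(overall = rep(TRUE, nrow(cohort)))
  if ("premature_death" %in% names(cohort)) {
    strata$non_premature <- cohort$premature_death == 0
    strata$premature <- cohort$premature_death == 1
  }
  rows <- list()
  for (v in variables) {
    x <- cohort[[v]]
    for (s in names(strata)) {
      xs <- x[strata[[s]]]
      if (is.numeric(xs) && !all(xs %in% c(0, 1, NA))) {
        m <- mean(xs, na.rm = TRUE)
        sd <- stats::sd(xs, na.rm = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = NA_character_, stratum = s,
          n = sum(!is.na(xs)), mean = m, sd = sd, pct = NA_real_,
          formatted = paste0(signif(m, 3), " ± ", signif(sd, 3)))
      } else {
        tab <- table(factor(xs))
        for (lv in names(tab)) {
          pct <- 100 * tab[[lv]] / sum(tab)
          rows[[length(rows) + 1]] <- data.frame(
            variable = v, level = lv, stratum = s, n = tab[[lv]],
            mean = NA_real_, sd = NA_real_, pct = pct,
            formatted = paste0(tab[[lv]], " (", signif(pct, 3), "%)"))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a cohort as CSV
#'
#' RFC-4180 CSV, UTF-8, ISO-8601 dates.
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly (writer); cohort data frame (reader).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (cl in intersect(c("baseline_date", "death_date", "loss_date"),
                       names(co)))
    co[[cl]] <- as.Date(ifelse(co[[cl]] == "", NA, co[[cl]]))
  co
}
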