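#' Read a sex- and age-specific reference life table
#'
#' Expects delimited text with columns `sex`, `age`, `m` (central death
#' rate per person-year). Ages must run contiguously from 40 to 100 within
#' each sex.
#'
#' @param path CSV path. The packaged default,
#'   `uk_life_table_synthetic.csv`, is a synthetic Gompertz-Makeham
#'   schedule calibrated to recent UK national period life expectancies at
#'   ages 40 and 60 — a stand-in for an official national life table, which
#'   should be substituted for real analyses.
#' @return Data frame with columns `sex`, `age`, `m`.
#' @export
read_life_table <- function(path = system.file(
                              "extdata", "uk_life_table_synthetic.csv",
                              package = "inflascore", mustWork = TRUE)) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sex", "age", "m") %in% names(lt)))
    stop("life table must have columns sex, age, m")
  for (s in unique(lt$sex)) {
    a <- sort(lt$age[lt$sex == s])
    if (!identical(as.integer(a), 40:100))
      stop("ages must be contiguous 40..100 for sex '", s, "'")
  }
  if (any(lt$m < 0) || any(!is.finite(lt$m)))
    stop("death rates must be finite and non-negative")
  lt[order(lt$sex, lt$age), c("sex", "age", "m")]
}

#' Exposure-group specification for life-table attribution
#'
#' Holds, for each exposure group (e.g. INFLA-Score quartile), its
#' prevalence and its hazard ratio for premature death relative to the
#' reference group, with 95% CI bounds. Prevalences must sum to 1 and the
#' reference group must have hazard ratio exactly 1.
#'
#' @param prevalence Named numeric vector of group prevalences.
#' @param hr Named numeric vector of hazard ratios (same names).
#' @param ci_low,ci_high Optional CI bounds (default equal to `hr`).
#' @param reference Name of the reference group (default the first).
#' @return Object of class `group_spec`.
#' @export
group_spec <- function(prevalence, hr, ci_low = hr, ci_high = hr,
                       reference = names(hr)[1]) {
  if (is.null(names(hr)) || is.null(names(prevalence)))
    stop("prevalence and hr must be named")
  if (!setequal(names(prevalence), names(hr)))
    stop("prevalence and hr must cover the same groups")
  prevalence <- prevalence[names(hr)]
  if (abs(sum(prevalence) - 1) > 1e-8)
    stop("group prevalences must sum to 1 (got ", sum(prevalence), ")")
  if (any(hr <= 0) || any(ci_low <= 0) || any(ci_high <= 0))
    stop("hazard ratios must be > 0")
  if (!reference %in% names(hr)) stop("unknown reference group")
  if (hr[[reference]] != 1)
    stop("reference group must have hr exactly 1")
  structure(list(prevalence = prevalence, hr = hr,
                 ci_low = ci_low[names(hr)], ci_high = ci_high[names(hr)],
                 reference = reference),
            class = "group_spec")
}

#' Calibrate exposure-group mortality schedules to a reference
#'
#' Splits a reference mortality schedule into per-group schedules that are
#' proportional (group hazard ratios, constant over age) and that mix back
#' to the reference: the reference-group rate is
#' `m_ref(a) / sum_g p_g * hr_g` and group g's rate is `hr_g` times that,
#' so `sum_g p_g * m_g(a) = m_ref(a)` at every age.
#'
#' @param m_ref Numeric vector of reference central death rates by age.
#' @param spec A [group_spec()].
#' @param hr Optional hazard-ratio override (same names as the spec),
#'   e.g. CI bounds; defaults to the point estimates.
#' @return Matrix of rates, one column per group.
#' @export
calibrate_group_rates <- function(m_ref, spec, hr = spec$hr) {
  if (!inherits(spec, "group_spec")) stop("spec must be a group_spec")
  divisor <- sum(spec$prevalence * hr)
  vapply(names(hr), function(g) m_ref * hr[[g]] / divisor,
         numeric(length(m_ref)))
}

#' Build a single-year life table from a mortality schedule
#'
#' Standard abridged life-table arithmetic on 1-year intervals with
#' mid-interval death timing: `q(a) = m(a) / (1 + 0.5 m(a))` (capped at 1),
#' survivorship `l` by recursion from `l(40) = 1`, person-years
#' `L(a) = l(a) - 0.5 d(a)`, terminal closure
#' `L(100) = l(100) / max(m(100), eps)`, and remaining expectancy
#' `e(a) = T(a) / l(a)`.
#'
#' @param m Numeric vector of central death rates for ages `ages`.
#' @param ages Integer ages (default 40..100; the last age is terminal).
#' @return Object of class `group_life_table`: data frame with columns
#'   `age`, `m`, `q`, `l`, `d`, `L`, `T`, `e`.
#' @export
build_life_table <- function(m, ages = 40:100) {
  if (length(m) != length(ages)) stop("m and ages must have equal length")
  if (any(!is.finite(m)) || any(m < 0))
    stop("death rates must be finite and non-negative")
  n <- length(ages)
  q <- pmin(m / (1 + 0.5 * m), 1)
  l <- cumprod(c(1, 1 - q))[seq_len(n)]
  d <- l * q
  L <- l - 0.5 * d
  L[n] <- l[n] / max(m[n], 1e-12)
  T <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, T / l, 0)
  structure(data.frame(age = ages, m = m, q = q, l = l, d = d, L = L,
                       T = T, e = e),
            class = c("group_life_table", "data.frame"))
}

#' @export
print.group_life_table <- function(x, ...) {
  cat("Life table, ages ", min(x$age), "-", max(x$age),
      "; e(", min(x$age), ") = ", round(x$e[1], 2), " y\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE)
  cat("...\n")
  invisible(x)
}

.expectancy_at <- function(lt, age) {
  i <- match(age, lt$age)
  if (is.na(i)) stop("index age ", age, " outside the life-table range")
  lt$e[i]
}

.gaps_for_hr <- function(m_ref, spec, hr, index_ages) {
  rates <- calibrate_group_rates(m_ref, spec, hr)
  e <- sapply(colnames(rates), function(g) {
    lt <- build_life_table(rates[, g])
    vapply(index_ages, function(a) .expectancy_at(lt, a), numeric(1))
  })
  if (is.null(dim(e))) e <- matrix(e, nrow = 1, dimnames = list(NULL, names(e)))
  e[, spec$reference] - e
}

#' Life-expectancy gap versus the reference exposure group
#'
#' For each exposure group, the difference in remaining life expectancy at
#' the index age(s) relative to the reference group, after calibrating
#' proportional group mortality schedules to the reference life table.
#' CI bounds are propagated by re-running the full calibration with the
#' group's hazard ratio set to its CI bound (other groups at their point
#' estimates); a parametric bootstrap (log-normal hazard-ratio draws) is
#' available as an alternative.
#'
#' @param m_ref Reference central death rates, ages 40..100.
#' @param spec A [group_spec()].
#' @param index_ages Ages at which to evaluate the gap (default 40 and 60).
#' @param ci `"substitution"` (default), `"bootstrap"`, or `"none"`.
#' @param boot_reps,boot_seed Bootstrap settings.
#' @return Data frame with columns `group`, `index_age`, `gap_years`,
#'   `gap_low`, `gap_high` (the reference group rows have zero gap).
#' @export
expectancy_gap <- function(m_ref, spec, index_ages = c(40, 60),
                           ci = c("substitution", "bootstrap", "none"),
                           boot_reps = 500, boot_seed = 1L) {
  ci <- match.arg(ci)
  if (any(index_ages < 40 | index_ages > 100))
    stop("index ages must lie within 40..100")
  groups <- names(spec$hr)
  point <- .gaps_for_hr(m_ref, spec, spec$hr, index_ages)
  lo <- hi <- point
  if (ci == "substitution") {
    for (g in setdiff(groups, spec$reference)) {
      for (bound in c("ci_low", "ci_high")) {
        hr_b <- spec$hr
        hr_b[[g]] <- spec[[bound]][[g]]
        gb <- .gaps_for_hr(m_ref, spec, hr_b, index_ages)[, g]
        lo[, g] <- pmin(lo[, g], gb)
        hi[, g] <- pmax(hi[, g], gb)
      }
    }
  } else if (ci == "bootstrap") {
    # log-normal HR draws consistent with the Wald CI
    old <- .Random.seed_exists()
    set.seed(boot_seed)
    on.exit(old(), add = TRUE)
    draws <- array(NA_real_,
                   c(boot_reps, length(index_ages), length(groups)),
                   dimnames = list(NULL, NULL, groups))
    se <- (log(spec$ci_high) - log(spec$ci_low)) / (2 * 1.96)
    for (b in seq_len(boot_reps)) {
      hr_b <- spec$hr
      for (g in setdiff(groups, spec$reference))
        hr_b[[g]] <- exp(stats::rnorm(1, log(spec$hr[[g]]), se[[g]]))
      draws[b, , ] <- .gaps_for_hr(m_ref, spec, hr_b, index_ages)
    }
    lo[] <- apply(draws, c(2, 3), stats::quantile, 0.025)
    hi[] <- apply(draws, c(2, 3), stats::quantile, 0.975)
  }
  data.frame(group = rep(groups, each = length(index_ages)),
             index_age = rep(index_ages, length(groups)),
             gap_years = as.vector(point),
             gap_low = as.vector(lo),
             gap_high = as.vector(hi))
}

# save/restore RNG state so bootstrap CIs do not disturb the caller's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Discrete-cohort simulation of remaining life expectancy
#'
#' Independent oracle for the life-table arithmetic: simulates `n` lives
#' through the 1-year mortality schedule (death probability
#' `q(a) = m(a)/(1 + 0.5 m(a))`, deaths at mid-interval, survivors past the
#' terminal age living `1/m(terminal)` further years on average) and
#' averages the realised lifetimes.
#'
#' @param m Central death rates for `ages`.
#' @param ages Integer ages.
#' @param n Number of simulated lives.
#' @return Mean years lived beyond `ages[1]`.
#' @export
simulate_cohort_expectancy <- function(m, ages = 40:100, n = 1e6) {
  q <- pmin(m / (1 + 0.5 * m), 1)
  k <- length(ages)
  alive <- rep(TRUE, n)
  years <- numeric(n)
  for (i in seq_len(k - 1)) {
    die <- alive & (stats::runif(n) < q[i])
    years[die] <- (i - 1) + 0.5
    alive <- alive & !die
    years[alive] <- i
  }
  # terminal open interval: exponential remaining lifetime at rate m(terminal)
  nterm <- sum(alive)
  if (nterm > 0)
    years[alive] <- (k - 1) + stats::rexp(nterm, rate = max(m[k], 1e-12))
  mean(years)
}
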