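#' Follow-up time and terminal status
#'
#' Person-years are counted from the baseline assessment date until the
#' earliest of death, loss to follow-up, or the administrative censoring
#' date (2022-02-01 by default), whichever comes first. Exactly one
#' terminal status is assigned per participant; on a date tie the death
#' takes precedence over censoring.
#'
#' @param baseline_date Vector of baseline `Date`s.
#' @param death_date,loss_date Optional `Date` vectors (`NA` where absent).
#' @param admin_date Administrative censoring `Date` (scalar).
#' @return Data frame with `time` (years, using 365.25 days/year), `status`
#'   (factor: `death`, `loss`, `admin`) and `exit_date`.
#' @export
follow_up <- function(baseline_date, death_date = NULL, loss_date = NULL,
                      admin_date = as.Date("2022-02-01")) {
  n <- length(baseline_date)
  baseline_date <- as.Date(baseline_date)
  death_date <- if (is.null(death_date)) as.Date(rep(NA, n)) else as.Date(death_date)
  loss_date <- if (is.null(loss_date)) as.Date(rep(NA, n)) else as.Date(loss_date)
  admin <- as.Date(rep(as.Date(admin_date), length.out = n))
  for (d in list(death_date, loss_date)) {
    bad <- !is.na(d) & d < baseline_date
    if (any(bad))
      stop("terminal date precedes baseline date for ", sum(bad), " record(s)")
  }
  cand <- cbind(as.numeric(death_date), as.numeric(loss_date),
                as.numeric(admin))
  exit <- apply(cand, 1, min, na.rm = TRUE)
  # death wins ties; otherwise the earliest date fires
  status <- ifelse(!is.na(death_date) & as.numeric(death_date) == exit, "death",
            ifelse(!is.na(loss_date) & as.numeric(loss_date) == exit, "loss",
                   "admin"))
  data.frame(time = (exit - as.numeric(baseline_date)) / 365.25,
             status = factor(status, levels = c("death", "loss", "admin")),
             exit_date = as.Date(exit, origin = "1970-01-01"))
}

#' Premature-death indicator
#'
#' A death is premature when it occurs strictly before the age threshold
#' (75 years): death at age 74.9 counts, death at exactly 75.0 does not,
#' and participants who did not die are never flagged.
#'
#' @param age_at_death Numeric vector of ages at death (`NA` where the
#'   participant did not die).
#' @param threshold Age threshold in years (default 75).
#' @return Logical vector.
#' @export
premature_flag <- function(age_at_death, threshold = 75) {
  !is.na(age_at_death) & age_at_death < threshold
}

.parse_icd10_range <- function(r) {
  r <- gsub("\\s", "", r)
  if (grepl("^[A-Z][0-9]{2}$", r)) {
    letter <- substr(r, 1, 1)
    lo <- hi <- as.integer(substr(r, 2, 3))
  } else if (grepl("^[A-Z][0-9]{2}-[A-Z]?[0-9]{2}$", r)) {
    letter <- substr(r, 1, 1)
    parts <- strsplit(r, "-", fixed = TRUE)[[1]]
    end <- parts[2]
    if (grepl("^[A-Z]", end)) {
      if (substr(end, 1, 1) != letter)
        stop("ICD-10 range must stay within one letter block: ", r)
      end <- substr(end, 2, nchar(end))
    }
    lo <- as.integer(substr(parts[1], 2, 3))
    hi <- as.integer(end)
  } else stop("malformed ICD-10 range: '", r, "'")
  if (lo > hi) stop("ICD-10 range start exceeds end: ", r)
  paste0(letter, sprintf("%02d", lo:hi))
}

#' Named ICD-10 range groups
#'
#' Builds a validated set of named cause groups from range strings such as
#' `"I20-I25"` (or the compact `"I20-25"`) and single categories such as
#' `"I69"`. Matching is at the 3-character category level; sub-codes are
#' ignored.
#'
#' @param ... Named arguments, each a character vector of ranges/codes.
#' @return Object of class `icd10_ranges`: named list of expanded
#'   3-character code vectors.
#' @export
icd10_ranges <- function(...) {
  groups <- list(...)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("every group must be named")
  out <- lapply(groups, function(g)
    unique(unlist(lapply(g, .parse_icd10_range))))
  structure(out, class = "icd10_ranges")
}

#' Default cause-of-death groups
#'
#' CHD (I20-I25), stroke (I60-I64 plus I69), respiratory disease
#' (J00-J99), cancer (C00-C97) and diabetes (E10-E14); CHD and stroke
#' together constitute cardiovascular disease.
#'
#' @return An `icd10_ranges` object.
#' @export
default_cause_groups <- function() {
  icd10_ranges(chd = "I20-I25",
               stroke = c("I60-I64", "I69"),
               respiratory = "J00-J99",
               cancer = "C00-C97",
               diabetes = "E10-E14")
}

#' Classify an ICD-10 code into a cause group
#'
#' @param icd10 Character vector of ICD-10 codes (e.g. `"I21"`, `"I21.4"`).
#'   Codes must start with a letter followed by two digits.
#' @param ranges An `icd10_ranges` object, default [default_cause_groups()].
#' @return Character vector of group labels; `NA` where the code falls
#'   outside every group.
#' @export
classify_cause <- function(icd10, ranges = default_cause_groups()) {
  if (!inherits(ranges, "icd10_ranges"))
    stop("ranges must be an icd10_ranges object")
  out <- rep(NA_character_, length(icd10))
  ok <- !is.na(icd10)
  bad <- ok & !grepl("^[A-Z][0-9]{2}", icd10)
  if (any(bad))
    stop("malformed ICD-10 code(s): ",
         paste(utils::head(icd10[bad], 5), collapse = ", "))
  cat3 <- substr(icd10, 1, 3)
  for (g in names(ranges))
    out[ok & is.na(out) & cat3 %in% ranges[[g]]] <- g
  out
}

#' Read an aging-disease ICD-10 code list
#'
#' One ICD-10 code or range per line; `#` starts a comment. Ranges are
#' expanded to 3-character categories.
#'
#' @param path Path to the list file.
#' @return Character vector of 3-character codes.
#' @export
read_icd10_codes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("code list '", path, "' contains no codes")
  unique(unlist(lapply(lines, .parse_icd10_range)))
}

#' Age-related hospitalization flag
#'
#' Flags participants with at least one hospitalization whose ICD-10 code
#' falls in the supplied aging-disease code list, returning the earliest
#' qualifying date.
#'
#' @param hospital_codes List (one element per participant) of character
#'   vectors of hospitalization ICD-10 codes.
#' @param hospital_dates List of `Date` vectors parallel to
#'   `hospital_codes`.
#' @param aging_codes Character vector of qualifying 3-character codes
#'   (e.g. from [read_icd10_codes()]); must be non-empty.
#' @return Data frame with logical `aging_hosp` and `first_aging_date`.
#' @export
aging_hospitalization_flag <- function(hospital_codes, hospital_dates,
                                       aging_codes) {
  if (length(aging_codes) == 0)
    stop("aging_codes is empty: supply the age-related disease code list")
  if (length(hospital_codes) != length(hospital_dates))
    stop("hospital_codes and hospital_dates must have equal length")
  res <- mapply(function(codes, dates) {
    if (length(codes) == 0 || all(is.na(codes)))
      return(c(FALSE, NA_real_))
    hit <- substr(codes, 1, 3) %in% aging_codes
    if (!any(hit)) return(c(FALSE, NA_real_))
    c(TRUE, min(as.numeric(as.Date(dates)[hit])))
  }, hospital_codes, hospital_dates)
  data.frame(aging_hosp = as.logical(res[1, ]),
             first_aging_date = as.Date(res[2, ], origin = "1970-01-01"))
}

.split_field <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", NA_character_, x), ";",
                  fixed = TRUE),
         function(v) if (length(v) == 1 && is.na(v)) character(0) else v)
}

#' Derive survival outcomes for a cohort table
#'
#' Appends follow-up time and status, premature-death and age-related
#' hospitalization outcomes to a cohort table (as produced by
#' [generate_cohort()], or any table with the same follow-up columns).
#'
#' For the premature-death analysis, deaths at age 75 or older are treated
#' as censoring events; by default the participant is censored at the death
#' date, or, with `premature_censoring = "age75"`, at the 75th birthday.
#'
#' @param cohort Cohort data frame with `baseline_date`, `age_baseline`,
#'   `death_date`, `loss_date`, `death_cause_icd10`, and semicolon-joined
#'   `hosp_codes` / `hosp_dates` columns.
#' @param aging_codes Aging-disease code vector for the hospitalization
#'   outcome (default: the packaged example list).
#' @param admin_date Administrative censoring date.
#' @param premature_censoring How deaths at >= 75 enter the premature-death
#'   risk set: censored at the death date (`"death"`, default) or at the
#'   75th birthday (`"age75"`).
#' @param cause_groups `icd10_ranges` for cause-of-death classification.
#' @return The cohort with appended columns `time`, `status`,
#'   `age_at_exit`, `premature_death`, `time_premature`, `cause_group`,
#'   `aging_hosp`, `time_aging_hosp`.
#' @export
derive_outcomes <- function(cohort,
                            aging_codes = read_icd10_codes(
                              system.file("extdata",
                                          "aging_disease_codes_example.txt",
                                          package = "inflascore",
                                          mustWork = TRUE)),
                            admin_date = as.Date("2022-02-01"),
                            premature_censoring = c("death", "age75"),
                            cause_groups = default_cause_groups()) {
  premature_censoring <- match.arg(premature_censoring)
  fu <- follow_up(cohort$baseline_date, cohort$death_date, cohort$loss_date,
                  admin_date)
  cohort$time <- fu$time
  cohort$status <- fu$status
  cohort$age_at_exit <- cohort$age_baseline + fu$time
  died <- fu$status == "death"
  cohort$premature_death <- as.integer(died & cohort$age_at_exit < 75)
  cohort$time_premature <- fu$time
  late <- died & cohort$age_at_exit >= 75
  if (premature_censoring == "age75" && any(late))
    cohort$time_premature[late] <- pmin(fu$time[late],
                                        75 - cohort$age_baseline[late])
  cohort$cause_group <- classify_cause(cohort$death_cause_icd10, cause_groups)
  hosp <- aging_hospitalization_flag(.split_field(cohort$hosp_codes),
                                     .split_field(cohort$hosp_dates),
                                     aging_codes)
  cohort$aging_hosp <- as.integer(hosp$aging_hosp)
  t_h <- (as.numeric(hosp$first_aging_date) -
            as.numeric(as.Date(cohort$baseline_date))) / 365.25
  cohort$time_aging_hosp <- ifelse(hosp$aging_hosp, pmin(t_h, fu$time),
                                   fu$time)
  cohort
}
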