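#' Six-point healthy-diet covariate score
#'
#' Awards one point per criterion met: red meat at most 3 times/week,
#' vegetables at least 4 tablespoons/day, fruit at least 3 servings/day,
#' fish at least 4 times/week, grains at least 5 servings/week, and urinary
#' sodium concentration at most 70.6 mmol/L. A total of 3 or more points
#' classifies the participant as following a healthy diet.
#'
#' @param data Data frame with columns `red_meat_wk`, `vegetables_day`,
#'   `fruit_day`, `fish_wk`, `grains_wk`, `urinary_na`.
#' @return Data frame with integer `healthy_diet_points` (0-6) and logical
#'   `healthy_diet_flag` (`points >= 3`). Rows with any missing component
#'   get `NA` in both (dropped from diet analyses, kept elsewhere).
#' @export
healthy_diet_score <- function(data) {
  need <- c("red_meat_wk", "vegetables_day", "fruit_day", "fish_wk",
            "grains_wk", "urinary_na")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing diet component column(s): ", paste(miss, collapse = ", "))
  pts <- (data$red_meat_wk <= 3) + (data$vegetables_day >= 4) +
    (data$fruit_day >= 3) + (data$fish_wk >= 4) +
    (data$grains_wk >= 5) + (data$urinary_na <= 70.6)
  data.frame(healthy_diet_points = as.integer(pts),
             healthy_diet_flag = pts >= 3)
}

#' HEI-2020 component standards
#'
#' Loads the packaged component-standard table for the Healthy Eating
#' Index-2020: 13 components (9 adequacy, 4 moderation), each scored by
#' linear interpolation between a zero-score and a maximum-score standard
#' on a density basis (per 1,000 kcal, percent of energy, or a fatty-acid
#' ratio). The table is plain CSV and can be edited or replaced to swap in
#' alternative cut-offs.
#'
#' @param path Optional path to an alternative standards CSV with columns
#'   `component`, `column`, `scale`, `per_1000kcal`, `max_points`, `best`,
#'   `zero`.
#' @return Data frame of standards.
#' @export
hei2020_standards <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hei2020_standards.csv",
                        package = "inflascore", mustWork = TRUE)
  std <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("component", "column", "scale", "per_1000kcal", "max_points",
            "best", "zero")
  if (!all(need %in% names(std)))
    stop("standards table must have columns: ", paste(need, collapse = ", "))
  std
}

#' Healthy Eating Index-2020 score (0-100)
#'
#' Sums 13 component scores. For each component the intake is converted to
#' its density basis (per 1,000 kcal where flagged), then scored as
#' `max_points * clamp((x - zero) / (best - zero), 0, 1)`; adequacy
#' components have `best > zero`, moderation components `best < zero`, so
#' the same interpolation covers both directions.
#'
#' @param data Data frame with the intake columns named in the standards
#'   table plus `energy_kcal`.
#' @param standards Component-standard table, default [hei2020_standards()].
#' @return Numeric vector of scores in \[0, 100\]; `NA` where any component
#'   or energy is missing.
#' @export
hei2020_score <- function(data, standards = hei2020_standards()) {
  miss <- setdiff(c(standards$column, "energy_kcal"), names(data))
  if (length(miss))
    stop("missing intake column(s): ", paste(miss, collapse = ", "))
  total <- numeric(nrow(data))
  for (i in seq_len(nrow(standards))) {
    s <- standards[i, ]
    x <- data[[s$column]] * s$scale
    if (s$per_1000kcal == 1) x <- x / (data$energy_kcal / 1000)
    frac <- (x - s$zero) / (s$best - s$zero)
    total <- total + s$max_points * pmin(pmax(frac, 0), 1)
  }
  total
}

# MED component definitions: column, direction (+1 beneficial scored at or
# above the median, -1 detrimental scored below the median)
.med_components <- function() {
  list(vegetables = list(col = "vegetables_day", dir = 1),
       legumes = list(col = "legumes_day", dir = 1),
       fruit_nuts = list(col = c("fruit_day", "nuts_day"), dir = 1),
       cereals = list(col = "grains_wk", dir = 1),
       fish = list(col = "fish_wk", dir = 1),
       mufa_sfa = list(col = "mufa_sfa_ratio", dir = 1),
       meat = list(col = "red_meat_wk", dir = -1),
       dairy = list(col = "dairy_day", dir = -1))
}

#' Mediterranean diet score (0-9)
#'
#' Median-cut score: one point for each beneficial component (vegetables,
#' legumes, fruit plus nuts, cereals, fish, MUFA:SFA ratio) at or above the
#' cohort median, one point for each detrimental component (meat, dairy)
#' below the cohort median, and one point for moderate alcohol intake
#' (10-50 g/day for men, 5-25 g/day for women). Medians are sex-specific by
#' default, matching how the score was defined for cohorts of both sexes.
#'
#' @param data Data frame with columns `vegetables_day`, `legumes_day`,
#'   `fruit_day`, `nuts_day`, `grains_wk`, `fish_wk`, `mufa_sfa_ratio`,
#'   `red_meat_wk`, `dairy_day`, `alcohol_g_day`, and `sex`
#'   (`"man"`/`"woman"`) when `sex_specific = TRUE`.
#' @param sex_specific Compute medians within sex (default `TRUE`).
#' @return Integer vector of scores in \[0, 9\].
#' @export
med_score <- function(data, sex_specific = TRUE) {
  comps <- .med_components()
  cols <- unique(c(unlist(lapply(comps, `[[`, "col")), "alcohol_g_day"))
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("missing intake column(s): ", paste(miss, collapse = ", "))
  grp <- if (sex_specific) {
    if (is.null(data$sex)) stop("sex column required for sex-specific medians")
    as.character(data$sex)
  } else rep("all", nrow(data))
  score <- integer(nrow(data))
  for (cmp in comps) {
    x <- Reduce(`+`, lapply(cmp$col, function(cl) data[[cl]]))
    med <- stats::ave(x, grp, FUN = function(v) stats::median(v, na.rm = TRUE))
    score <- score + if (cmp$dir > 0) (x >= med) else (x < med)
  }
  alc <- data$alcohol_g_day
  lo <- ifelse(grp == "man", 10, 5)
  hi <- ifelse(grp == "man", 50, 25)
  score <- score + (alc >= lo & alc <= hi)
  as.integer(score)
}

#' DASH diet score (8-40)
#'
#' Quintile-sum score over 8 components: fruit, vegetables, nuts and
#' legumes, whole grains and low-fat dairy are scored by their cohort
#' quintile rank (1 = lowest intake, 5 = highest); sodium, red and
#' processed meat and sweetened beverages are scored reversed (5 = lowest
#' intake). The sum therefore ranges from 8 (least DASH-accordant) to 40.
#'
#' @param data Data frame with columns `fruit_day`, `vegetables_day`,
#'   `nuts_day`, `legumes_day`, `whole_grains_day`, `lowfat_dairy_day`,
#'   `sodium_mg_day`, `red_meat_wk`, `sweet_beverages_day`.
#' @return Integer vector of scores in \[8, 40\].
#' @export
dash_score <- function(data) {
  beneficial <- list(fruit = "fruit_day", vegetables = "vegetables_day",
                     nuts_legumes = c("nuts_day", "legumes_day"),
                     whole_grains = "whole_grains_day",
                     lowfat_dairy = "lowfat_dairy_day")
  detrimental <- list(sodium = "sodium_mg_day", red_meat = "red_meat_wk",
                      sweet_beverages = "sweet_beverages_day")
  cols <- unlist(c(beneficial, detrimental))
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("missing intake column(s): ", paste(miss, collapse = ", "))
  qrank <- function(cl) {
    x <- Reduce(`+`, lapply(cl, function(c) data[[c]]))
    as.integer(bin_exposure(x, k = 5))
  }
  score <- integer(nrow(data))
  for (cl in beneficial) score <- score + qrank(cl)
  for (cl in detrimental) score <- score + (6L - qrank(cl))
  as.integer(score)
}

#' Tertile bins for dietary pattern scores
#'
#' Convenience wrapper around [bin_exposure()] with `k = 3`, labelling the
#' groups T1 (lowest) to T3.
#'
#' @param scores Numeric vector of pattern scores.
#' @return Factor with levels T1, T2, T3.
#' @export
bin_tertiles <- function(scores) {
  bin_exposure(scores, k = 3, labels = c("T1", "T2", "T3"))
}

#' Average repeated dietary recalls
#'
#' Averages per-recall intakes (1-5 recalls per participant) into one row
#' per participant before scoring, so that pattern scores are
#' averaging-order invariant.
#'
#' @param long Data frame with one row per (participant, recall).
#' @param id_col Participant identifier column name.
#' @param recall_col Recall index column name (dropped from the output).
#' @return Data frame with one row per participant: numeric columns
#'   averaged, non-numeric columns taken from the first recall, and an
#'   `n_recalls` count.
#' @export
average_recalls <- function(long, id_col = "id", recall_col = "recall") {
  stopifnot(id_col %in% names(long))
  ids <- long[[id_col]]
  keep <- setdiff(names(long), c(id_col, recall_col))
  first <- !duplicated(ids)
  out <- long[first, c(id_col, keep), drop = FALSE]
  num <- keep[vapply(long[keep], is.numeric, logical(1))]
  for (cl in num)
    out[[cl]] <- tapply(long[[cl]], ids, mean)[as.character(out[[id_col]])]
  out$n_recalls <- as.integer(table(ids)[as.character(out[[id_col]])])
  rownames(out) <- NULL
  out
}
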