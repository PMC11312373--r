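#' Append all exposure and diet scores to a cohort
#'
#' Computes NLR, fits the decile map on the supplied population, appends
#' INFLA-Score component points, total and quartile, the 6-point
#' healthy-diet covariate, and the HEI-2020, MED and DASH pattern scores
#' with their tertiles.
#'
#' @param cohort Cohort data frame.
#' @param variant Decile-to-points mapping variant (see
#'   [fit_decile_map()]).
#' @param quartile_k Number of exposure bins (4 by default).
#' @return The cohort with appended columns `nlr`, `infla_pts_*`,
#'   `infla_score`, `infla_q`, `healthy_diet_points`, `healthy_diet_flag`,
#'   `hei2020`, `med`, `dash`, `hei_t`, `med_t`, `dash_t`.
#' @export
score_cohort <- function(cohort, variant = "halves", quartile_k = 4) {
  cohort$nlr <- compute_nlr(cohort$neut, cohort$lymph)
  map <- fit_decile_map(cohort, variant = variant)
  cohort <- cbind(cohort[setdiff(names(cohort),
                                 c(paste0("infla_pts_", INFLA_MARKERS),
                                   "infla_score"))],
                  compute_infla_score(cohort, map))
  cohort$infla_q <- bin_exposure(cohort$infla_score, k = quartile_k)
  hd <- healthy_diet_score(cohort)
  cohort$healthy_diet_points <- hd$healthy_diet_points
  cohort$healthy_diet_flag <- hd$healthy_diet_flag
  cohort$hei2020 <- hei2020_score(cohort)
  cohort$med <- med_score(cohort)
  cohort$dash <- dash_score(cohort)
  cohort$hei_t <- bin_tertiles(cohort$hei2020)
  cohort$med_t <- bin_tertiles(cohort$med)
  cohort$dash_t <- bin_tertiles(cohort$dash)
  cohort
}

.default_pipeline_config <- function() {
  list(seed = 1L, n_participants = 20000L,
       stages = c("simulate", "score", "outcomes", "fit",
                  "life_expectancy", "joint", "report"),
       cohort = list(), variant = "halves",
       admin_censor_date = "2022-02-01",
       life_table = "packaged", aging_codes = "packaged",
       patterns = c("hei", "med", "dash"))
}

#' Validate a pipeline configuration
#'
#' Fills defaults and checks the schema: known stage names, a life-table
#' source whenever the life-expectancy stage is enabled, an aging-disease
#' code list whenever outcomes are derived, and a valid seed.
#'
#' @param config List (possibly partial) or path to a YAML file.
#' @return Validated config list.
#' @export
validate_pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  def <- .default_pipeline_config()
  unknown <- setdiff(names(config), c(names(def), "input_csv"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  bad <- setdiff(cfg$stages, def$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(cfg$seed)) stop("seed must be an integer")
  if ("life_expectancy" %in% cfg$stages &&
      (is.null(cfg$life_table) || !nzchar(cfg$life_table)))
    stop("configuration error: life-expectancy stage enabled but no ",
         "life_table path given")
  if ("outcomes" %in% cfg$stages &&
      (is.null(cfg$aging_codes) || !nzchar(cfg$aging_codes)))
    stop("configuration error: outcomes stage enabled but no aging_codes ",
         "list given")
  bad_p <- setdiff(cfg$patterns, c("hei", "med", "dash"))
  if (length(bad_p)) stop("unknown pattern(s): ", paste(bad_p, collapse = ", "))
  cfg
}

.stage_msg <- function(stage, t0) {
  message(sprintf("[inflascore] stage %-16s %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

.write_table <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- simulate (or ingest a cohort CSV),
#' score, outcomes, models, life expectancy, joint effects, report --
#' writing every output table under `outdir` together with a JSON manifest
#' carrying the seed and a hash of the configuration. All randomness is
#' routed through the single configured seed, so re-running the same
#' config reproduces every numeric table byte-for-byte.
#'
#' @param config List or YAML path (see [validate_pipeline_config()]).
#' @param outdir Output directory (created if needed).
#' @param seed Optional seed override.
#' @return Invisibly, a list with the validated config, file `manifest`
#'   and key in-memory results.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("inflarun"),
                         seed = NULL) {
  cfg <- validate_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  files <- character(0)
  results <- list()
  t0 <- as.numeric(Sys.time())

  cohort <- NULL
  if ("simulate" %in% cfg$stages) {
    if (!is.null(cfg$input_csv)) {
      cohort <- read_cohort(cfg$input_csv)
    } else {
      ccfg <- do.call(cohort_config,
                      c(list(n_participants = cfg$n_participants,
                             seed = cfg$seed), cfg$cohort))
      cohort <- generate_cohort(ccfg)
    }
    files["cohort"] <- .write_table(cohort, outdir, "cohort.csv")
    .stage_msg("simulate", t0)
  }

  if ("score" %in% cfg$stages) {
    cohort <- score_cohort(cohort, variant = cfg$variant)
    files["scored"] <- .write_table(cohort, outdir, "cohort_scored.csv")
    .stage_msg("score", t0)
  }

  aging <- if (identical(cfg$aging_codes, "packaged"))
    read_icd10_codes(system.file("extdata",
                                 "aging_disease_codes_example.txt",
                                 package = "inflascore", mustWork = TRUE))
  else read_icd10_codes(cfg$aging_codes)

  if ("outcomes" %in% cfg$stages) {
    cohort <- derive_outcomes(cohort, aging_codes = aging,
                              admin_date = as.Date(cfg$admin_censor_date))
    files["outcomes"] <- .write_table(cohort, outdir, "cohort_outcomes.csv")
    .stage_msg("outcomes", t0)
  }

  pattern_cols <- c(hei = "hei_t", med = "med_t", dash = "dash_t")
  outcomes <- list(
    aging_hosp = c(time = "time_aging_hosp", event = "aging_hosp"),
    premature_death = c(time = "time_premature", event = "premature_death"))

  if ("fit" %in% cfg$stages) {
    est <- list()
    for (oc in names(outcomes)) {
      f <- cox_fit(cohort, outcomes[[oc]][["time"]],
                   outcomes[[oc]][["event"]], "infla_q",
                   default_adjustment())
      tt <- trend_test(cohort, outcomes[[oc]][["time"]],
                       outcomes[[oc]][["event"]], "infla_q",
                       default_adjustment())
      rc <- rcs_curve(cohort, "infla_score", outcomes[[oc]][["time"]],
                      outcomes[[oc]][["event"]], default_adjustment())
      est[[oc]] <- cbind(outcome = oc, f$estimates, p_trend = tt$p_trend,
                         p_nonlinearity = rc$p_nonlinearity)
      results$rcs[[oc]] <- rc
    }
    results$fit <- do.call(rbind, est)
    files["models"] <- .write_table(results$fit, outdir,
                                    "model_estimates.csv")
    .stage_msg("fit", t0)
  }

  if ("life_expectancy" %in% cfg$stages) {
    lt <- if (identical(cfg$life_table, "packaged")) read_life_table()
    else read_life_table(cfg$life_table)
    gaps <- list()
    for (s in c("man", "woman")) {
      sub <- cohort[cohort$sex == s, , drop = FALSE]
      f <- cox_fit(sub, "time_premature", "premature_death", "infla_q",
                   setdiff(default_adjustment(), "sex"))
      e <- f$estimates
      prev <- as.vector(table(sub$infla_q)) / sum(!is.na(sub$infla_q))
      spec <- group_spec(stats::setNames(prev, e$level),
                         stats::setNames(e$hr, e$level),
                         stats::setNames(ifelse(is.na(e$ci_low), 1,
                                                e$ci_low), e$level),
                         stats::setNames(ifelse(is.na(e$ci_high), 1,
                                                e$ci_high), e$level))
      g <- expectancy_gap(lt$m[lt$sex == s], spec)
      gaps[[s]] <- cbind(sex = s, g)
    }
    results$life_expectancy <- do.call(rbind, gaps)
    files["life_expectancy"] <- .write_table(results$life_expectancy,
                                             outdir, "life_expectancy.csv")
    .stage_msg("life_expectancy", t0)
  }

  if ("joint" %in% cfg$stages) {
    jt <- list(); md <- list()
    for (p in cfg$patterns) for (oc in names(outcomes)) {
      jf <- joint_fit(cohort, pattern_cols[[p]], "infla_q",
                      outcomes[[oc]][["time"]], outcomes[[oc]][["event"]])
      jt[[paste(p, oc)]] <- cbind(pattern = p, outcome = oc, jf$estimates)
      mf <- modification_fit(cohort, pattern_cols[[p]], "infla_q",
                             outcomes[[oc]][["time"]],
                             outcomes[[oc]][["event"]])
      md[[paste(p, oc)]] <- cbind(pattern = p, outcome = oc, mf$estimates)
    }
    results$joint <- do.call(rbind, jt)
    results$modification <- do.call(rbind, md)
    files["joint"] <- .write_table(results$joint, outdir,
                                   "joint_estimates.csv")
    files["modification"] <- .write_table(results$modification, outdir,
                                          "modification_estimates.csv")
    .stage_msg("joint", t0)
  }

  if ("report" %in% cfg$stages) {
    files["table1"] <- .write_table(cohort_summary(cohort), outdir,
                                    "table1_summary.csv")
    .stage_msg("report", t0)
  }

  manifest <- list(seed = cfg$seed, config_hash = cfg_hash,
                   n_participants = nrow(cohort),
                   stages = cfg$stages,
                   files = as.list(files),
                   elapsed_s = round(as.numeric(Sys.time()) - t0, 2))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(list(config = cfg, outdir = outdir,
                           manifest = manifest, cohort = cohort,
                           results = results),
                      class = "inflascore_run"))
}

#' @export
print.inflascore_run <- function(x, ...) {
  cat("inflascore pipeline run\n  outdir: ", x$outdir,
      "\n  seed: ", x$config$seed,
      "\n  stages: ", paste(x$config$stages, collapse = ", "),
      "\n  tables: ", paste(names(x$manifest$files), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
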