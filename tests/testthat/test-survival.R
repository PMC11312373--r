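test_that("partial-likelihood maximum matches a brute-force grid search", {
  # 8-observation toy data with tied death times
  toy <- data.frame(time = c(1, 1, 2, 2, 3, 4, 5, 6),
                    event = c(1, 1, 1, 0, 1, 1, 0, 1),
                    x = c(1, 0, 1, 1, 0, 1, 0, 0))
  f <- survival::coxph(survival::Surv(time, event) ~ x, data = toy,
                       ties = "efron")
  b_grid <- oracle_grid_beta(toy$time, toy$event, toy$x)
  expect_equal(unname(coef(f)), b_grid, tolerance = 1e-4)
  # the same through the module surface, on a two-level factor
  toy$grp <- factor(ifelse(toy$x == 1, "Q2", "Q1"))
  cf <- cox_fit(toy, "time", "event", "grp")
  expect_equal(unname(log(cf$estimates$hr[2])), b_grid, tolerance = 1e-4)
  # a second configuration, heavier ties
  set.seed(12)
  toy2 <- data.frame(time = sample(1:3, 20, TRUE),
                     event = rbinom(20, 1, 0.7), x = rbinom(20, 1, 0.5))
  f2 <- survival::coxph(survival::Surv(time, event) ~ x, data = toy2,
                        ties = "efron")
  expect_equal(unname(coef(f2)),
               oracle_grid_beta(toy2$time, toy2$event, toy2$x),
               tolerance = 1e-4)
})

test_that("two-group exponential data recover the generating rate ratio", {
  set.seed(13)
  d <- simulate_ph_groups(10000, c(Q1 = 0, Q2 = log(2)), base_rate = 0.1,
                          censor_time = 8)
  f <- cox_fit(d, "time", "event", "group")
  z <- (log(f$estimates$hr[2]) - log(2)) / f$estimates$log_hr_se[2]
  expect_lt(abs(z), 3)
  expect_true(f$estimates$ci_low[2] <= f$estimates$hr[2])
  expect_true(f$estimates$hr[2] <= f$estimates$ci_high[2])
})

test_that("permuting event labels against the exposure gives a null estimate", {
  set.seed(14)
  d <- simulate_ph_groups(4000, c(Q1 = 0, Q2 = log(3)), base_rate = 0.1)
  perm <- sample(nrow(d))
  d$group <- d$group[perm]  # break the association
  f <- cox_fit(d, "time", "event", "group")
  expect_lt(abs(log(f$estimates$hr[2]) / f$estimates$log_hr_se[2]), 3)
})

test_that("model guards reject degenerate inputs", {
  d <- data.frame(time = 1:10, event = rep(0, 10),
                  grp = rep(c("a", "b"), 5))
  expect_error(cox_fit(d, "time", "event", "grp"), "no events")
  d$event <- rep(1, 10)
  d$cst <- 1
  expect_error(cox_fit(d, "time", "event", "grp", "cst"), "constant")
  expect_error(cox_fit(d, "time", "event", "missingcol"), "not found")
  d$one <- "a"
  expect_error(trend_test(d, "time", "event", "one"), "constant")
})

test_that("trend test detects a monotone gradient and keeps its direction", {
  set.seed(15)
  d <- simulate_ph_groups(8000, c(Q1 = 0, Q2 = log(1.3), Q3 = log(1.6),
                                  Q4 = log(2)), base_rate = 0.08)
  tt <- trend_test(d, "time", "event", "group")
  expect_lt(tt$p_trend, 1e-6)
  expect_gt(tt$coef, 0)
})

test_that("spline curve is anchored at 1 at the reference score", {
  set.seed(16)
  score <- rnorm(6000)
  d <- simulate_ph_score(score, function(s) 0.3 * s, base_rate = 0.1)
  rc <- rcs_curve(d, "score", "time", "event")
  at_ref <- rc$curve[rc$curve$score == rc$ref, ]
  expect_equal(at_ref$hr, 1)
  expect_equal(rc$ref, median(score))
  expect_true(all(rc$curve$ci_low <= rc$curve$hr + 1e-12))
  expect_equal(length(rc$knots), 4)
})

test_that("spline nonlinearity test flags a J-shaped truth but not a linear one", {
  set.seed(17)
  score <- rnorm(20000)
  dj <- simulate_ph_score(score, function(s) 0.18 * s^2, base_rate = 0.05)
  rcj <- rcs_curve(dj, "score", "time", "event")
  expect_lt(rcj$p_nonlinearity, 0.05)
  # under a linear truth the nonlinear terms carry no signal; a single
  # realisation should sit far from the detection region
  dl <- simulate_ph_score(score, function(s) 0.3 * s, base_rate = 0.05)
  rcl <- rcs_curve(dl, "score", "time", "event")
  expect_gt(rcl$p_nonlinearity, 1e-4)
  expect_error(rcs_curve(dl, "score", "time", "event",
                         knot_quantiles = c(0.5, 0.5, 0.6, 0.9)),
               "not distinct")
})

test_that("proportional hazards hold for exponential group data", {
  set.seed(25)
  d <- simulate_ph_groups(5000, c(Q1 = 0, Q2 = log(1.5)), base_rate = 0.1)
  tab <- ph_check(cox_fit(d, "time", "event", "group"))
  expect_gt(tab["GLOBAL", "p"], 0.001)  # truly proportional generator
  expect_error(ph_check(42), "infla_cox")
})

test_that("affine rescaling of a covariate leaves other hazard ratios unchanged", {
  set.seed(18)
  d <- simulate_ph_groups(3000, c(Q1 = 0, Q2 = log(1.5)), base_rate = 0.1)
  d$z <- rnorm(3000, 50, 10)
  f1 <- cox_fit(d, "time", "event", "group", "z")
  d$z <- d$z / 10 + 3
  f2 <- cox_fit(d, "time", "event", "group", "z")
  expect_equal(f1$estimates$hr[2], f2$estimates$hr[2], tolerance = 1e-8)
})

test_that("subgroup runner partitions the cohort and tolerates empty strata", {
  set.seed(19)
  d <- simulate_ph_groups(6000, c(Q1 = 0, Q2 = log(1.4)), base_rate = 0.1)
  d$age_grp <- ifelse(runif(6000) < 0.5, "le55", "gt55")
  sg <- subgroup_run(d, "age_grp", "time", "event", "group",
                     adjust = character(0))
  expect_equal(sum(sg$n), nrow(d))                     # partition bookkeeping
  expect_equal(sort(unique(sg$stratum)), c("gt55", "le55"))
  # single stratum reproduces the unstratified fit
  d$all <- "everyone"
  sg1 <- subgroup_run(d, "all", "time", "event", "group",
                      adjust = character(0))
  f <- cox_fit(d, "time", "event", "group")
  expect_equal(sg1$hr, f$estimates$hr, tolerance = 1e-12)
  # a stratum without events is reported inestimable, not fatal
  d$age_grp[1:3] <- "tiny"
  d$event[1:3] <- 0
  sg2 <- subgroup_run(d, "age_grp", "time", "event", "group",
                      adjust = character(0))
  expect_true(all(is.na(sg2$hr[sg2$stratum == "tiny"])))
  expect_false(anyNA(sg2$hr[sg2$stratum == "gt55"]))
})

test_that("sensitivity filters act exactly as specified", {
  set.seed(20)
  d <- simulate_ph_groups(3000, c(Q1 = 0, Q2 = log(1.5)), base_rate = 0.05,
                          censor_time = 12)
  d$cvd <- 0; d$cancer <- 0; d$diabetes <- 0; d$respiratory <- 0
  d$score <- rnorm(3000)
  base <- cox_fit(d, "time", "event", "group")
  # (1) with no prevalent disease the exclusion is a no-op
  s1 <- sensitivity_run(d, 1, "time", "event", "group", adjust = character(0))
  expect_equal(s1$n_retained, nrow(d))
  expect_equal(s1$estimates$hr, base$estimates$hr, tolerance = 1e-12)
  # (1) removes exactly the flagged participants
  d2 <- d; d2$cvd[1:100] <- 1; d2$cancer[101:150] <- 1
  s1b <- sensitivity_run(d2, 1, "time", "event", "group",
                         adjust = character(0))
  expect_equal(s1b$n_retained, nrow(d) - 150)
  # (2) rebins the continuous score into quintiles
  s2 <- sensitivity_run(d, 2, "time", "event", "group",
                        adjust = character(0), score_col = "score")
  expect_equal(nrow(s2$estimates), 5)
  # (3) drops follow-up < 2 years; hand count
  short <- sum(d$time < 2)
  expect_gt(short, 0)
  s3 <- sensitivity_run(d, 3, "time", "event", "group",
                        adjust = character(0))
  expect_equal(s3$n_retained, nrow(d) - short)
  # (3) is a no-op when every follow-up exceeds two years
  d3 <- d; d3$time <- d3$time + 2.1
  s3b <- sensitivity_run(d3, 3, "time", "event", "group",
                         adjust = character(0))
  expect_equal(s3b$n_retained, nrow(d3))
  expect_error(sensitivity_run(d[0, ], 3, "time", "event", "group",
                               adjust = character(0)), "every participant")
})
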