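make_intake <- function(red_meat = 5, veg = 1, fruit = 1, fish = 1,
                        grains = 2, na = 100) {
  data.frame(red_meat_wk = red_meat, vegetables_day = veg, fruit_day = fruit,
             fish_wk = fish, grains_wk = grains, urinary_na = na)
}

test_that("healthy-diet score counts the six criteria with flag at >= 3", {
  all_met <- make_intake(3, 4, 3, 4, 5, 70.6)  # boundary values all count
  got <- healthy_diet_score(all_met)
  expect_equal(got$healthy_diet_points, 6L)
  expect_true(got$healthy_diet_flag)
  none <- make_intake(4, 3.9, 2.9, 3.9, 4.9, 70.7)
  got0 <- healthy_diet_score(none)
  expect_equal(got0$healthy_diet_points, 0L)
  expect_false(got0$healthy_diet_flag)
  three <- make_intake(3, 4, 3, 1, 1, 100)     # first three criteria only
  got3 <- healthy_diet_score(three)
  expect_equal(got3$healthy_diet_points, 3L)
  expect_true(got3$healthy_diet_flag)
  two <- make_intake(3, 4, 1, 1, 1, 100)
  expect_false(healthy_diet_score(two)$healthy_diet_flag)
})

test_that("healthy-diet score signals missing components", {
  x <- make_intake()
  x$urinary_na <- NA
  expect_true(is.na(healthy_diet_score(x)$healthy_diet_points))
  expect_error(healthy_diet_score(x[-1]), "missing diet component")
})

hei_fixture <- function(n = 1) {
  std <- hei2020_standards()
  d <- as.data.frame(stats::setNames(as.list(rep(0, nrow(std))),
                                     std$column))
  d <- d[rep(1, n), , drop = FALSE]
  d$energy_kcal <- 2000
  rownames(d) <- NULL
  list(data = d, std = std)
}

test_that("HEI-2020 attains 100 at the adequacy maxima / moderation minima and 0 at the reverse", {
  fx <- hei_fixture()
  best <- fx$data
  worst <- fx$data
  for (i in seq_len(nrow(fx$std))) {
    s <- fx$std[i, ]
    dens2raw <- function(v) {
      v <- v / s$scale
      if (s$per_1000kcal == 1) v * (best$energy_kcal / 1000) else v
    }
    best[[s$column]] <- dens2raw(s$best)
    worst[[s$column]] <- dens2raw(s$zero)
  }
  expect_equal(hei2020_score(best), 100)
  expect_equal(hei2020_score(worst), 0)
  expect_equal(sum(hei2020_standards()$max_points), 100)
})

test_that("HEI-2020 is monotone in the beneficial direction of each component", {
  set.seed(5)
  fx <- hei_fixture(50)
  d <- fx$data
  for (cl in fx$std$column) d[[cl]] <- rgamma(50, 2, 1)
  base <- hei2020_score(d)
  up <- d; up$whole_grains_day <- up$whole_grains_day + 1
  expect_true(all(hei2020_score(up) >= base))
  salty <- d; salty$sodium_mg_day <- salty$sodium_mg_day + 500
  expect_true(all(hei2020_score(salty) <= base))
})

med_fixture <- function(n = 40, seed = 6) {
  set.seed(seed)
  data.frame(sex = rep(c("man", "woman"), length.out = n),
             vegetables_day = rgamma(n, 4), legumes_day = rgamma(n, 2),
             fruit_day = rgamma(n, 3), nuts_day = rgamma(n, 2),
             grains_wk = rgamma(n, 5), fish_wk = rgamma(n, 2),
             mufa_sfa_ratio = rgamma(n, 4), red_meat_wk = rgamma(n, 3),
             dairy_day = rgamma(n, 3), alcohol_g_day = rgamma(n, 2, 0.2))
}

test_that("MED score matches a component-wise median-rule oracle", {
  d <- med_fixture()
  got <- med_score(d)
  # independent check: loop per sex and component
  oracle <- integer(nrow(d))
  comp_ben <- list("vegetables_day", "legumes_day",
                   c("fruit_day", "nuts_day"), "grains_wk", "fish_wk",
                   "mufa_sfa_ratio")
  comp_det <- list("red_meat_wk", "dairy_day")
  for (s in c("man", "woman")) {
    i <- d$sex == s
    for (cc in comp_ben) {
      x <- rowSums(d[, cc, drop = FALSE])
      oracle[i] <- oracle[i] + (x[i] >= median(x[i]))
    }
    for (cc in comp_det) {
      x <- d[[cc]]
      oracle[i] <- oracle[i] + (x[i] < median(x[i]))
    }
    lim <- if (s == "man") c(10, 50) else c(5, 25)
    oracle[i] <- oracle[i] + (d$alcohol_g_day[i] >= lim[1] &
                                d$alcohol_g_day[i] <= lim[2])
  }
  expect_identical(got, as.integer(oracle))
  expect_true(all(got >= 0 & got <= 9))
})

test_that("components exactly at the median score by the stated at-or-above rule", {
  d <- med_fixture(20)
  d[] <- lapply(d, function(x) if (is.numeric(x)) rep(x[1], 20) else x)
  d$alcohol_g_day <- rep(0, 20)  # outside the moderate band
  got <- med_score(d, sex_specific = FALSE)
  # all beneficial components sit at the median (point), detrimental are
  # not below it (no point), alcohol out of band (no point)
  expect_true(all(got == 6L))
})

dash_fixture <- function(n = 100) {
  inc <- seq_len(n)
  data.frame(fruit_day = inc, vegetables_day = inc, nuts_day = inc / 2,
             legumes_day = inc / 2, whole_grains_day = inc,
             lowfat_dairy_day = inc, sodium_mg_day = rev(inc) * 30,
             red_meat_wk = rev(inc) / 10, sweet_beverages_day = rev(inc) / 20)
}

test_that("DASH spans 8 (worst) to 40 (best quintiles everywhere)", {
  d <- dash_fixture()
  got <- dash_score(d)
  expect_equal(got[100], 40L)  # highest beneficial, lowest detrimental
  expect_equal(got[1], 8L)
  expect_true(all(got >= 8 & got <= 40))
  # monotone: raising sodium can only lower the score
  d2 <- d
  d2$sodium_mg_day[50] <- max(d$sodium_mg_day) + 1
  expect_true(dash_score(d2)[50] <= got[50])
})

test_that("tertile bins split uniform scores into three equal groups", {
  t <- bin_tertiles(1:99)
  expect_equal(as.vector(table(t)), rep(33L, 3))
  expect_equal(levels(t), c("T1", "T2", "T3"))
  expect_error(bin_tertiles(rep(2, 30)), "distinct")
})

test_that("scoring averaged recalls equals scoring pre-averaged intakes", {
  set.seed(7)
  base <- make_intake(red_meat = runif(10, 0, 6), veg = runif(10, 0, 8),
                      fruit = runif(10, 0, 5), fish = runif(10, 0, 6),
                      grains = runif(10, 0, 9), na = runif(10, 40, 120))
  base$id <- 1:10
  long <- do.call(rbind, lapply(1:3, function(r) {
    jig <- base
    num <- setdiff(names(jig), "id")
    for (cl in num) jig[[cl]] <- jig[[cl]] + rnorm(10, 0, 0.3)
    jig$recall <- r
    jig
  }))
  avg <- average_recalls(long)
  pre <- aggregate(long[setdiff(names(long), c("id", "recall"))],
                   by = list(id = long$id), FUN = mean)
  expect_equal(avg$n_recalls, rep(3L, 10))
  expect_equal(healthy_diet_score(avg)$healthy_diet_points,
               healthy_diet_score(pre)$healthy_diet_points)
})
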