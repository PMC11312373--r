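test_that("NLR is the neutrophil/lymphocyte quotient and rejects zero denominators", {
  expect_equal(compute_nlr(2.0, 2.0), 1.0)
  expect_equal(compute_nlr(4.22, 1.96), 2.1531, tolerance = 1e-4)
  expect_equal(compute_nlr(c(2, 3), c(1, 2)), c(2, 1.5))
  expect_error(compute_nlr(4.0, 0.0), "must be > 0")
  expect_error(compute_nlr(c(1, 2), c(1, -1)), "must be > 0")
})

test_that("decile cut-points match hand-interpolated empirical quantiles", {
  d <- data.frame(crp = 1:100, wbc = 1:100, plt = 1:100, nlr = 1:100)
  map <- fit_decile_map(d)
  expect_equal(map$cuts$crp, oracle_quantile7(1:100, 1:9 / 10))
  expect_equal(map$cuts$crp[1], 10.9)
  expect_equal(map$cuts$crp[9], 90.1)
  expect_true(all(diff(map$cuts$crp) >= 0))
  expect_length(map$cuts$wbc, 9)
})

test_that("degenerate and undersized marker columns are flagged", {
  d <- data.frame(crp = rep(5, 50), wbc = 1:50, plt = 1:50, nlr = 1:50)
  expect_warning(fit_decile_map(d), "degenerate")
  expect_error(fit_decile_map(data.frame(crp = 1:5, wbc = 1:5, plt = 1:5,
                                         nlr = 1:5)),
               "at least 10")
})

test_that("two disjoint half-populations are separated at the median cut", {
  x <- c(stats::rnorm(50, 0, 0.1), stats::rnorm(50, 100, 0.1))
  d <- data.frame(crp = x, wbc = x, plt = x, nlr = x)
  map <- fit_decile_map(d)
  pts <- decile_points(x, "crp", map)
  expect_true(all(pts[1:50] <= 0))
  expect_true(all(pts[51:100] >= 0))
  expect_true(map$cuts$crp[5] > 1 && map$cuts$crp[5] < 99)
})

test_that("decile points follow the stated mapping in both variants", {
  d <- data.frame(crp = 1:100, wbc = 1:100, plt = 1:100, nlr = 1:100)
  map <- fit_decile_map(d, variant = "halves")
  expect_equal(decile_points(0.5, "crp", map), -4L)   # below 10th pctile
  expect_equal(decile_points(99.9, "crp", map), 4L)   # above 90th pctile
  expect_equal(decile_points(55, "crp", map), 0L)     # decile 6
  expect_equal(decile_points(65, "crp", map), 1L)     # decile 7
  expect_equal(decile_points(45, "crp", map), 0L)     # decile 5
  # halves variant: deciles 1..5 -> -4..0, 6..10 -> 0..4
  mids <- seq(5, 95, by = 10)
  expect_equal(decile_points(mids, "crp", map),
               c(-4L, -3L, -2L, -1L, 0L, 0L, 1L, 2L, 3L, 4L))
  mapb <- fit_decile_map(d, variant = "bonaccio")
  expect_equal(decile_points(mids, "crp", mapb),
               c(-4L, -3L, -2L, -1L, 0L, 0L, 1L, 2L, 3L, 4L))
  # variants differ at deciles 5 and 7 boundaries: decile 4 and 7
  expect_equal(decile_points(35, "crp", mapb), -1L)  # decile 4
  expect_equal(decile_points(45, "crp", mapb), 0L)   # decile 5
})

test_that("values exactly at a cut-point fall in the lower decile", {
  d <- data.frame(crp = 1:100, wbc = 1:100, plt = 1:100, nlr = 1:100)
  map <- fit_decile_map(d)
  c1 <- map$cuts$crp[1]
  expect_equal(decile_points(c1, "crp", map), -4L)
  expect_equal(decile_points(c1 + 1e-9, "crp", map), -3L)
})

test_that("reversed marker direction mirrors the decile mapping", {
  d <- data.frame(crp = 1:100, wbc = 1:100, plt = 1:100, nlr = 1:100)
  map <- fit_decile_map(d, directions = c(crp = 1, wbc = 1, plt = -1,
                                          nlr = 1))
  expect_equal(decile_points(0.5, "plt", map), 4L)
  expect_equal(decile_points(99.9, "plt", map), -4L)
})

test_that("INFLA-Score totals span [-16, 16] with the stated extremes", {
  set.seed(1)
  pop <- data.frame(crp = rlnorm(500), wbc = rgamma(500, 10),
                    plt = rgamma(500, 20, 0.1), nlr = rlnorm(500))
  map <- fit_decile_map(pop)
  hi <- data.frame(crp = 1e4, wbc = 1e4, plt = 1e5, nlr = 1e4)
  lo <- data.frame(crp = 1e-6, wbc = 1e-6, plt = 1e-6, nlr = 1e-6)
  expect_equal(compute_infla_score(hi, map)$infla_score, 16L)
  expect_equal(compute_infla_score(lo, map)$infla_score, -16L)
  mid <- data.frame(crp = median(pop$crp), wbc = median(pop$wbc),
                    plt = median(pop$plt), nlr = median(pop$nlr))
  expect_equal(compute_infla_score(mid, map)$infla_score, 0L)
  sc <- compute_infla_score(pop, map)
  expect_true(all(sc$infla_score >= -16 & sc$infla_score <= 16))
  expect_true(all(abs(as.matrix(sc[paste0("infla_pts_",
                                          c("crp", "wbc", "plt",
                                            "nlr"))])) <= 4))
  expect_equal(sc$infla_score,
               as.integer(rowSums(sc[paste0("infla_pts_",
                                            c("crp", "wbc", "plt",
                                              "nlr"))])))
})

test_that("missing markers propagate NA rather than being imputed", {
  set.seed(2)
  pop <- data.frame(crp = rlnorm(100), wbc = rgamma(100, 10),
                    plt = rgamma(100, 20, 0.1), nlr = rlnorm(100))
  map <- fit_decile_map(pop)
  pop$crp[3] <- NA
  sc <- compute_infla_score(pop, map)
  expect_true(is.na(sc$infla_score[3]))
  expect_false(anyNA(sc$infla_score[-3]))
})

test_that("module totals equal the brute-force sort-rank-map oracle", {
  set.seed(11)
  for (variant in c("halves", "bonaccio")) {
    pop <- data.frame(crp = rlnorm(300, 0.5, 1), wbc = rgamma(300, 11, 1.6),
                      plt = rgamma(300, 18, 0.07), nlr = rlnorm(300, 0.7, 0.4))
    map <- fit_decile_map(pop, variant = variant)
    got <- compute_infla_score(pop, map)$infla_score
    expect_identical(got, oracle_infla_total(pop, pop, variant = variant))
  }
})

test_that("raising any single marker never decreases the total", {
  set.seed(3)
  pop <- data.frame(crp = rlnorm(200), wbc = rgamma(200, 10),
                    plt = rgamma(200, 20, 0.1), nlr = rlnorm(200))
  map <- fit_decile_map(pop)
  base <- compute_infla_score(pop, map)$infla_score
  for (m in c("crp", "wbc", "plt", "nlr")) {
    bumped <- pop
    bumped[[m]] <- bumped[[m]] * 1.5
    expect_true(all(compute_infla_score(bumped, map)$infla_score >= base))
  }
})

test_that("positive affine rescaling of a marker leaves points unchanged", {
  set.seed(4)
  pop <- data.frame(crp = rlnorm(200), wbc = rgamma(200, 10),
                    plt = rgamma(200, 20, 0.1), nlr = rlnorm(200))
  map <- fit_decile_map(pop)
  pts <- decile_points(pop$crp, "crp", map)
  pop2 <- pop
  pop2$crp <- 3.7 * pop2$crp + 11
  map2 <- fit_decile_map(pop2)
  expect_identical(decile_points(pop2$crp, "crp", map2), pts)
})

test_that("quantile exposure bins partition uniform scores evenly", {
  sc <- -16:15
  q4 <- bin_exposure(sc, 4)
  expect_equal(as.vector(table(q4)), rep(8L, 4))
  expect_equal(levels(q4), paste0("Q", 1:4))
  q5 <- bin_exposure(sc, 5)
  expect_equal(nlevels(q5), 5)
  expect_equal(sum(table(q5)), 32)
  expect_error(bin_exposure(rep(1, 50), 4), "distinct")
})

test_that("tied integer scores bin by the lower-bin tie rule", {
  sc <- rep(1:4, each = 25)
  q <- bin_exposure(sc, 4)
  # brute-force rank oracle: cuts at the type-7 quartiles, ties go low
  cuts <- oracle_quantile7(sc, c(.25, .5, .75))
  idx <- 1L + vapply(sc, function(v) sum(v > cuts), integer(1))
  expect_equal(as.integer(q), idx)
  expect_equal(as.vector(table(q)), rep(25L, 4))
  # tie block straddling a cut keeps the whole block together
  sc2 <- rep(c(1, 1, 1, 2, 3, 4, 5, 6), 10)
  q2 <- bin_exposure(sc2, 4)
  expect_true(all(tapply(as.integer(q2), sc2,
                         function(v) length(unique(v))) == 1))
})
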