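# Independent oracles used across the suite. They re-derive results by
# different routes than the package (manual quantile interpolation,
# hand-written partial likelihood, discrete simulation) on purpose.

# type-7 quantile by hand: h = (n-1)p + 1, linear interpolation of the
# order statistics
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    if (lo >= n) return(s[n])
    s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  }, numeric(1))
}

# brute-force INFLA total: sort, rank into deciles against the population,
# map to points, sum over the four markers
oracle_infla_total <- function(panel, population,
                               markers = c("crp", "wbc", "plt", "nlr"),
                               variant = "halves") {
  total <- integer(nrow(panel))
  for (m in markers) {
    cuts <- oracle_quantile7(population[[m]], 1:9 / 10)
    for (i in seq_len(nrow(panel))) {
      d <- 1L + sum(panel[[m]][i] > cuts)
      pt <- if (variant == "halves") {
        if (d <= 5) d - 5L else d - 6L
      } else {
        if (d <= 4) d - 5L else if (d <= 6) 0L else d - 6L
      }
      total[i] <- total[i] + pt
    }
  }
  total
}

# Efron log partial likelihood for a single numeric covariate
oracle_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (tt in sort(unique(time[event == 1]))) {
    risk <- time >= tt
    dead <- event == 1 & time == tt
    d <- sum(dead)
    sr <- sum(exp(beta * x[risk]))
    sd_ <- sum(exp(beta * x[dead]))
    ll <- ll + beta * sum(x[dead])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sr - (l / d) * sd_)
  }
  ll
}

# two-stage grid maximisation of the Efron partial likelihood
oracle_grid_beta <- function(time, event, x, lim = 3) {
  coarse <- seq(-lim, lim, by = 0.01)
  ll <- vapply(coarse, oracle_efron_loglik, numeric(1), time, event, x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, oracle_efron_loglik, numeric(1), time, event, x)
  fine[which.max(llf)]
}

# small cohort fixture
tiny_cohort <- function(n = 2000, seed = 42, ...) {
  generate_cohort(cohort_config(n_participants = n, seed = seed, ...))
}
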