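# Regenerates inst/extdata/uk_life_table_synthetic.csv: a synthetic
# sex-specific mortality schedule m(a) = A*exp(B*(a-40)) + C
# (Gompertz-Makeham) for ages 40..100, with (A, B) fitted so that the
# life-table expectancies at ages 40 and 60 match recent UK national
# period life tables (men ~40.5/22.5 y, women ~43.8/25.2 y). It stands in
# for an official national life table, which is not redistributed here.
lt_e <- function(m, ages = 40:100) {
  q <- pmin(m / (1 + 0.5 * m), 1)
  l <- cumprod(c(1, 1 - q))[seq_along(ages)]
  L <- l - 0.5 * l * q
  L[length(ages)] <- l[length(ages)] / max(m[length(ages)], 1e-12)
  rev(cumsum(rev(L)))[c(1, 21)] / l[c(1, 21)]
}
gm <- function(A, B, C, ages = 40:100) A * exp(B * (ages - 40)) + C
fit_sex <- function(e40, e60, C = 3e-4) {
  obj <- function(p) sum((lt_e(gm(exp(p[1]), p[2], C)) - c(e40, e60))^2)
  o <- optim(c(log(8e-4), 0.09), obj, control = list(maxit = 5000,
                                                     reltol = 1e-14))
  c(A = exp(o$par[1]), B = o$par[2], C = C)
}
men <- fit_sex(40.5, 22.5)
wom <- fit_sex(43.8, 25.2)
out <- rbind(
  data.frame(sex = "man", age = 40:100,
             m = signif(gm(men["A"], men["B"], men["C"]), 8)),
  data.frame(sex = "woman", age = 40:100,
             m = signif(gm(wom["A"], wom["B"], wom["C"]), 8)))
write.csv(out, file.path("inst", "extdata", "uk_life_table_synthetic.csv"),
          row.names = FALSE, quote = FALSE)
cat("men e40/e60:", lt_e(gm(men["A"], men["B"], men["C"])), "\n")
cat("women e40/e60:", lt_e(gm(wom["A"], wom["B"], wom["C"])), "\n")
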