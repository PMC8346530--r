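# Independent explicit-formula oracles. These deliberately avoid cor(),
# cor.test(), t.test() and chisq.test() so that the package's statistics can
# be checked against a second route.

pearson_brute <- function(x, y) {
  n <- length(x)
  sxy <- n * sum(x * y) - sum(x) * sum(y)
  sxx <- n * sum(x^2) - sum(x)^2
  syy <- n * sum(y^2) - sum(y)^2
  r <- sxy / sqrt(sxx * syy)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = tstat, p = 2 * pt(-abs(tstat), df = n - 2))
}

# pooled-variance (Student) two-sample t-test
ttest_brute <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = nx + ny - 2))
}

# Pearson chi-square on a 2x2 table, no continuity correction
chisq_brute <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  list(chi2 = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}
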