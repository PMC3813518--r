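# independent oracles kept deliberately simple and separate from the
# implementation they check

# ordinary least squares slope
ols_slope <- function(x, y) {
  unname(stats::coef(stats::lm(y ~ x))[2])
}

# exhaustive least-trimmed-squares slope: every 2-point base defines a
# candidate line; each candidate is scored by the sum of its h smallest
# squared residuals; the best candidate wins. Brute force, O(n^3 log n).
lts_slope <- function(x, y, h = floor(length(x) * 3 / 4)) {
  n <- length(x)
  best <- Inf
  best_slope <- NA_real_
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] == x[i]) next
      b <- (y[j] - y[i]) / (x[j] - x[i])
      a <- y[i] - b * x[i]
      r2 <- sort((y - a - b * x)^2)
      score <- sum(r2[1:h])
      if (score < best) {
        best <- score
        best_slope <- b
      }
    }
  }
  best_slope
}
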