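# Independent step-by-step evaluation of the Watson-Williams F statistic,
# deliberately coded with explicit loops and scalar accumulation so it shares
# no code path with watson_williams().
ww_oracle <- function(groups) {
  k <- length(groups)
  N <- 0
  sum_Ri <- 0
  Sx <- 0
  Sy <- 0
  for (g in groups) {
    sx <- 0
    sy <- 0
    for (a in g) {
      sx <- sx + cos(a)
      sy <- sy + sin(a)
    }
    sum_Ri <- sum_Ri + sqrt(sx^2 + sy^2)
    Sx <- Sx + sx
    Sy <- Sy + sy
    N <- N + length(g)
  }
  R <- sqrt(Sx^2 + Sy^2)
  rw <- sum_Ri / N
  if (rw < 0.53) {
    kap <- 2 * rw + rw^3 + (5 / 6) * rw^5
  } else if (rw < 0.85) {
    kap <- -0.4 + 1.39 * rw + 0.43 / (1 - rw)
  } else {
    kap <- 1 / (rw^3 - 4 * rw^2 + 3 * rw)
  }
  corr <- 1 + 3 / (8 * kap)
  f <- corr * ((N - k) * (sum_Ri - R)) / ((k - 1) * (N - sum_Ri))
  list(f = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}
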