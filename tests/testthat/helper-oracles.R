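# Independent brute-force oracles used to cross-check the package's
# closed-form implementations. Everything here is written as literally as
# possible (explicit loops, no shared code with the package internals).

# Two-way ANOVA variance components by explicit double loops, then the
# absolute-agreement single-measures ICC from first principles.
icc_bruteforce <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + x[i, j]
  grand <- grand / (n * k)
  ssr <- 0
  for (i in 1:n) {
    ri <- 0
    for (j in 1:k) ri <- ri + x[i, j]
    ri <- ri / k
    ssr <- ssr + k * (ri - grand)^2
  }
  ssc <- 0
  for (j in 1:k) {
    cj <- 0
    for (i in 1:n) cj <- cj + x[i, j]
    cj <- cj / n
    ssc <- ssc + n * (cj - grand)^2
  }
  sse <- 0
  for (i in 1:n) for (j in 1:k) {
    ri <- mean(x[i, ]); cj <- mean(x[, j])
    sse <- sse + (x[i, j] - ri - cj + grand)^2
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Literal step-down Holm adjustment: walk the sorted p-values, carrying the
# running maximum forward.
holm_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (r in 1:m) {
    cand <- (m - r + 1) * p[ord[r]]
    running <- max(running, cand)
    adj[ord[r]] <- min(1, running)
  }
  adj
}

# Percentile by hand: linear interpolation between order statistics with
# index h = (n - 1) * p + 1 (the inclusive convention).
percentile_bruteforce <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# small phantom config used where full default geometry is unnecessary
tiny_config <- function(...) {
  phantom_config(grid_shape = c(32L, 28L, 12L),
                 tumor_semiaxes = list(x = c(6, 8), y = c(6, 8), z = c(5, 7)),
                 ...)
}
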