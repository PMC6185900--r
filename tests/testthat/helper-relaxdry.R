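## Shared fixtures and independent oracles for the suite.

echo_grid <- function(n = 1000, spacing = 10) spacing * seq_len(n)

## Random two-component model with T2 ratio >= `min_ratio` and minor
## amplitude fraction >= `min_minor` (identifiable regime).
rand_model2 <- function(min_ratio = 2.5, min_minor = 0.05) {
  t2_short <- stats::runif(1, 15, 60)
  t2_long <- t2_short * stats::runif(1, min_ratio, 6)
  frac_long <- stats::runif(1, min_minor, 1 - min_minor)
  total <- stats::runif(1, 50, 150)
  multiexp_model(total * c(frac_long, 1 - frac_long), c(t2_long, t2_short))
}

## Closed-form non-negative least squares for exactly two exponential
## basis columns: try the unconstrained solution, else the best single-column
## fits with the other amplitude clamped at zero.
nnls2_oracle <- function(X, y) {
  a <- tryCatch(qr.solve(X, y), error = function(e) c(0, 0))
  if (all(a >= 0)) return(a)
  a1 <- max(sum(X[, 1] * y) / sum(X[, 1]^2), 0)
  a2 <- max(sum(X[, 2] * y) / sum(X[, 2]^2), 0)
  r1 <- sum((y - a1 * X[, 1])^2)
  r2 <- sum((y - a2 * X[, 2])^2)
  if (r1 <= r2) c(a1, 0) else c(0, a2)
}

## Dense grid-search oracle for the two-component decay fit: profiled
## residual over all (T2_long, T2_short) pairs from a log grid.
grid_oracle_rss <- function(times, y, n_grid = 30) {
  cand <- exp(seq(log(times[1]), log(times[length(times)]),
                  length.out = n_grid))
  best <- Inf
  for (i in 2:n_grid) for (j in 1:(i - 1)) {
    X <- cbind(exp(-times / cand[i]), exp(-times / cand[j]))
    a <- nnls2_oracle(X, y)
    rss <- sum((y - X %*% a)^2)
    if (rss < best) best <- rss
  }
  best
}

## Brute-force Kapur objective, written independently of the package:
## explicit per-cut entropy sums over the two histogram classes.
kapur_brute <- function(pixels) {
  counts <- tabulate(as.vector(pixels) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  score <- rep(-Inf, 255)
  for (s in 1:255) {
    lowp <- p[1:s]; highp <- p[(s + 1):256]
    P1 <- sum(lowp); P2 <- sum(highp)
    if (P1 <= 0 || P2 <= 0) next
    h <- function(q) { q <- q[q > 0] / sum(q); -sum(q * log(q)) }
    score[s] <- h(lowp) + h(highp)
  }
  which.max(score)
}

## Exhaustive consecutive-pair scan oracle for rupture detection.
scan_oracle <- function(time_min, icw, thr) {
  hits <- numeric(0)
  for (i in 2:length(icw))
    if (icw[i - 1] - icw[i] >= thr) hits <- c(hits, time_min[i])
  hits
}
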