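# Independent oracles used by the tests. These are deliberately naive
# implementations (double loops, fine-grid quadrature) kept separate from
# the package code paths they check.

# Brute-force normalized cross-correlation at one delay m:
# sum over t of centred x(t) * y(t - m), normalized by the series length
# and the full-series population sds (cross-correlogram convention).
brute_rxy <- function(x, y, m) {
  N <- length(x)
  xm <- mean(x); ym <- mean(y)
  sx <- sqrt(sum((x - xm)^2) / N)
  sy <- sqrt(sum((y - ym)^2) / N)
  if (sx == 0 || sy == 0) return(NA_real_)
  acc <- 0; n_ov <- 0
  for (t in 1:N) {
    u <- t - m
    if (u >= 1 && u <= N) {
      acc <- acc + (x[t] - xm) * (y[u] - ym)
      n_ov <- n_ov + 1
    }
  }
  if (n_ov == 0) return(NA_real_)
  acc / (N * sx * sy)
}

# Independent splicing oracle: build the exact cumulative integral of the
# piecewise-constant profile (cell edges at sample midpoints) and evaluate
# it at the 16 segment boundaries.
splice_oracle <- function(pos, val, n_seg = 15) {
  o <- order(pos); pos <- pos[o]; val <- val[o]
  n <- length(pos)
  edges <- c(pos[1], (pos[-1] + pos[-n]) / 2, pos[n])
  Fcum <- c(0, cumsum(val * diff(edges)))
  Fat <- function(s) {
    i <- pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1), n)
    Fcum[i] + (s - edges[i]) * val[i]
  }
  b <- seq(pos[1], pos[n], length.out = n_seg + 1)
  diff(Fat(b)) / ((pos[n] - pos[1]) / n_seg)
}

# Analytic peak of a Gaussian spot of amplitude a and sd s after isotropic
# Gaussian blur of sd sigma, evaluated at distance r from the spot centre.
blurred_spot <- function(a, s, sigma, r = 0) {
  s2 <- s^2 + sigma^2
  a * (s^2 / s2) * exp(-r^2 / (2 * s2))
}
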