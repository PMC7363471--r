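# Shared fixtures, generated in code. Heavier simulated objects are cached in
# an environment so several test files can reuse them within one run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# independent transcription of the eight node equations, used as the oracle
# for the compiled drift
oracle_drift <- function(s, x0, a, p, b2, cz = 0, cx = 0) {
  x1 <- s[1]; y1 <- s[2]; z <- s[3]; x2 <- s[4]; y2 <- s[5]
  g <- s[6]; x3 <- s[7]; y3 <- s[8]
  f1 <- if (x1 < 0) x1^3 - 3 * x1^2 else (x2 - 0.6 * (z - 4)^2) * x1
  f2 <- if (x2 < -0.25) 0 else 6 * (x2 + 0.25)
  c(y1 - f1 - z + 3.1,
    1 - 5 * x1^2 - y1,
    (4 * (x1 - x0) - z - cz) / 28571,
    -y2 + x2 - x2^3 + 0.45 + b2 * g - 0.3 * (z - 3.5),
    (-y2 + f2) / 25,
    -0.01 * (g - 0.1 * x1),
    0.02 * (y3 - x3^3 + 3 * x3^2 + cx),
    0.02 * (a - 10 * x3 - y3))
}

# brute-force O(N^2) sample entropy (Chebyshev, self-matches excluded)
oracle_sampen <- function(x, m = 1, r) {
  N <- length(x)
  nm <- N - m
  A <- 0; B <- 0
  for (i in 1:(nm - 1)) {
    for (j in (i + 1):nm) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(Inf)
  -log(A / B)
}

# two-sample ECDF sup-distance evaluated at every jump point
oracle_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

toy_connectome <- function(n = 4, seed = 7) synthetic_connectome(n, seed = seed)

short_config <- function(duration = 160, seed = 1, ...) {
  integration_config(duration = duration, seed = seed, ...)
}
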