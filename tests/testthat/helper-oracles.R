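# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they verify.

# Lower convex hull baseline by recursive chord splitting: start from the
# end points; wherever a point dips below the current chord, anchor the
# deepest one and recurse. O(n^2) worst case, geometry-only.
oracle_lower_hull <- function(x, y) {
  rec <- function(i, k) {
    if (k - i < 2L) return(integer(0))
    mid <- (i + 1L):(k - 1L)
    chord <- y[i] + (x[mid] - x[i]) / (x[k] - x[i]) * (y[k] - y[i])
    dev <- y[mid] - chord
    m <- which.min(dev)
    if (dev[m] < -1e-13 * max(1, abs(y[i]), abs(y[k]))) {
      j <- mid[m]
      c(rec(i, j), j, rec(j, k))
    } else integer(0)
  }
  n <- length(x)
  idx <- c(1L, rec(1L, n), n)
  stats::approx(x[idx], y[idx], xout = x)$y
}

# stress index by the literal formula: ED over the window divided by
# n_total / n_w
oracle_si <- function(y_stress, y_control, wavenumbers, lo, hi, n_total) {
  keep <- wavenumbers >= lo & wavenumbers <= hi
  ed <- sqrt(sum((y_stress[keep] - y_control[keep])^2))
  ed * sum(keep) / n_total
}

# quadratic least squares straight from the normal equations
oracle_quadfit <- function(si, rc) {
  X <- cbind(1, si, si^2)
  beta <- solve(t(X) %*% X, t(X) %*% rc)
  c(c = beta[1], b = beta[2], a = beta[3])
}

# piecewise-linear interpolation evaluated point by point
oracle_interp <- function(x_asc, y, xq) {
  vapply(xq, function(q) {
    i <- max(which(x_asc <= q))
    if (x_asc[i] == q) return(y[i])
    t <- (q - x_asc[i]) / (x_asc[i + 1] - x_asc[i])
    (1 - t) * y[i] + t * y[i + 1]
  }, numeric(1))
}

# small helper: a random smooth test spectrum (descending grid)
random_spectrum <- function(n = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- seq(2000, 1000, length.out = n)
  y <- 0.5 + 0.3 * sin(x / 90) + cumsum(rnorm(n, 0, 0.01))
  ftir_spectrum(x, y)
}
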