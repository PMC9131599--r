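# Independent oracles used across the suite. These deliberately avoid the
# package's own integration/overlap code paths.

# Dense numeric oracle for the common area: the pointwise minimum is formed on
# the shared grid, treated as a piecewise-linear function, and integrated
# numerically on a `factor`-times oversampled grid. Independent of the
# package's closed-form trapezoid (and exact for piecewise-linear input, so
# the two must agree to floating precision).
oracle_common_area <- function(e1, e2, factor = 100) {
  m <- pmin(e1, e2)
  m <- c(m, m[1])  # close the periodic cycle base
  n <- length(m)
  xd <- seq(1, n, length.out = (n - 1) * factor + 1)
  y <- approx(seq_len(n), m, xout = xd)$y
  h <- diff(xd)
  sum((y[-1] + y[-length(y)]) / 2 * h)
}

# Envelope-level variant: interpolates each envelope onto the dense grid
# before taking the minimum, so crossing knots between grid points are
# resolved. Always >= the grid-level value (the minimum of linear functions is
# concave between shared knots); quantifies the cost of ignoring sub-knots.
oracle_common_area_crossings <- function(e1, e2, factor = 100) {
  e1 <- c(e1, e1[1]); e2 <- c(e2, e2[1])  # close the periodic cycle base
  n <- length(e1)
  xd <- seq(1, n, length.out = (n - 1) * factor + 1)
  f1 <- approx(seq_len(n), e1, xout = xd)$y
  f2 <- approx(seq_len(n), e2, xout = xd)$y
  y <- pmin(f1, f2)
  h <- diff(xd)
  sum((y[-1] + y[-length(y)]) / 2 * h)
}

# Brute-force interval overlap on a 1 ms grid.
oracle_overlap_s <- function(eventsA, eventsB, t_max, dt = 1e-3) {
  grid <- seq(0, t_max, by = dt)
  on_mask <- function(ev) {
    m <- rep(FALSE, length(grid))
    for (i in seq_len(nrow(ev))) {
      m <- m | (grid >= ev$onset_s[i] & grid < ev$offset_s[i])
    }
    m
  }
  sum(on_mask(eventsA) & on_mask(eventsB)) * dt
}

# Random rectified envelope with a mix of smooth bumps and noise.
random_envelope <- function(n = 200) {
  x <- seq(0, 1, length.out = n)
  y <- abs(runif(1, 0.1, 1) * sin(2 * pi * runif(1, 0.5, 3) * x + runif(1, 0, 2 * pi))) +
    runif(1, 0, 0.3) * runif(n)
  y
}

# Minimal raw-channel construction for filter tests.
make_channel <- function(samples, fs_hz = 1000, muscle = "VL") {
  structure(list(fs_hz = fs_hz, t0 = 0, samples = samples, muscle = muscle),
            class = "raw_emg_channel")
}

make_envelope <- function(values, fs_hz = 1000, muscle = "VL") {
  structure(list(fs_hz = fs_hz, t0 = 0, values = values, muscle = muscle),
            class = "envelope_trace")
}
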