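# Independent oracles and tiny fixture builders shared across test files.
# Everything here deliberately avoids the package's own code paths.

# Eq-by-hand RMSSD: explicit loop, denominator = number of differences.
brute_rmssd <- function(rr) {
  if (length(rr) < 2) return(NA_real_)
  s <- 0
  for (i in 2:length(rr)) s <- s + (rr[i] - rr[i - 1])^2
  sqrt(s / (length(rr) - 1))
}

# Mann-Whitney U by O(n1*n2) pair counting (pairs with x > y, ties half).
brute_u <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s
}

# Benjamini-Hochberg step-up written out by hand.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- prev
  }
  q
}

# Analytic two-sided power of the Welch t test via the noncentral t
# distribution with Satterthwaite degrees of freedom.
welch_power_oracle <- function(n1, m1, s1, n2, m2, s2, alpha = 0.05) {
  se2 <- s1^2 / n1 + s2^2 / n2
  nu <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  ncp <- (m1 - m2) / sqrt(se2)
  tc <- qt(1 - alpha / 2, nu)
  1 - pt(tc, nu, ncp) + pt(-tc, nu, ncp)
}

make_stream <- function(rr) {
  reconstruct_timestamps(new_rr_series(
    rr, as.POSIXct("2019-11-03 10:15:00", tz = "UTC")))
}

make_trace_1hz <- function(distance_cm) {
  new_proximity_trace((seq_along(distance_cm) - 1) * 1000, distance_cm,
                      resolution = "1hz")
}

quiet_cfg <- function(...) {
  # small, fast session preset used where the scientific presets don't matter
  sim_config(n_asd = 2, n_cp = 2, sample_rate_hz = 5, ...)
}
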