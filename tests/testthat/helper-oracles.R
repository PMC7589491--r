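# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

default_geo <- function(sample_volume = 1) {
  cell_geometry(area = 1.77, donor_volume = 1, receiver_volume = 7,
                sample_volume = sample_volume)
}

make_experiment <- function(true_peff = 1e-5, noise_cv = 0,
                            n_replicates = 1, seed = 1,
                            sample_volume = 1, c0 = 10000,
                            schedule = sampling_schedule()) {
  simulate_permeation(simulation_config(
    true_peff = true_peff, geometry = default_geo(sample_volume),
    schedule = schedule, donor_concentration_0 = c0,
    n_replicates = n_replicates, noise_cv = noise_cv, seed = seed))
}

# Independent linear-window oracle: exhaustive enumeration with lm(),
# same tie rule (higher R2, then longer window, then later start).
oracle_linear_portion <- function(times, values, min_window = 4) {
  n <- length(times)
  best <- NULL
  for (s in seq_len(n - min_window + 1L)) {
    for (e in seq(s + min_window - 1L, n)) {
      y <- values[s:e]
      if (stats::var(y) < 1e-300) next
      r2 <- summary(stats::lm(y ~ times[s:e]))$r.squared
      cand <- list(start = s, end = e, r_squared = r2)
      if (is.null(best)) { best <- cand; next }
      if (r2 > best$r_squared + 1e-9) { best <- cand; next }
      if (abs(r2 - best$r_squared) <= 1e-9) {
        len <- e - s + 1L; blen <- best$end - best$start + 1L
        if (len > blen || (len == blen && s > best$start)) best <- cand
      }
    }
  }
  best
}

# Numerical two-compartment oracle: integrates
#   dCr/dt = peff * S * (Cd - Cr) / Vr,  Cd = (q_total - Cr*Vr)/Vd
# with deSolve at tight tolerances.
ode_receiver_end <- function(c_start, q_total, peff, geo, delta_t) {
  rhs <- function(t, y, parms) {
    cd <- (q_total - y[1] * geo$receiver_volume) / geo$donor_volume
    list(peff * geo$area * (cd - y[1]) / geo$receiver_volume)
  }
  out <- deSolve::ode(y = c(cr = c_start), times = c(0, delta_t),
                      func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), "cr"])
}
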