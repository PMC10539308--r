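# Independent closed-form oracles used across tests.

# Magnitude CDF of a mixture of 2-D Brownian states, written from the
# closed form directly (kept separate from the package's jump_cdf).
oracle_mixture_cdf <- function(r, fractions, coeffs, dt) {
  out <- 0
  for (i in seq_along(fractions)) {
    v <- 4 * coeffs[i] * dt
    out <- out + fractions[i] * if (v > 0) 1 - exp(-r^2 / v) else (r >= 0)
  }
  out
}

# Quadratic ligand-depletion isotherm evaluated directly.
oracle_quadratic_isotherm <- function(x, kd, b0, bmax, c) {
  s <- c + x + kd
  b0 + (bmax - b0) * (s - sqrt(s^2 - 4 * c * x)) / (2 * c)
}

# Build a survival_curve object from an explicit grid (analytic curves).
make_curve <- function(times, survival, corrected = TRUE, k_b = 0) {
  structure(
    list(times = times, survival = survival, corrected = corrected,
         k_b_applied = if (corrected) k_b else NA_real_,
         n_molecules = length(times), min_duration = times[1],
         censoring = "include"),
    class = "survival_curve"
  )
}

# Dwell set whose empirical survival reproduces S() exactly on a frame grid.
dwells_from_survival <- function(S, n, t_max, frame_interval = 0.5,
                                 t0 = 2.5) {
  tg <- seq(t0, t_max, by = frame_interval)
  counts <- round(n * S(tg))
  drops <- c(-diff(counts), counts[length(counts)])
  dwell_set(rep(tg, drops), frame_interval = frame_interval,
            min_duration = t0)
}

# Simple straight-line track with given frames and x positions (y = 0).
make_track <- function(frames, x, y = rep(0, length(x)), cell = "c1",
                       id = "t1") {
  list(cell_id = cell, track_id = id,
       points = data.frame(frame = as.integer(frames), x = x, y = y))
}
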