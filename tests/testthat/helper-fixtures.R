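# shared fixtures, built once per test run

fixture_env <- new.env(parent = emptyenv())

# small 1-slot corpus used across backend tests
tiny_corpus <- function() {
  if (is.null(fixture_env$corpus)) {
    fixture_env$corpus <- synth_corpus(
      seed = 101, n_slots = 1, words_per_slot = 10, utterances_per_word = 4
    )
  }
  fixture_env$corpus
}

tiny_noise <- function() {
  if (is.null(fixture_env$noise)) {
    fixture_env$noise <- synth_noise(tiny_corpus(), duration_s = 15, seed = 102)
  }
  fixture_env$noise
}

# geometry with few fibers for nerve/spread unit tests
small_geometry <- function(n_fibers = 50) {
  cochlea_geometry(n_fibers = n_fibers)
}

# a single-fiber rectangular-pulse drive matrix on the nerve time grid
pulse_drive <- function(current, t_on_ms, dur_ms, total_ms, dt_us = 10,
                        n_fibers = 1) {
  n_t <- round(total_ms * 1000 / dt_us)
  m <- matrix(0, n_fibers, n_t)
  on <- round(t_on_ms * 1000 / dt_us) + 1
  off <- on + round(dur_ms * 1000 / dt_us) - 1
  m[, on:off] <- current
  structure(m, time_step_us = dt_us, fiber_pos = seq_len(n_fibers))
}

# independent closed-form LIF oracle for a noiseless rectangular pulse:
# V_k = (1 - a) * sum_{j<=k} a^(k-j) I_j; returns first crossing step (1-based)
lif_crossing_oracle <- function(drive_row, dt_ms, tau_m_ms, threshold) {
  a <- exp(-dt_ms / tau_m_ms)
  v <- 0
  for (k in seq_along(drive_row)) {
    v <- a * v + (1 - a) * drive_row[k]
    if (v >= threshold) return(k)
  }
  NA_integer_
}
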