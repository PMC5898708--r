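#' Auditory-nerve model parameters
#'
#' Parameters of the stochastic leaky integrate-and-fire fiber population:
#' membrane leak, spiking threshold with a relative-spread perturbation
#' (giving a sigmoidal firing-efficiency curve whose coefficient of variation
#' approximates `relative_spread`), per-fiber absolute refractory periods
#' (truncated normal), an exponentially decaying relative-refractory threshold
#' elevation, conduction latency with Gaussian jitter, and per-step membrane
#' noise.
#'
#' Parameter values are declared defaults typical for electrically stimulated
#' auditory-nerve fibers; every one is configurable and downstream behaviour
#' is calibrated through the internal-representation gain, not through these.
#'
#' @param tau_m_ms Membrane time constant (ms).
#' @param threshold Threshold drive (uA-equivalent at the fiber).
#' @param relative_spread CV of the stochastic threshold perturbation.
#' @param abs_ref_mean_ms,abs_ref_sd_ms Absolute refractory period draw
#'   (truncated normal > 0), per fiber.
#' @param rel_ref_tau_ms Relative-refractory decay time constant (ms).
#' @param rel_ref_strength Peak relative threshold elevation factor.
#' @param latency_mean_ms Spike latency (ms).
#' @param jitter_sd_ms Latency jitter sd (ms).
#' @param membrane_noise_sd Per-step membrane noise sd (uA-equivalent);
#'   default scales with `relative_spread * threshold`.
#' @param time_step_us Simulation step (us).
#' @return An object of class `an_params`.
#' @export
an_params <- function(tau_m_ms = 0.5, threshold = 12, relative_spread = 0.06,
                      abs_ref_mean_ms = 0.7, abs_ref_sd_ms = 0.1,
                      rel_ref_tau_ms = 1.3, rel_ref_strength = 1,
                      latency_mean_ms = 0.45, jitter_sd_ms = 0.1,
                      membrane_noise_sd = NULL, time_step_us = 10) {
  stopifnot(tau_m_ms > 0, threshold > 0, relative_spread >= 0,
            abs_ref_mean_ms > 0, rel_ref_tau_ms > 0, time_step_us > 0)
  structure(
    list(
      tau_m_ms = tau_m_ms, threshold = threshold,
      relative_spread = relative_spread,
      abs_ref_mean_ms = abs_ref_mean_ms, abs_ref_sd_ms = abs_ref_sd_ms,
      rel_ref_tau_ms = rel_ref_tau_ms, rel_ref_strength = rel_ref_strength,
      latency_mean_ms = latency_mean_ms, jitter_sd_ms = jitter_sd_ms,
      membrane_noise_sd = membrane_noise_sd %||%
        (0.25 * relative_spread * threshold),
      time_step_us = time_step_us
    ),
    class = "an_params"
  )
}

#' Simulate the auditory-nerve population
#'
#' Runs every fiber as a leaky integrate-and-fire unit over the fiber x time
#' drive matrix from [spread_excitation()]. Fully reproducible given `seed`
#' (each fiber has an independent deterministic random stream).
#'
#' @param excitation Fiber x time drive matrix with attribute `time_step_us`
#'   (from [spread_excitation()]).
#' @param params An [an_params()].
#' @param seed Integer seed.
#' @return A `spike_raster`: list with `$spikes` (list of sorted spike-time
#'   vectors in seconds per fiber), `$fiber_pos` (mm), `$duration` (s).
#' @export
simulate_population <- function(excitation, params = an_params(), seed = 1) {
  dt_ms <- attr(excitation, "time_step_us") / 1000
  stopifnot(!is.null(dt_ms))
  spikes <- lif_population(
    excitation, dt_ms, params$tau_m_ms, params$threshold,
    params$relative_spread, params$abs_ref_mean_ms, params$abs_ref_sd_ms,
    params$rel_ref_tau_ms, params$rel_ref_strength,
    params$latency_mean_ms, params$jitter_sd_ms,
    params$membrane_noise_sd, as.integer(seed)
  )
  structure(
    list(
      spikes = lapply(spikes, function(s) sort(s) / 1000),
      fiber_pos = attr(excitation, "fiber_pos"),
      duration = ncol(excitation) * dt_ms / 1000
    ),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d fibers, %.3f s, %d spikes\n",
              length(x$spikes), x$duration, sum(lengths(x$spikes))))
  invisible(x)
}

#' Export a spike raster as a tidy event list
#'
#' @param x A `spike_raster`.
#' @param ... Unused.
#' @return Tibble with `fiber`, `position_mm`, `time` (s).
#' @export
tidy.spike_raster <- function(x, ...) {
  tibble(
    fiber = rep(seq_along(x$spikes), lengths(x$spikes)),
    position_mm = rep(x$fiber_pos, lengths(x$spikes)),
    time = unlist(x$spikes) %0% numeric(0)
  )
}
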