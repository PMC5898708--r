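#' SNR protocol for the train/test score matrix
#'
#' @param snr_grid SNR grid in dB (sorted ascending).
#' @param repetitions Repetitions per SNR; the last is held out for testing,
#'   the rest train.
#' @param n_sentences Sentences per repetition.
#' @return An object of class `snr_protocol`.
#' @export
snr_protocol <- function(snr_grid = seq(-12, 21, by = 3), repetitions = 8,
                         n_sentences = 120) {
  if (is.unsorted(snr_grid, strictly = TRUE)) {
    abort("`snr_grid` must be sorted ascending")
  }
  stopifnot(repetitions >= 2, n_sentences >= 1)
  structure(
    list(snr_grid = snr_grid, repetitions = repetitions,
         n_sentences = n_sentences),
    class = "snr_protocol"
  )
}

#' Full pipeline configuration
#'
#' Bundles every stage parameter set with two presets: `"paper"` mirrors the
#' full published protocol (5-slot corpus, 120 sentences, 8 repetitions,
#' SNRs -12 to 21 dB, 1000 fibers) and `"desk"` is a scaled-down protocol
#' (1-slot corpus of 10 words, 30 sentences, 3 repetitions, SNRs -12 to 3 dB,
#' 100 fibers) sized so that a full SRT estimate runs in minutes on one CPU.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param lambda_mm Idealized spatial-spread width in mm (used when no fitted
#'   profile set is supplied).
#' @param sigma_int Internal-noise standard deviation.
#' @param ... Overrides for any of the component fields (`geometry`, `ace`,
#'   `an`, `ir`, `hmm`, `protocol`, `corpus_spec`, `gain`).
#' @return An object of class `ci_config`.
#' @export
ci_config <- function(preset = c("desk", "paper"), lambda_mm = 9,
                      sigma_int = 0.19, ...) {
  preset <- match.arg(preset)
  base <- if (preset == "paper") {
    list(
      corpus_spec = list(n_slots = 5, words_per_slot = 10,
                         utterances_per_word = 8),
      geometry = cochlea_geometry(n_fibers = 1000),
      an = an_params(time_step_us = 10),
      protocol = snr_protocol(seq(-12, 21, by = 3), repetitions = 8,
                              n_sentences = 120)
    )
  } else {
    list(
      corpus_spec = list(n_slots = 1, words_per_slot = 10,
                         utterances_per_word = 8),
      geometry = cochlea_geometry(n_fibers = 100),
      an = an_params(time_step_us = 20),
      protocol = snr_protocol(seq(-12, 3, by = 3), repetitions = 3,
                              n_sentences = 30)
    )
  }
  cfg <- utils::modifyList(
    c(base, list(
      preset = preset, lambda_mm = lambda_mm, sigma_int = sigma_int,
      ace = ace_params(), ir = ir_params(),
      hmm = hmm_params(), gain = NULL
    )),
    list(...)
  )
  structure(cfg, class = "ci_config")
}

#' @export
print.ci_config <- function(x, ...) {
  cat(sprintf(
    "<ci_config> preset '%s': lambda = %g mm, sigma_int = %g, %d fibers,\n  SNRs [%s] dB, %d sentences x %d repetitions\n",
    x$preset, x$lambda_mm, x$sigma_int, x$geometry$n_fibers,
    paste(x$protocol$snr_grid, collapse = ", "),
    x$protocol$n_sentences, x$protocol$repetitions
  ))
  invisible(x)
}

#' Run the model front end on one audio signal
#'
#' Audio to internal representation: ACE encoding, spatial spread onto the
#' fiber array, stochastic auditory-nerve simulation, and temporal
#' integration with forward masking. Internal noise is *not* applied here
#' (see [apply_internal_noise()]).
#'
#' @param audio Mono waveform at the configured sample rate.
#' @param config A [ci_config()].
#' @param profiles A `spread_profile_set`; defaults to idealized profiles at
#'   `config$lambda_mm`.
#' @param seed Integer seed for the nerve simulation.
#' @param gain IR gain override (defaults to `config$gain` or 1).
#' @return An `internal_representation`.
#' @export
frontend_ir <- function(audio, config, profiles = NULL, seed = 1,
                        gain = NULL) {
  profiles <- profiles %||% idealized_profiles(config$geometry,
                                               config$lambda_mm)
  eg <- ace_encode(audio, config$ace)
  exc <- spread_excitation(eg, profiles, config$geometry,
                           time_step_us = config$an$time_step_us)
  raster <- simulate_population(exc, config$an, seed = seed)
  irp <- config$ir
  irp$gain <- gain %||% config$gain %||% irp$gain
  grouping <- build_grouping(config$geometry)
  integrate_spikes(raster, grouping, irp)
}

#' Calibrate the pipeline gain on clean corpus material
#'
#' Runs the front end (gain 1) on clean sentences until at least
#' `min_duration_s` of material is accumulated and returns the gain that maps
#' the 99th percentile of IR amplitudes to 50 (see [calibrate_gain()]).
#'
#' @param corpus A [synth_corpus()] result.
#' @param config A [ci_config()].
#' @param profiles Optional `spread_profile_set`.
#' @param seed Integer seed.
#' @param min_duration_s Minimum calibration material duration.
#' @return The gain (scalar).
#' @export
calibrate_pipeline_gain <- function(corpus, config, profiles = NULL,
                                    seed = 1, min_duration_s = 10) {
  fs <- corpus$sample_rate
  sent <- corpus_sentences(corpus, n = 200, seed = child_seed(seed, "cal"))
  irs <- list()
  total <- 0
  for (i in seq_len(nrow(sent))) {
    sig <- sent$signal[[i]]
    irs[[i]] <- frontend_ir(sig, config, profiles,
                            seed = child_seed(seed, "cal_an", i), gain = 1)
    total <- total + length(sig) / fs
    if (total >= min_duration_s) break
  }
  calibrate_gain(irs)
}
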