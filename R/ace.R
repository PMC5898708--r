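#' ACE-style coding strategy parameters
#'
#' Parameter set for the n-of-m coding strategy: short-time spectral analysis
#' into `n_channels` contiguous bands, per-frame selection of the `n_maxima`
#' largest channel envelopes, logarithmic loudness-growth compression between
#' `base_level` and `saturation_level`, and linear mapping onto the electrical
#' dynamic range `[current_at_threshold, current_at_comfort]`. Channels map to
#' electrodes in reversed tonotopic order: channel 1 (lowest band) drives
#' electrode 1 (most apical).
#'
#' @param n_channels Number of analysis channels / electrodes.
#' @param n_maxima Maxima selected per frame (`1 <= n_maxima <= n_channels`).
#' @param channel_rate Per-channel stimulation rate in pulses/s.
#' @param phase_width_us,inter_phase_gap_us Biphasic pulse shape in
#'   microseconds.
#' @param analysis_window FFT analysis window length in samples.
#' @param base_level,saturation_level Envelope bounds of the loudness-growth
#'   function (dimensionless, `saturation_level > base_level`).
#' @param compression_steepness Steepness of the logarithmic loudness growth.
#' @param current_at_threshold,current_at_comfort Electrical dynamic range in
#'   uA (global; threshold/comfort levels are not individualized).
#' @param sample_rate Expected audio sample rate in Hz.
#' @return An object of class `ace_params`.
#' @export
ace_params <- function(n_channels = 22, n_maxima = 8, channel_rate = 900,
                       phase_width_us = 25, inter_phase_gap_us = 8,
                       analysis_window = 128,
                       base_level = 0.0156, saturation_level = 0.5859,
                       compression_steepness = 416.2,
                       current_at_threshold = 100, current_at_comfort = 500,
                       sample_rate = 16000) {
  stopifnot(
    n_maxima >= 1, n_maxima <= n_channels,
    saturation_level > base_level,
    current_at_comfort > current_at_threshold,
    channel_rate > 0, analysis_window >= 32
  )
  structure(
    list(
      n_channels = n_channels, n_maxima = n_maxima,
      channel_rate = channel_rate,
      phase_width_us = phase_width_us,
      inter_phase_gap_us = inter_phase_gap_us,
      analysis_window = analysis_window,
      base_level = base_level, saturation_level = saturation_level,
      compression_steepness = compression_steepness,
      current_at_threshold = current_at_threshold,
      current_at_comfort = current_at_comfort,
      sample_rate = sample_rate
    ),
    class = "ace_params"
  )
}

# channel -> FFT-bin allocation over 188-7938 Hz: linear spacing (one 125 Hz
# bin per channel at 16 kHz / 128 samples) below ~1.2 kHz, logarithmic above;
# every channel is guaranteed at least one bin
ace_band_bins <- function(params) {
  fs <- params$sample_rate
  nfft <- params$analysis_window
  df <- fs / nfft
  n_lin <- 8
  edges_lin <- 188 + df * (0:n_lin)
  n_log <- params$n_channels - n_lin
  edges_log <- edges_lin[n_lin + 1] *
    (7938 / edges_lin[n_lin + 1])^(seq_len(n_log) / n_log)
  edges <- c(edges_lin, edges_log)
  centers <- (seq_len(floor(nfft / 2)) ) * df  # bin k has centre k*df
  bins <- lapply(seq_len(params$n_channels), function(i) {
    which(centers >= edges[i] & centers < edges[i + 1])
  })
  if (any(lengths(bins) == 0)) abort("empty analysis band; widen the window")
  bins
}

#' Mix speech and noise at a target SNR
#'
#' Draws a random segment of the noise (position set by `offset_seed`), scales
#' it so that `20*log10(rms(speech)/rms(noise)) = snr_db`, and adds it to the
#' unscaled speech. The clean components are kept as an attribute so the
#' realized SNR can be verified.
#'
#' @param speech,noise Numeric waveforms at equal sample rates; `noise` must
#'   be at least as long as `speech`.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param offset_seed Integer seed for the noise segment position.
#' @param sample_rate Optional; checked against attributes when both signals
#'   carry a `sample_rate` attribute.
#' @return The mixture waveform, with attribute `components` (list with
#'   `speech` and `noise`).
#' @export
mix_at_snr <- function(speech, noise, snr_db, offset_seed = 1,
                       sample_rate = NULL) {
  fs_s <- attr(speech, "sample_rate")
  fs_n <- attr(noise, "sample_rate")
  if (!is.null(fs_s) && !is.null(fs_n) && fs_s != fs_n) {
    abort("speech and noise sample rates differ")
  }
  if (length(noise) < length(speech)) abort("noise shorter than speech")
  set.seed(offset_seed)
  start <- sample.int(length(noise) - length(speech) + 1, 1)
  seg <- noise[start:(start + length(speech) - 1)]
  gain <- rms(speech) / (rms(seg) * 10^(snr_db / 20))
  seg <- seg * gain
  structure(as.numeric(speech) + seg,
            components = list(speech = as.numeric(speech), noise = seg),
            sample_rate = fs_s %||% sample_rate)
}

# framewise pre-compression channel envelopes (frames x channels); a sine at
# a band centre with amplitude a yields an envelope of about a
ace_envelopes <- function(audio, params = ace_params()) {
  x <- as.numeric(audio)
  fs <- params$sample_rate
  nfft <- params$analysis_window
  hop <- max(1L, round(fs / params$channel_rate))
  bins <- ace_band_bins(params)
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(nfft) - 1) / (nfft - 1)))
  win_gain <- sum(win) / 2
  if (length(x) < nfft) x <- c(x, numeric(nfft - length(x)))
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  env <- matrix(0, length(starts), params$n_channels)
  for (fi in seq_along(starts)) {
    seg <- x[starts[fi]:(starts[fi] + nfft - 1)] * win
    X <- fft(seg)
    p <- Mod(X[2:(floor(nfft / 2) + 1)])^2
    env[fi, ] <- vapply(bins, function(b) sqrt(sum(p[b])), numeric(1)) / win_gain
  }
  structure(env, starts = starts, hop = hop, n_padded = length(x))
}

#' Encode audio into an electrodogram with an n-of-m strategy
#'
#' Short-time spectral analysis (hann window, FFT) produces `n_channels`
#' envelopes per frame; the `n_maxima` largest envelopes above `base_level`
#' are selected, compressed by the logarithmic loudness-growth function and
#' mapped linearly onto `[current_at_threshold, current_at_comfort]`. Pulses
#' are placed at `channel_rate` pulses/s per selected channel and interleaved
#' within the frame (no two pulses are simultaneous), ordered from base to
#' apex within a frame.
#'
#' @param audio Mono numeric waveform.
#' @param params An [ace_params()].
#' @return An electrodogram: tibble with columns `electrode` (1 = apical),
#'   `time` (s), `current` (uA), of class `electrodogram` with attributes
#'   `params`, `duration`, `n_electrodes`.
#' @export
ace_encode <- function(audio, params = ace_params()) {
  if (is.matrix(audio) && ncol(audio) > 1) abort("audio must be mono")
  fs <- params$sample_rate
  env <- ace_envelopes(audio, params)
  starts <- attr(env, "starts")
  hop <- attr(env, "hop")
  n_padded <- attr(env, "n_padded")
  frame_dur <- hop / fs

  B <- params$base_level; M <- params$saturation_level
  rho <- params$compression_steepness
  Tl <- params$current_at_threshold; Cl <- params$current_at_comfort
  slot_dur <- frame_dur / params$n_maxima

  acc_e <- vector("list", length(starts))
  acc_t <- vector("list", length(starts))
  acc_c <- vector("list", length(starts))
  for (fi in seq_along(starts)) {
    e <- env[fi, ]
    cand <- which(e > B)
    if (!length(cand)) next
    sel <- cand[order(e[cand], decreasing = TRUE)][seq_len(min(params$n_maxima, length(cand)))]
    sel <- sort(sel, decreasing = TRUE) # base-to-apex stimulation order
    v <- pmin(e[sel], M)
    p <- log(1 + rho * (v - B) / (M - B)) / log(1 + rho)
    acc_e[[fi]] <- sel
    acc_t[[fi]] <- (starts[fi] - 1) / fs + (seq_along(sel) - 1) * slot_dur
    acc_c[[fi]] <- Tl + p * (Cl - Tl)
  }
  eg <- tibble(
    electrode = unlist(acc_e) %0% integer(0),
    time = unlist(acc_t) %0% numeric(0),
    current = unlist(acc_c) %0% numeric(0)
  )
  structure(
    eg,
    class = c("electrodogram", class(eg)),
    params = params,
    duration = n_padded / fs,
    n_electrodes = params$n_channels
  )
}

#' @export
print.electrodogram <- function(x, ...) {
  cat(sprintf("<electrodogram> %d pulses on %d electrodes, %.3f s\n",
              nrow(x), attr(x, "n_electrodes"), attr(x, "duration")))
  NextMethod()
}

#' Read / write electrodograms as delimited text
#'
#' Tabular format: electrode index (1-22, apical to basal), pulse time in
#' seconds, current in uA.
#'
#' @param electrodogram An `electrodogram`.
#' @param path File path.
#' @return Tibble (reader) / `path` invisibly (writer).
#' @export
write_electrodogram <- function(electrodogram, path) {
  utils::write.csv(as.data.frame(electrodogram), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrodogram
#' @export
read_electrodogram <- function(path) {
  as_tibble(utils::read.csv(path))
}

#' Center frequencies of the analysis channels
#'
#' @param params An [ace_params()].
#' @return Numeric vector of channel center frequencies in Hz.
#' @export
ace_center_freqs <- function(params = ace_params()) {
  df <- params$sample_rate / params$analysis_window
  vapply(ace_band_bins(params), function(b) mean(b) * df, numeric(1))
}
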