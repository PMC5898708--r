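#' Synthesize a closed-vocabulary matrix-sentence corpus
#'
#' Generates a stand-in for a matrix sentence test: a fixed number of slots
#' (word positions), a closed vocabulary per slot, and several utterances per
#' word. Words are synthetic harmonic complexes, not recorded speech: each
#' word has a word-specific fundamental and a word-specific spectral-envelope
#' trajectory (formant-like peaks gliding over the word), and each utterance
#' adds small random perturbations of pitch, duration and envelope so that
#' utterances of one word differ but stay closer to each other than to other
#' words. The generator is a pure function of `(seed, spec)`.
#'
#' @param seed Integer seed.
#' @param n_slots Number of sentence slots.
#' @param words_per_slot Vocabulary size per slot (>= 2).
#' @param utterances_per_word Utterances per word (>= 2).
#' @param sample_rate Sampling rate in Hz (>= 8000).
#' @param word_duration_s Nominal word duration in seconds.
#' @return An object of class `ci_corpus`: `$utterances` is a tibble with
#'   columns `slot`, `word`, `utterance`, `signal` (list column of numeric
#'   waveforms), plus `$sample_rate`, `$n_slots`, `$vocabulary`.
#' @export
synth_corpus <- function(seed = 1, n_slots = 5, words_per_slot = 10,
                         utterances_per_word = 8, sample_rate = 16000,
                         word_duration_s = 0.4) {
  if (n_slots < 1 || words_per_slot < 2 || utterances_per_word < 2) {
    abort("need n_slots >= 1, words_per_slot >= 2, utterances_per_word >= 2")
  }
  if (sample_rate < 8000) abort("sample_rate must be >= 8 kHz")
  set.seed(seed)
  vocab <- lapply(seq_len(n_slots), function(s) {
    sprintf("s%d_w%02d", s, seq_len(words_per_slot))
  })
  # word-specific acoustics: fundamental + 3 formant-like peaks with glides
  word_specs <- list()
  for (s in seq_len(n_slots)) {
    for (j in seq_len(words_per_slot)) {
      word_specs[[vocab[[s]][j]]] <- list(
        slot = s,
        f0 = runif(1, 100, 220),
        formants_start = sort(runif(3, 300, 4500)),
        formants_end = sort(runif(3, 300, 4500)),
        bw_oct = runif(1, 0.25, 0.4)
      )
    }
  }
  grid <- expand.grid(
    word_idx = seq_along(word_specs),
    utterance = seq_len(utterances_per_word)
  )
  utt_seeds <- sample.int(2^31 - 2, nrow(grid))
  rows <- purrr::pmap(
    list(grid$word_idx, grid$utterance, utt_seeds),
    function(wi, u, us) {
      sp <- word_specs[[wi]]
      sig <- synth_word(sp, sample_rate, word_duration_s, us)
      tibble(
        slot = sp$slot, word = names(word_specs)[wi],
        utterance = u, signal = list(sig)
      )
    }
  )
  structure(
    list(
      utterances = dplyr::bind_rows(rows),
      sample_rate = sample_rate,
      n_slots = n_slots,
      vocabulary = vocab,
      word_duration_s = word_duration_s
    ),
    class = "ci_corpus"
  )
}

# one harmonic-complex token; per-utterance perturbations of pitch, duration
# and envelope keep same-word utterances similar but not identical
synth_word <- function(spec, fs, dur, utt_seed) {
  set.seed(utt_seed)
  f0 <- spec$f0 * (1 + rnorm(1, 0, 0.02))
  dur <- dur * (1 + runif(1, -0.08, 0.08))
  fst <- spec$formants_start * (1 + rnorm(3, 0, 0.03))
  fen <- spec$formants_end * (1 + rnorm(3, 0, 0.03))
  n <- round(dur * fs)
  t <- seq_len(n) / fs
  harm <- seq_len(floor(min(6000, fs / 2 - 500) / f0))
  phases <- runif(length(harm), 0, 2 * pi)
  frac <- (seq_len(n) - 1) / (n - 1)
  log_hf <- log2(harm * f0)
  # envelope per harmonic per time: sum of Gaussian bumps in log-frequency
  env <- matrix(0, n, length(harm))
  for (k in 1:3) {
    fk <- fst[k] + (fen[k] - fst[k]) * frac # n
    env <- env + exp(-0.5 * (outer(log2(fk), log_hf, "-") / spec$bw_oct)^2)
  }
  carr <- sin(outer(t, 2 * pi * harm * f0) +
              matrix(phases, n, length(harm), byrow = TRUE))
  sig <- rowSums(env * carr)
  # onset/offset ramps and fixed RMS
  ramp <- round(0.01 * fs)
  w <- rep(1, n)
  w[seq_len(ramp)] <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
  w[n + 1 - seq_len(ramp)] <- w[seq_len(ramp)]
  sig <- sig * w
  sig / rms(sig) * 0.1
}

#' @export
print.ci_corpus <- function(x, ...) {
  cat(sprintf(
    "<ci_corpus> %d slots x %d words x %d utterances @ %d Hz\n",
    x$n_slots, length(x$vocabulary[[1]]),
    max(x$utterances$utterance), x$sample_rate
  ))
  invisible(x)
}

corpus_rms <- function(corpus) {
  rms(unlist(corpus$utterances$signal))
}

#' Draw sentences from a corpus
#'
#' Samples `n` sentences (one word per slot, a random utterance of each) and
#' assembles their waveforms with leading/trailing silence and short
#' inter-word gaps, so that recognizer silence models have material to absorb.
#' Word choice is balanced per slot as in matrix-test lists: within each block
#' of `words_per_slot` sentences every word of the slot occurs exactly once,
#' in shuffled order, so any list at least as long as the vocabulary covers
#' every word.
#'
#' @param corpus A [synth_corpus()] result.
#' @param n Number of sentences.
#' @param seed Integer seed.
#' @param lead_s,gap_s Leading/trailing silence and inter-word gap (seconds).
#' @param utterances Optional subset of utterance indices to draw from (used
#'   for train/test splits).
#' @return Tibble with `sentence`, `words` (list of labels), `signal` (list).
#' @export
corpus_sentences <- function(corpus, n, seed = 1, lead_s = 0.1, gap_s = 0.05,
                             utterances = NULL) {
  set.seed(seed)
  fs <- corpus$sample_rate
  utt <- corpus$utterances
  if (!is.null(utterances)) utt <- dplyr::filter(utt, .data$utterance %in% utterances)
  lead <- numeric(round(lead_s * fs))
  gap <- numeric(round(gap_s * fs))
  # balanced word schedule per slot (shuffled blocks of the full vocabulary)
  schedule <- lapply(seq_len(corpus$n_slots), function(s) {
    v <- corpus$vocabulary[[s]]
    unlist(lapply(seq_len(ceiling(n / length(v))), function(b) {
      v[sample.int(length(v))]
    }))[seq_len(n)]
  })
  purrr::map_dfr(seq_len(n), function(i) {
    parts <- list(lead)
    words <- character(corpus$n_slots)
    for (s in seq_len(corpus$n_slots)) {
      words[s] <- schedule[[s]][i]
      cand <- which(utt$slot == s & utt$word == words[s])
      if (!length(cand)) abort(paste0("no utterances for word ", words[s]))
      pick <- cand[sample.int(length(cand), 1)]
      parts <- c(parts, utt$signal[pick], list(gap))
    }
    parts[[length(parts)]] <- lead
    tibble(sentence = i, words = list(words),
           signal = list(unlist(parts)))
  })
}

#' Synthesize stationary speech-shaped noise
#'
#' Gaussian noise spectrally shaped to the long-term average spectrum of the
#' corpus (random-phase spectral synthesis), RMS-normalized to the corpus RMS.
#'
#' @param corpus A [synth_corpus()] result.
#' @param duration_s Noise duration in seconds (> 0).
#' @param seed Integer seed.
#' @return Numeric waveform at the corpus sample rate.
#' @export
synth_noise <- function(corpus, duration_s = 60, seed = 1) {
  if (duration_s <= 0) abort("duration_s must be > 0")
  if (nrow(corpus$utterances) == 0) abort("corpus is empty")
  fs <- corpus$sample_rate
  target <- ltas(unlist(corpus$utterances$signal), fs, nfft = 512)
  n <- round(duration_s * fs)
  set.seed(seed)
  # random-phase synthesis: white Gaussian spectrum shaped by the target
  # magnitude (interpolated onto the n-point frequency grid)
  half <- floor(n / 2)
  freqs <- (0:half) * fs / n
  mag <- approx(target$freq, sqrt(target$power), xout = freqs, rule = 2)$y
  re <- rnorm(half + 1) * mag
  im <- rnorm(half + 1) * mag
  im[1] <- 0
  if (n %% 2 == 0) im[half + 1] <- 0
  spec <- complex(real = re, imaginary = im)
  full <- c(spec, Conj(rev(spec[2:(half + (n %% 2 == 0))])))
  x <- Re(fft(full, inverse = TRUE)) / n
  x / rms(x) * corpus_rms(corpus)
}

# Welch-style long-term average spectrum (hann, 50% overlap)
ltas <- function(x, fs, nfft = 512) {
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nfft) / (nfft + 1)))
  hop <- nfft / 2
  starts <- seq(1, max(1, length(x) - nfft + 1), by = hop)
  p <- numeric(nfft / 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * w
    X <- fft(seg)[1:(nfft / 2 + 1)]
    p <- p + Mod(X)^2
  }
  tibble(freq = (0:(nfft / 2)) * fs / nfft, power = p / length(starts))
}

#' Write / read a corpus as WAV files plus a manifest
#'
#' Each utterance is written as a 16-bit PCM mono WAV file and listed in a
#' `manifest.csv` (path, slot, word, utterance). A minimal WAV codec is built
#' in; no external audio package is required.
#'
#' @param corpus A `ci_corpus`.
#' @param dir Output directory (created if missing).
#' @return The directory (writer) / a `ci_corpus` (reader), invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- corpus$utterances
  man$path <- sprintf("%s_u%02d.wav", man$word, man$utterance)
  purrr::pwalk(list(man$path, man$signal), function(p, s) {
    write_wav(s, file.path(dir, p), corpus$sample_rate)
  })
  utils::write.csv(man[, c("path", "slot", "word", "utterance")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  sigs <- lapply(man$path, function(p) read_wav(file.path(dir, p)))
  fs <- unique(vapply(sigs, attr, numeric(1), "sample_rate"))
  if (length(fs) != 1) abort("mixed sample rates in corpus directory")
  vocab <- lapply(sort(unique(man$slot)), function(s) {
    sort(unique(man$word[man$slot == s]))
  })
  structure(
    list(
      utterances = tibble(
        slot = man$slot, word = man$word, utterance = man$utterance,
        signal = lapply(sigs, as.numeric)
      ),
      sample_rate = fs, n_slots = length(vocab), vocabulary = vocab,
      word_duration_s = NA_real_
    ),
    class = "ci_corpus"
  )
}

#' Minimal mono 16-bit PCM WAV I/O
#'
#' @param x Numeric waveform in `[-1, 1]`.
#' @param path File path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path` invisibly (writer); waveform with attribute `sample_rate`
#'   (reader).
#' @export
write_wav <- function(x, path, sample_rate) {
  pcm <- as.integer(pmax(pmin(round(x * 32767), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  n_data <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_data, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_data, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (hdr != "RIFF") abort("not a RIFF/WAV file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") abort("not a WAV file")
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) abort("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1) abort("only mono PCM supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), n = 2, size = 2, endian = "little"))
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2, signed = TRUE,
                     endian = "little")
      return(structure(pcm / 32768, sample_rate = fs))
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
}
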