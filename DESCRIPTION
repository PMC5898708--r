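Package: cisrt
Title: Physiologically Inspired Modelling of Speech Reception Thresholds in
    Cochlear Implant Users
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the signal path of a cochlear implant (CI) listener from
    audio to a predicted speech reception threshold (SRT): an n-of-m ACE-style
    speech coding strategy, per-electrode electrical field spatial spread along a
    one-dimensional cochlea, a stochastic leaky integrate-and-fire auditory nerve
    population, a spectrogram-like internal representation with forward masking
    and multiplicative internal noise, and a whole-word hidden-Markov-model
    recognizer that yields SRTs from the 50% iso-score line over a training-SNR
    by testing-SNR matrix. Includes individualization machinery: exponential
    fits with offsets to electrical field imaging (EFI) maps and their
    full-width-half-maximum, a phenomenological auditory-performance score from
    anamnesis data, linear mapping of performance metrics onto internal-noise
    standard deviations, and an ordinary-least-squares SRT predictor. Ships
    synthetic generators (matrix-sentence corpus, speech-shaped noise, EFI maps,
    participant cohorts) so the full pipeline can be exercised without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
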