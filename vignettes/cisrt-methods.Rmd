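---
title: "Modelling speech reception thresholds of cochlear-implant listeners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling speech reception thresholds of cochlear-implant listeners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cisrt` simulates the complete signal path of a cochlear-implant (CI)
listener in a speech-in-noise test, from audio waveforms to a predicted
speech reception threshold (SRT), and provides the statistical machinery to
individualize that model to single listeners. This vignette explains the
model, its assumptions, the parameters that matter, and the design choices
made where the underlying literature leaves the design open.

## The model

### Front end: from audio to an internal representation

1. **Mixing.** A sentence is mixed with a random temporal passage of
   stationary speech-shaped noise at a target SNR (`mix_at_snr()`). The
   speech is never rescaled; only the noise gain changes.

2. **ACE-style coding (`ace_encode()`).** An n-of-m strategy: a 128-sample
   FFT analysis (hann window) at 16 kHz splits the spectrum into 22
   contiguous bands spanning 188-7938 Hz (one FFT bin per channel below
   ~1.2 kHz, logarithmic spacing above). Per frame, the `n_maxima = 8`
   largest channel envelopes above the base level are selected, compressed
   by a logarithmic loudness-growth function (`rho = 416.2`) between base
   level 0.0156 and saturation level 0.5859, and mapped linearly onto the
   electrical dynamic range 100-500 uA. Pulses are interleaved within each
   frame (no simultaneous stimulation), at about 900 pulses/s per channel.
   Channel 1 (lowest band) drives electrode 1, the most apical. The device
   literature does not pin down one exact parameterization; these defaults
   are declared, typical clinical values, and every one is configurable.
   Threshold and comfort currents are global, not per-electrode.

3. **Spatial spread (`idealized_profiles()`, `fit_efi_profiles()`).** The
   cochlea is a straight 35 mm axis; the 22-electrode array (0.75 mm pitch)
   sits centrally (electrode 1 at 9.625 mm). A per-electrode weight function
   transfers pulse current onto 1000 equally spaced nerve fibers. Two
   sources of weight functions exist: an idealized homogeneous double-sided
   exponential with width `lambda` (the distance to 1/e of the peak), and
   profiles fitted to electrical field imaging (EFI) maps (below). Profiles
   are peak-normalized before use so both pathways are commensurable; the
   drive a fiber receives is pulse current times weight, summed over
   temporally overlapping pulses.

4. **Auditory nerve (`simulate_population()`).** Each fiber is a leaky
   integrate-and-fire unit: membrane time constant 0.5 ms, spiking threshold
   with a stochastic perturbation of relative spread 0.06 (giving the
   sigmoidal single-pulse firing-efficiency curve with CV approximately
   equal to the relative spread), per-fiber absolute refractory periods
   drawn from a truncated normal (0.7 +/- 0.1 ms), an exponentially decaying
   relative-refractory threshold elevation (tau 1.3 ms), conduction latency
   0.45 ms with 0.1 ms Gaussian jitter, and membrane noise. The upstream
   literature defers the parameter values to an inaccessible dissertation;
   the defaults here are typical for electrically stimulated fibers, and no
   downstream result depends on their exact values - the output scale is
   calibrated at the internal representation. The default threshold (12
   uA-equivalent at the fiber) is chosen so that the electrical dynamic
   range spans sub- to supra-threshold single-pulse drive at the profile
   peak, which preserves place selectivity. Biphasic pulses are rectified to
   their cathodic-phase drive. Membrane noise is injected as 50 us events
   with variance-preserving scaling (the 0.5 ms membrane integrates ~10
   events, so voltage statistics match per-step injection). Emitted spike
   times respect each fiber's absolute refractory period by construction.

5. **Internal representation (`build_grouping()`, `integrate_spikes()`).**
   Fibers are partitioned into 46 contiguous place groups: one per electrode
   (bounded by arithmetic midpoints between neighbours) and 0.75 mm groups
   beyond the array, with the residual 0.25 mm at each cochlear end merged
   into the terminal groups (merging rather than dropping keeps the
   partition exact; either choice yields 46 rows). Spike counts per 2 ms
   frame (500 Hz frame rate) are smoothed by a leaky integrator (tau 10 ms),
   then a forward-masking trace - accumulating with past smoothed output,
   decaying with tau 100 ms, scaled by strength 0.5 - is subtracted and the
   result floored at zero. The masking mechanism is named but not specified
   in the source literature; this subtractive decaying-trace construction
   and both time constants are this package's design, the order is fixed as
   smooth-then-mask, and tests rely only on the suppression contract (a
   second burst responds less than the first). The gain is calibrated once
   per configuration so that the 99th percentile of IR amplitudes on clean
   calibration material equals 50, anchoring the conventional 0-50 range.

6. **Internal noise (`apply_internal_noise()`).** Every place-time bin is
   multiplied independently by Gaussian noise with mean 1 and standard
   deviation `sigma_int` (typically 0.025-0.3). No clipping is applied;
   negative bins pass to the recognizer as-is. This is a deliberately coarse
   stand-in for individual cognitive limitations, not a mechanistic model.

### Back end: recognition and SRT extraction

Whole-word left-to-right HMMs with 6 states and one diagonal Gaussian per
state, plus 3-state silence models, are trained embedded at sentence level
(`train_word_models()`): flat start from a uniform segmentation, then
segmental Viterbi re-estimation under the known transcription. No word
boundaries are ever supplied; decoding (`recognize_sentences()`) runs over
the closed grammar silence - slot words - silence, with ties resolved to the
earlier-indexed word. Features are the raw 46-dimensional IR frames; no
delta features or normalization are applied by default (left configurable).

One backend numerical choice deserves emphasis: the state-variance floor
defaults to 0.3 times the global per-dimension variance. With one Gaussian
per state trained on as few as two repetitions, maximum-likelihood variances
are severely underestimated; the resulting overconfident models respond to
variance-estimation noise rather than to the input degradations under study.
Concretely, multiplicative internal noise then *helps* matched-trained
recognition - it inflates the trained variances, acting as a regularizer -
which inverts the expected ordering of predicted SRTs in internal noise. A
strong floor neutralizes this channel: all configurations are compared with
comparably regularized models, and the degradation that internal noise
inflicts on test tokens shows through. Weak floors (1-10% of global
variance) were found insufficient to remove the pathology at the reduced
protocol scale.

The SNR protocol (`run_snr_matrix()`) trains models at each SNR of a grid on
all-but-one repetitions and decodes the held-out repetition at every testing
SNR, yielding a word-correct matrix over the train x test plane. The SRT
(`estimate_srt()`) is read from the envelope (maximum over training SNRs) of
each testing-SNR column: linear interpolation at the 50% criterion between
the lowest adjacent bracketing pair. If the envelope never reaches 50% the
SRT is undefined and flagged (this happens for severely degraded
configurations and mirrors listeners for whom no SRT can be measured); an
envelope already at criterion at the grid floor is flagged `at_grid_floor`.

### EFI individualization

An EFI map is the voltage on every electrode while stimulating each one,
normalized by the stimulation current (impedance units; stored as kOhm, with
Ohm-to-kOhm conversion at I/O - the absolute unit only affects reporting,
never the peak-normalized model weights). Diagonal entries are dominated by
electrode-tissue impedance and are excluded. Per stimulating electrode,
`v(x) = A exp(-|x - x_e| / lambda) + c` is fitted separately to the apical
and basal off-diagonal recordings, with separate vertical offsets per side.
The returned profile is the fitted curve beyond +/- 0.75 mm of the
electrode, a linear interpolation across that region (avoiding unphysically
peaky profiles), and the fitted exponential extrapolated beyond the array
with its offset clamped at zero or above.

Numerical choices: because EFI noise is predominantly multiplicative
(constant CV), the fits minimize log-domain residuals when all recordings
are positive; several starts (log-linear with free offset, zero-offset
log-linear, difference-ratio) plus a profiled 1-D fit over `lambda` (with
the linear parameters solved exactly) are scored on the same criterion and
the best is kept. Sides with fewer than three recordings (edge electrodes)
mirror the opposite side and are flagged; near-constant sides collapse to a
flat offset-only profile flagged degenerate.

The full width at half maximum (`profile_fwhm()`) is the width of the region
where the composed profile is at least half its absolute maximum - the
reference level is zero impedance, not the offset, following the published
definition; the maximum is the composed (tent-interpolated) peak. A side
that never falls below half-maximum inside the cochlea is clipped at the
domain boundary and flagged.

### Individualization statistics

- `auditory_performance()` evaluates the phenomenological anamnesis score
  `AP = dur_mHL * (-0.23 %/y) + dur_sHL * delta_s + B1 + B2` with `delta_s`
  of -0.83, -0.64, -0.45 %/y for no, one, and two hearing aids. `B1`/`B2`
  (age-at-implantation and etiology adjustments) are accepted as numeric
  inputs; their source lookup figures are not re-derived.
- `map_sigma()` maps a cohort metric linearly onto sigma in [0.15, 0.25],
  poorest performer highest; endpoints are exact, and the mapping commutes
  with averaging (an affine identity used in the tests).
- `combine_sigmas()` implements the equal-weight combination as the
  arithmetic mean of the two unrounded sigma values - validated against the
  bundled cohort table, which this choice reproduces cell by cell.
- Rounding for table display is half-away-from-zero at 3 decimals
  (`0.2105... -> 0.211`), since banker's rounding cannot reproduce printed
  tables. Three printed cells of the bundled cohort differ from recomputation
  by exactly 0.001 (printed-rounding artifacts of unrounded source inputs);
  tests assert those at +/- 0.001 and all anchors exactly. Whether the
  source mapped sigma from rounded or unrounded AP values is unknowable from
  its text; this package maps from the printed values.
- `fit_srt_glm()` is ordinary least squares of measured SRT on mean FWHM,
  AP and TRT with intercept; `glm_predict()` evaluates it (or the published
  coefficient set `reference_glm_coefficients()`).

## Synthetic data: what it emulates and what it does not

The generators make the package self-contained:

- `synth_corpus()` builds a closed matrix-style corpus (default 5 slots x 10
  words x 8 utterances, 16 kHz, 0.4 s per word). Words are harmonic
  complexes with word-specific fundamentals and formant-like
  spectral-envelope trajectories; utterances perturb pitch (2%), duration
  (8%) and envelope (3%) so same-word utterances cluster. This captures the
  closed-vocabulary structure and multi-utterance variability the recognizer
  needs, but none of the phonetics of real speech: synthetic words are more
  spectrally stationary and more separable than real matrix-test words, so
  absolute scores and SRTs are not comparable to human data - only contrasts
  (between spreads, noise levels, configurations) are meaningful.
- `synth_noise()` shapes Gaussian noise to the corpus long-term spectrum
  (random-phase synthesis) at corpus RMS. The spectral-matching tolerance
  used in tests (2 dB mean absolute deviation, 100 Hz-6 kHz) is this
  package's choice; the source literature gives no acoustic detail beyond
  "stationary, speech-shaped".
- `synth_efi()` generates maps with exponential decay plus offset,
  multiplicative lognormal noise, linearly interpolated per-electrode decay
  lengths (wider apically, matching the published trend), and inflated
  diagonals to exercise the fitter's exclusion rule.
- `synth_participants()` draws TRT from a truncated normal N(49, 9^2) on
  [20, 80], anamnesis fields spanning AP of roughly -30 to +6 %, and
  measured SRTs as a fixed linear function of TRT (-0.1 dB per TRT %, noise
  sd 1.5 dB), making the TRT-SRT correlation negative by construction.

## Protocol presets and problem sizes

Two presets (`ci_config()`):

- `"paper"`: 5-slot corpus, 120 sentences, 8 repetitions (7 train / 1
  test), SNRs -12 to 21 dB in 3 dB steps, 1000 fibers, 10 us nerve time
  step. This mirrors the full published protocol and is the configuration a
  study-scale run would use.
- `"desk"`: 1-slot corpus of 10 words, 30 sentences, 3 repetitions (2
  train / 1 test), SNRs -12 to 3 dB, 100 fibers, 20 us time step. These
  sizes were chosen so that one full SRT estimate completes in about two
  minutes on a single core, making systematic sweeps and the test suite
  practical; the vignette's and tests' trend statements (SRT worsens with
  wider spread and stronger internal noise) are asserted at this scale.
  Absolute desk-scale SRTs are not comparable to full-scale values; at
  reduced scale only orderings are meaningful, and published full-scale
  figures (e.g. a 0.4 dB test-retest spread) are reported by the same
  mechanism but not numerically reproduced.

Sentence lists are balanced per slot (each word once per block of ten, as in
matrix-test lists), which also guarantees vocabulary coverage for embedded
training on short lists.

## Determinism and provenance

Every stochastic stage takes a seed; child seeds for mixing offsets, nerve
simulation and internal noise are derived deterministically from the master
seed and the stage's indices, so any run is bit-reproducible. The C++ nerve
kernel uses a self-contained xorshift128+ stream per fiber, independent of
R's RNG state. Sweeps and individualized runs attach a provenance record
(configuration hash, seeds, package version).

## Known limitations

- One-dimensional cochlea, equal electrode-nerve distance, homogeneous
  fiber survival: no 3-D volume conduction, no CT-based geometry, no dead
  regions. EFI-based spread is therefore an upper bound on what spread
  individualization could explain.
- Global threshold/comfort currents; no per-electrode levels or loudness
  growth individualization.
- The internal noise models cognition only as a multiplicative distortion of
  the recognizer input; back-end (HMM) degradation is out of scope.
- Synthetic speech: absolute intelligibility scores do not transfer to
  human data (see above).
- `estimate_srt()` interpolates only the lowest crossing pair of the
  envelope; non-monotonic envelopes above the crossing are ignored by
  design.
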