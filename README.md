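# cisrt

Physiologically inspired modelling of speech reception thresholds (SRTs) in
cochlear-implant (CI) users.

CI listeners vary enormously in how well they understand speech in noise,
and the physiological and cognitive factors behind that variance are poorly
understood. `cisrt` implements a complete computer model of a CI listener in
a matrix-sentence test for researchers who want to study two such factors in
isolation and in combination:

- **electrical field spatial spread** — how far each electrode's field
  reaches along the cochlea, either as an idealized double-sided exponential
  `w_e(x) = exp(-|x - x_e| / λ)` or fitted per electrode to electrical field
  imaging (EFI) maps, summarized by the full width at half maximum (FWHM);
- **internal noise** — multiplicative Gaussian noise (mean 1, standard
  deviation σ_int) on the model's internal representation, a coarse stand-in
  for individual cognitive limitations.

The signal path: audio → ACE-style n-of-m coding (22 electrodes, 8 maxima)
→ spatial spread onto 1000 leaky integrate-and-fire auditory-nerve fibers →
spectrogram-like internal representation (46 place rows at 500 Hz) with
forward masking and internal noise → whole-word hidden-Markov-model
recognizer under a closed grammar. Training/testing over an SNR grid yields
a word-correct matrix whose 50% iso-score envelope defines the predicted
SRT:

    SRT = the SNR at which 50% of words are recognized,
          interpolated on the envelope max over training SNRs.

Individualization machinery is included: the anamnesis-based auditory
performance score `AP = Dur(mHL)·(−0.23 %/y) + Dur(sHL)·Δs + B1 + B2`, the
linear mapping of cohort performance metrics onto σ_int ∈ [0.15, 0.25], the
equal-weight combination of metrics, and the linear SRT predictor
`SRT_pred(dB) = 11.62 − 0.0183·FWHM(mm) + 0.0644·AP − 0.1403·TRT(%)`.
A 14-participant reference cohort (TRT, AP, σ_int, measured SRT) ships with
the package, as do synthetic generators for corpora, speech-shaped noise,
EFI maps and participant tables, so everything runs without proprietary
data.

## Worked example

Internal-noise individualization for the bundled reference cohort — compute
the three σ_int columns from the printed TRT and AP values and check the
TRT–SRT association:

```r
library(cisrt)

cohort <- reference_cohort()
sigma_table(cohort)[1:3, c("id", "trt", "ap",
                           "sigma_trt", "sigma_both", "sigma_ap")]
#> # A tibble: 3 × 6
#>   id      trt    ap sigma_trt sigma_both sigma_ap
#>   <chr> <dbl> <dbl>     <dbl>      <dbl>    <dbl>
#> 1 08     44.9 -17.6     0.205      0.211    0.216
#> 2 12     62.7 -15.8     0.15       0.18     0.211
#> 3 30     41.6   5.4     0.215      0.183    0.15

pearson(cohort$trt, cohort$srt)
#> # A tibble: 1 × 3
#>        r       p     n
#>    <dbl>   <dbl> <int>
#> 1 -0.720 0.00366    14
```

Participant 08 (TRT 44.9 %, AP −17.6 %) receives σ_int = 0.205 from the
TRT-only mapping, 0.216 from the AP-only mapping, and 0.211 from their
equal-weight combination; the cohort's text-reception threshold correlates
at r = −0.72 (p < 0.01) with the measured SRT — listeners who are better at
reconstructing masked written sentences also understand speech in noise at
lower SNRs.

A complete model run at desk scale — predict one SRT for a synthetic corpus
with spread λ = 9 mm and σ_int = 0.19:

```r
cfg   <- ci_config("desk", lambda_mm = 9, sigma_int = 0.19)
corp  <- do.call(synth_corpus, c(list(seed = 11), cfg$corpus_spec))
noise <- synth_noise(corp, duration_s = 30, seed = 12)
res   <- run_srt(corp, noise, cfg, seed = 1)
res$srt
#> # A tibble: 1 × 3
#>     srt criterion flag 
#>   <dbl>     <dbl> <chr>
#> 1 -5.25        50 ok
```

The desk-scale SRT of −5.25 dB SNR is the SNR at which the recognizer gets
half the words right; it is meaningful only relative to other
configurations (the synthetic one-slot corpus is easier than real
sentences). `run_sweep()` maps SRT against λ and σ_int, `fit_efi_profiles()`
+ `fwhm_table()` extract spread widths from EFI maps, and
`run_individualized()` predicts per-participant SRTs with σ_int and/or
spread individualized, reporting Pearson r, RMS error and bias against
measured SRTs.

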