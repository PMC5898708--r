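#' Reference cohort of 14 cochlear-implant users
#'
#' A published reference cohort of 14 CI users of Cochlear devices, bundled as
#' a tibble. Columns: `id` (participant label), `trt` (text reception
#' threshold, % tolerated sentence coverage; higher is better), `ap`
#' (phenomenological auditory-performance score in %, see
#' [auditory_performance()]), the three printed internal-noise standard
#' deviations derived from these metrics (`sigma_trt`, `sigma_both`,
#' `sigma_ap`), and `srt` (measured speech reception threshold in dB SNR;
#' lower is better).
#'
#' The sigma columns are the printed three-decimal values; recompute them from
#' `trt` and `ap` with [sigma_table()]. Per-participant mean spatial-spread
#' FWHM values were published only as supplementary material; use
#' [synthetic_fwhm()] for a clearly labelled stand-in.
#'
#' @return A tibble with 14 rows.
#' @export
#' @examples
#' reference_cohort()
reference_cohort <- function() {
  tibble::tribble(
    ~id,  ~trt,  ~ap,    ~sigma_trt, ~sigma_both, ~sigma_ap, ~srt,
    "08", 44.9,  -17.6,  0.205,      0.211,       0.216,     2.7,
    "12", 62.7,  -15.8,  0.150,      0.180,       0.211,     2.0,
    "30", 41.6,  5.4,    0.215,      0.183,       0.150,     6.2,
    "31", 60.7,  -5.8,   0.156,      0.169,       0.182,     0.8,
    "32", 30.4,  0.7,    0.250,      0.207,       0.164,     6.2,
    "41", 38.4,  -17.0,  0.225,      0.220,       0.214,     4.5,
    "44", 50.3,  -2.6,   0.188,      0.181,       0.173,     4.0,
    "46", 49.8,  2.6,    0.190,      0.174,       0.158,     2.9,
    "48", 54.5,  -0.7,   0.175,      0.171,       0.168,     -0.1,
    "50", 49.5,  -14.8,  0.191,      0.199,       0.208,     1.6,
    "60", 55.1,  -29.5,  0.174,      0.212,       0.250,     -0.1,
    "61", 52.7,  2.2,    0.181,      0.170,       0.159,     1.7,
    "62", 56.1,  -5.0,   0.170,      0.175,       0.180,     4.4,
    "63", 38.9,  -17.0,  0.223,      0.219,       0.214,     3.9
  )
}

#' Synthetic per-participant mean FWHM values
#'
#' The reference cohort's per-participant electrode-averaged spatial-spread
#' FWHMs are not part of the bundled table (they were published only as
#' supplementary material); only the cohort extremes (5.1 mm and 9.8 mm) are
#' known. This generator draws a synthetic stand-in column uniformly over that
#' published range. It is labelled synthetic on purpose: any analysis using it
#' probes the machinery, not the real electrode data.
#'
#' @param n Number of values.
#' @param seed Integer seed.
#' @param range_mm Known cohort range of mean FWHM in mm.
#' @return Numeric vector of length `n` (mm).
#' @export
synthetic_fwhm <- function(n = 14, seed = 1, range_mm = c(5.1, 9.8)) {
  set.seed(seed)
  runif(n, range_mm[1], range_mm[2])
}

#' Auditory-performance (AP) score from anamnesis data
#'
#' Phenomenological percentage score summarizing the pre-implantation history
#' of a CI user: durations of moderate and severe/profound hearing loss,
#' hearing-aid use during the severe phase, and two supplied adjustment terms
#' for age at implantation (`b1`) and etiology (`b2`).
#'
#' `AP = dur_mhl * (-0.23 %/y) + dur_shl * delta_s + b1 + b2`, where `delta_s`
#' is -0.83 %/y for no hearing aid, -0.64 %/y for one side, and -0.45 %/y for
#' both sides. More negative AP means a more deprived auditory system.
#'
#' @param dur_mhl Duration of moderate hearing loss in years.
#' @param dur_shl Duration of severe/profound hearing loss in years.
#' @param hearing_aid_use One of `"none"`, `"one_side"`, `"both_sides"`
#'   (vectorized, recycled against the durations).
#' @param b1,b2 Adjustment terms in % (supplied, not derived here).
#' @return AP in % (numeric vector).
#' @export
#' @examples
#' auditory_performance(10, 5, "both_sides", 0, 0) # -4.55
auditory_performance <- function(dur_mhl, dur_shl, hearing_aid_use, b1, b2) {
  stopifnot(all(dur_mhl >= 0), all(dur_shl >= 0))
  delta <- c(none = -0.83, one_side = -0.64, both_sides = -0.45)
  if (!all(hearing_aid_use %in% names(delta))) {
    abort(paste0(
      "`hearing_aid_use` must be one of: ", paste(names(delta), collapse = ", ")
    ))
  }
  dur_mhl * (-0.23) + dur_shl * delta[hearing_aid_use] + b1 + b2
}

#' Map a performance metric linearly onto internal-noise standard deviations
#'
#' Linearly rescales cohort metric values onto a sigma range such that the
#' poorest performer receives the largest internal-noise standard deviation
#' and the best performer the smallest. Endpoints map exactly.
#'
#' @param metric Numeric vector of cohort metric values (e.g. TRT or AP).
#' @param sigma_range Target sigma interval, default `c(0.15, 0.25)`.
#' @param higher_is_better Logical; if `TRUE` (default) the maximum metric maps
#'   to `min(sigma_range)`.
#' @return Numeric vector of sigma values, one per cohort member.
#' @export
#' @examples
#' map_sigma(reference_cohort()$trt)[1] # participant 08 -> 0.2051...
map_sigma <- function(metric, sigma_range = c(0.15, 0.25),
                      higher_is_better = TRUE) {
  stopifnot(length(metric) >= 2, all(is.finite(metric)))
  lo <- min(metric); hi <- max(metric)
  if (hi - lo <= 0) abort("metric range is degenerate; cannot map onto sigma")
  s_min <- min(sigma_range); s_max <- max(sigma_range)
  frac <- (metric - lo) / (hi - lo)
  if (higher_is_better) s_max - frac * (s_max - s_min)
  else s_min + frac * (s_max - s_min)
}

#' Combine two internal-noise standard deviations with equal weights
#'
#' Arithmetic mean of the two (unrounded) sigma values; used to let a
#' cognitive metric and an anamnesis-based metric contribute equally.
#'
#' @param sigma_a,sigma_b Numeric vectors of sigma values.
#' @return Numeric vector.
#' @export
combine_sigmas <- function(sigma_a, sigma_b) {
  stopifnot(all(is.finite(sigma_a)), all(is.finite(sigma_b)))
  (sigma_a + sigma_b) / 2
}

#' Internal-noise table for a cohort
#'
#' Computes the three sigma columns (TRT-only, equal-weight combination,
#' AP-only) for a cohort tibble with `trt` and `ap` columns, from unrounded
#' intermediates. `digits = NULL` returns unrounded values; otherwise values
#' are rounded half-away-from-zero as in printed tables.
#'
#' @param cohort Tibble with columns `trt` and `ap`.
#' @param sigma_range Target sigma interval.
#' @param digits Decimal places for rounding, or `NULL` for unrounded.
#' @return The cohort tibble with columns `sigma_trt`, `sigma_both`,
#'   `sigma_ap` replaced/added.
#' @export
sigma_table <- function(cohort, sigma_range = c(0.15, 0.25), digits = 3) {
  stopifnot(all(c("trt", "ap") %in% names(cohort)))
  s_trt <- map_sigma(cohort$trt, sigma_range)
  s_ap <- map_sigma(cohort$ap, sigma_range)
  s_both <- combine_sigmas(s_trt, s_ap)
  out <- dplyr::mutate(cohort,
    sigma_trt = s_trt, sigma_both = s_both, sigma_ap = s_ap
  )
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      dplyr::all_of(c("sigma_trt", "sigma_both", "sigma_ap")),
      ~ round_half_up(.x, digits)
    ))
  }
  out
}

#' Pearson correlation with significance test
#'
#' Thin tidy wrapper around [stats::cor.test()] (two-sided t test).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A one-row tibble with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Fit the linear SRT predictor
#'
#' Ordinary least squares of measured SRT on electrode-averaged spatial-spread
#' FWHM, auditory performance (AP) and text-reception threshold (TRT), with
#' intercept:
#' `SRT_pred(dB) = b0 + b_fwhm * FWHM(mm) + b_ap * AP(%) + b_trt * TRT(%)`.
#'
#' @param cohort Tibble with columns `fwhm`, `ap`, `trt` and the response
#'   column (default `srt`), one row per participant (>= 5 complete rows).
#' @param response Name of the response column.
#' @return An object of class `srt_glm` wrapping the `lm` fit; supports
#'   [tidy()], [glance()] and [glm_predict()].
#' @export
fit_srt_glm <- function(cohort, response = "srt") {
  need <- c("fwhm", "ap", "trt", response)
  stopifnot(all(need %in% names(cohort)))
  dat <- cohort[stats::complete.cases(cohort[need]), need]
  if (nrow(dat) < 5) abort("need at least 5 complete records to fit")
  names(dat)[names(dat) == response] <- ".srt"
  fit <- lm(.srt ~ fwhm + ap + trt, data = dat)
  if (any(is.na(coef(fit)))) abort("rank-deficient design; cannot fit")
  f <- summary(fit)$fstatistic
  structure(
    list(
      fit = fit,
      coefficients = setNames(
        coef(fit), c("intercept", "fwhm", "ap", "trt")
      ),
      f_statistic = unname(f[1]),
      f_p = unname(pf(f[1], f[2], f[3], lower.tail = FALSE)),
      r_fitted_measured = cor(fitted(fit), dat$.srt),
      n = nrow(dat)
    ),
    class = "srt_glm"
  )
}

#' @export
print.srt_glm <- function(x, ...) {
  cat("Linear SRT predictor (OLS on FWHM, AP, TRT)\n")
  print(round(x$coefficients, 4))
  cat(sprintf(
    "F = %.2f (p = %.3g), r(fitted, measured) = %.2f, n = %d\n",
    x$f_statistic, x$f_p, x$r_fitted_measured, x$n
  ))
  invisible(x)
}

#' @export
tidy.srt_glm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "fwhm", "ap", "trt"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' @export
glance.srt_glm <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    statistic = x$f_statistic,
    p.value = x$f_p,
    r.fitted.measured = x$r_fitted_measured,
    nobs = x$n
  )
}

#' Published coefficient set for the linear SRT predictor
#'
#' The reference coefficient values of the fitted linear SRT predictor:
#' intercept 11.62 dB, -0.0183 dB/mm (FWHM), +0.0644 dB/% (AP),
#' -0.1403 dB/% (TRT). Useful with [glm_predict()] to evaluate the published
#' model without refitting.
#'
#' @return Named numeric vector of class `srt_glm_coefs`.
#' @export
reference_glm_coefficients <- function() {
  structure(
    c(intercept = 11.62, fwhm = -0.0183, ap = 0.0644, trt = -0.1403),
    class = "srt_glm_coefs"
  )
}

#' Predict SRT from the linear model
#'
#' Evaluates the linear SRT predictor at given FWHM, AP and TRT values.
#'
#' @param model An `srt_glm` fit, an `srt_glm_coefs` coefficient set, or a
#'   named numeric vector with elements `intercept`, `fwhm`, `ap`, `trt`.
#' @param fwhm Electrode-averaged FWHM in mm.
#' @param ap Auditory performance in %.
#' @param trt Text-reception threshold in %.
#' @return Predicted SRT in dB SNR (vectorized).
#' @export
#' @examples
#' glm_predict(reference_glm_coefficients(), 5.1, 2.6, 49.8) # 4.71 dB
glm_predict <- function(model, fwhm, ap, trt) {
  co <- if (inherits(model, "srt_glm")) model$coefficients else unclass(model)
  stopifnot(all(c("intercept", "fwhm", "ap", "trt") %in% names(co)),
            all(is.finite(fwhm)), all(is.finite(ap)), all(is.finite(trt)))
  co[["intercept"]] + co[["fwhm"]] * fwhm + co[["ap"]] * ap + co[["trt"]] * trt
}

#' Evaluate predicted against measured SRTs
#'
#' Cohort-level goodness-of-prediction metrics: Pearson r and p, RMS error and
#' bias (mean of predicted minus measured; positive bias = predicted SRTs too
#' high = performance underestimated). Undefined predictions (`NA`) are
#' excluded and counted.
#'
#' @param predicted,measured Numeric vectors of SRTs in dB SNR.
#' @return One-row tibble: `r`, `p`, `rmse`, `bias`, `n`, `n_undefined`.
#' @export
srt_evaluation <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured))
  ok <- is.finite(predicted) & is.finite(measured)
  d <- predicted[ok] - measured[ok]
  ct <- if (sum(ok) >= 3 && sd(predicted[ok]) > 0 && sd(measured[ok]) > 0) {
    pearson(predicted[ok], measured[ok])
  } else {
    tibble(r = NA_real_, p = NA_real_, n = sum(ok))
  }
  tibble(
    r = ct$r, p = ct$p,
    rmse = sqrt(mean(d^2)), bias = mean(d),
    n = sum(ok), n_undefined = sum(!ok)
  )
}
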