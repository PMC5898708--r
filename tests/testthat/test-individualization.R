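test_that("auditory performance evaluates the anamnesis model exactly", {
  expect_equal(auditory_performance(0, 0, "none", 0, 0), 0, ignore_attr = TRUE)
  expect_equal(auditory_performance(10, 5, "both_sides", 0, 0), -4.55,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(auditory_performance(0, 10, "none", 0, 0), -8.3,
               tolerance = 1e-12, ignore_attr = TRUE)
  # b1/b2 shift the score additively
  expect_equal(auditory_performance(10, 5, "both_sides", 2, -1), -4.55 + 1,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(auditory_performance(1, 1, "sometimes", 0, 0), "hearing_aid_use")
})

test_that("sigma mapping endpoints and known cohort cells are exact", {
  co <- reference_cohort()
  s_trt <- map_sigma(co$trt)
  # endpoint exactness: best/poorest performers get 0.15 / 0.25 exactly
  expect_identical(s_trt[which.max(co$trt)], 0.15)
  expect_identical(s_trt[which.min(co$trt)], 0.25)
  # affine identity: mapping the cohort mean equals the mean of mapped sigmas
  lo <- min(co$trt); hi <- max(co$trt)
  map_of_mean <- 0.25 - (mean(co$trt) - lo) / (hi - lo) * 0.1
  expect_equal(mean(s_trt), map_of_mean, tolerance = 1e-12)
  expect_error(map_sigma(c(5, 5, 5)), "degenerate")
})

test_that("cohort sigma table reproduces the printed reference values", {
  st <- sigma_table(reference_cohort())
  co <- reference_cohort()
  # all printed cells at +/- 0.001 (a few printed cells carry a one-digit
  # rounding artifact from unrounded source inputs)
  expect_true(all(abs(st$sigma_trt - co$sigma_trt) <= 0.00101))
  expect_true(all(abs(st$sigma_both - co$sigma_both) <= 0.00101))
  expect_true(all(abs(st$sigma_ap - co$sigma_ap) <= 0.00101))
  # anchor participants reproduce exactly
  p08 <- which(co$id == "08"); p12 <- which(co$id == "12")
  p30 <- which(co$id == "30")
  expect_identical(st$sigma_trt[p08], 0.205)
  expect_identical(st$sigma_both[p08], 0.211)
  expect_identical(st$sigma_ap[p08], 0.216)
  expect_identical(st$sigma_trt[p12], 0.150)
  expect_identical(st$sigma_ap[p30], 0.150)
  # equal-weight combination is the mean of unrounded sigmas
  un <- sigma_table(reference_cohort(), digits = NULL)
  expect_equal(un$sigma_both, (un$sigma_trt + un$sigma_ap) / 2)
  expect_identical(combine_sigmas(0.2, 0.2), 0.2)
})

test_that("cohort averages of the sigma mappings match printed values", {
  un <- sigma_table(reference_cohort(), digits = NULL)
  r3 <- function(x) sign(x) * floor(abs(x) * 1000 + 0.5) / 1000
  expect_identical(r3(mean(un$sigma_trt)), 0.193)
  expect_identical(r3(mean(un$sigma_both)), 0.191)
  # AP-only average computes to 0.189 against a printed 0.190
  expect_lt(abs(mean(un$sigma_ap) - 0.190), 0.0011)
})

test_that("pearson reproduces the cohort TRT-SRT correlation and basics", {
  co <- reference_cohort()
  ct <- pearson(co$trt, co$srt)
  expect_equal(round(ct$r, 2), -0.72)
  expect_lt(ct$p, 0.01)
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson(x, rep(1, 10)), "variance")
})

test_that("cohort summary statistics match the printed table", {
  co <- reference_cohort()
  expect_equal(round(mean(co$srt), 1), 2.9)
  expect_equal(round(mean(co$ap), 1), -8.2)
  expect_equal(round(mean(co$trt), 1), 49.0)
})

test_that("OLS recovers exact coefficients from noiseless responses", {
  co <- reference_cohort()
  co$fwhm <- synthetic_fwhm(14, seed = 3)
  truth <- reference_glm_coefficients()
  co$srt <- glm_predict(truth, co$fwhm, co$ap, co$trt)
  # summary.lm warns about the (intended) numerically perfect fit
  fit <- suppressWarnings(fit_srt_glm(co))
  expect_equal(unname(fit$coefficients), unname(unclass(truth)),
               tolerance = 1e-9)
  expect_equal(fit$r_fitted_measured, 1, tolerance = 1e-9)
  td <- suppressWarnings(tidy(fit))
  expect_identical(td$term, c("intercept", "fwhm", "ap", "trt"))
  expect_equal(suppressWarnings(glance(fit))$r.squared, 1, tolerance = 1e-9)
})

test_that("OLS on predictor-independent responses shows no fit", {
  set.seed(42)
  n <- 200
  d <- tibble::tibble(
    fwhm = runif(n, 5, 10), ap = rnorm(n, -8, 10), trt = rnorm(n, 49, 9),
    srt = rnorm(n, 3, 2)
  )
  fit <- fit_srt_glm(d)
  expect_gt(fit$f_p, 0.01)
  expect_lt(abs(fit$r_fitted_measured), 0.3)
})

test_that("rank-deficient designs are rejected", {
  co <- reference_cohort()
  co$fwhm <- co$trt # perfectly collinear
  expect_error(fit_srt_glm(co), "rank-deficient")
})

test_that("glm_predict evaluates the published model", {
  m <- reference_glm_coefficients()
  expect_equal(glm_predict(m, 0, 0, 0), 11.62, tolerance = 1e-12)
  expect_equal(glm_predict(m, 5.1, 2.6, 49.8), 4.71, tolerance = 0.005)
  # linearity in TRT: +10 % lowers the prediction by 1.403 dB
  expect_equal(glm_predict(m, 5, 0, 60) - glm_predict(m, 5, 0, 50), -1.403,
               tolerance = 1e-9)
})

test_that("srt_evaluation computes r, RMS error and bias with exclusions", {
  ev <- srt_evaluation(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ev$r, 1, tolerance = 1e-12)
  expect_identical(ev$rmse, 0)
  expect_identical(ev$bias, 0)
  ev2 <- srt_evaluation(c(1, 2, NA, 4), c(0, 2, 3, 5))
  expect_identical(ev2$n, 3L)
  expect_identical(ev2$n_undefined, 1L)
  expect_equal(ev2$bias, mean(c(1, 0, -1)))
  expect_equal(ev2$rmse, sqrt(mean(c(1, 0, 1))))
})
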