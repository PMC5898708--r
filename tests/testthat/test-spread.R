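test_that("idealized profiles follow the double-sided exponential exactly", {
  g <- small_geometry()
  ps <- idealized_profiles(g, lambda_mm = 2)
  p <- ps$profiles[[11]]
  expect_equal(eval_profile(p, p$x_peak), 1)
  expect_equal(eval_profile(p, p$x_peak + 2), exp(-1))
  expect_equal(eval_profile(p, p$x_peak - 2), exp(-1))
  expect_equal(eval_profile(p, p$x_peak + 4), exp(-2))
  expect_error(idealized_profiles(g, 0), "lambda")
})

test_that("FWHM analytics: symmetric, asymmetric and clipped profiles", {
  g <- small_geometry()
  p2 <- idealized_profiles(g, 2)$profiles[[11]]
  fw <- profile_fwhm(p2, g)
  expect_equal(as.numeric(fw), 2 * 2 * log(2), tolerance = 1e-12)
  expect_false(attr(fw, "clipped"))

  # asymmetric sides: per-side crossings at lambda * ln 2 sum up
  pa <- cisrt:::new_spread_profile(
    1, 17.5, c(A = 1, lambda = 1, offset = 0), c(A = 1, lambda = 3, offset = 0),
    halfwidth_mm = 0
  )
  expect_equal(as.numeric(profile_fwhm(pa, g)), (1 + 3) * log(2),
               tolerance = 1e-12)

  # offsets at 0.6 * max: the profile never falls below half-maximum
  po <- cisrt:::new_spread_profile(
    1, 17.5, c(A = 0.4, lambda = 2, offset = 0.6),
    c(A = 0.4, lambda = 2, offset = 0.6), halfwidth_mm = 0
  )
  fwo <- profile_fwhm(po, g)
  expect_equal(as.numeric(fwo), 35)
  expect_true(attr(fwo, "clipped"))

  # idealized-profile identity over a lambda grid
  for (lam in c(1, 2, 4, 8)) {
    p <- idealized_profiles(g, lam)$profiles[[5]]
    expect_equal(as.numeric(profile_fwhm(p, g)), 2 * lam * log(2),
                 tolerance = 1e-9)
  }
})

test_that("EFI fits recover noiseless ground truth over a parameter grid", {
  g <- small_geometry()
  for (lam in c(1, 2, 4, 8)) {
    for (off in c(0, 0.5)) {
      efi <- synth_efi(g, lambda_apical_mm = lam, lambda_basal_mm = lam,
                       peak_kohm = 2, offset_kohm = off, noise_cv = 0,
                       seed = 1)
      td <- tidy(fit_efi_profiles(efi, g))
      interior <- 4:19
      expect_lt(max(abs(td$lambda_apical[interior] - lam) / lam), 1e-3)
      expect_lt(max(abs(td$lambda_basal[interior] - lam) / lam), 1e-3)
      expect_lt(max(abs(td$a_apical[interior] - 2) / 2), 1e-3)
      if (off > 0) {
        expect_lt(max(abs(td$offset_apical[interior] - off) / off), 1e-2)
      }
    }
  }
})

test_that("EFI fits tolerate 5% multiplicative noise (median lambda error)", {
  g <- small_geometry()
  errs <- sapply(1:20, function(s) {
    efi <- synth_efi(g, lambda_apical_mm = 4, lambda_basal_mm = 2,
                     peak_kohm = 2, offset_kohm = 0.2, noise_cv = 0.05,
                     seed = s)
    truth <- attr(efi, "truth")
    td <- tidy(fit_efi_profiles(efi, g))
    interior <- 4:19
    median(abs((td$lambda_apical[interior] + td$lambda_basal[interior]) / 2 -
                 truth$lambda[interior]) / truth$lambda[interior])
  })
  expect_lt(median(errs), 0.10)
})

test_that("degenerate and edge cases are flagged, continuity holds", {
  g <- small_geometry()
  # constant off-diagonal map: offset absorbs everything, flat flagged fit
  m <- matrix(0.7, 22, 22)
  diag(m) <- 10
  td <- tidy(fit_efi_profiles(efi_map(m), g))
  expect_true(all(td$a_apical < 1e-6))
  expect_true(all(grepl("degenerate", td$flags)))
  expect_true(all(abs(td$fwhm - 35) < 1e-6)) # flat profile never halves
  expect_true(all(td$clipped))

  # edge electrodes mirror their single usable side
  efi <- synth_efi(g, noise_cv = 0)
  ps <- fit_efi_profiles(efi, g)
  expect_true("mirrored_apical" %in% ps$profiles[[1]]$flags)
  expect_true("mirrored_basal" %in% ps$profiles[[22]]$flags)

  # tent interpolation is continuous at the +/- 0.75 mm joints
  p <- ps$profiles[[11]]
  for (s in c(-1, 1)) {
    x0 <- p$x_peak + s * p$halfwidth_mm
    expect_equal(eval_profile(p, x0 - 1e-9), eval_profile(p, x0 + 1e-9),
                 tolerance = 1e-6)
  }
  # non-finite entries are rejected
  m_bad <- efi$matrix; m_bad[3, 4] <- NaN
  bad <- structure(list(matrix = m_bad, n_electrodes = 22), class = "efi_map")
  expect_error(fit_efi_profiles(bad, g), "non-finite")
})

test_that("fitted profiles are non-increasing away from the peak", {
  g <- small_geometry()
  efi <- synth_efi(g, noise_cv = 0.05, seed = 7)
  ps <- fit_efi_profiles(efi, g)
  for (p in ps$profiles[c(3, 11, 20)]) {
    xr <- seq(p$x_peak + p$halfwidth_mm, 35, length.out = 80)
    xl <- seq(0, p$x_peak - p$halfwidth_mm, length.out = 80)
    expect_true(all(diff(eval_profile(p, xr)) <= 1e-9))
    expect_true(all(diff(eval_profile(p, xl)) >= -1e-9))
  }
})

test_that("spread excitation applies peak weights and adds linearly", {
  g <- cochlea_geometry(n_fibers = 281) # fiber exactly at electrode 11
  ps <- idealized_profiles(g, 2)
  x11 <- g$electrode_pos[11]
  fiber_at <- which.min(abs(g$fiber_pos - x11))
  expect_lt(abs(g$fiber_pos[fiber_at] - x11), 1e-9)

  eg <- tibble::tibble(electrode = 11L, time = 0.001, current = 200)
  attr(eg, "params") <- ace_params()
  attr(eg, "duration") <- 0.005
  class(eg) <- c("electrodogram", class(eg))
  exc <- spread_excitation(eg, ps, g, time_step_us = 10)
  expect_equal(max(exc[fiber_at, ]), 200)
  # fiber at distance lambda receives current / e
  fiber_far <- which.min(abs(g$fiber_pos - (x11 + 2)))
  expect_equal(max(exc[fiber_far, ]), 200 * exp(-1), tolerance = 1e-6)
  # linearity in pulse current
  eg2 <- eg; eg2$current <- 400
  exc2 <- spread_excitation(eg2, ps, g, time_step_us = 10)
  expect_equal(sum(exc2), 2 * sum(exc), tolerance = 1e-9)
})

test_that("EFI text round trip preserves the map and units", {
  g <- small_geometry()
  efi <- synth_efi(g, noise_cv = 0.05, seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_efi(efi, path)
  back <- read_efi(path)
  expect_equal(back$matrix, efi$matrix, tolerance = 1e-12)
  # ohm-declared input is converted to kohm storage
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("# unit: ohm", path2)
  utils::write.table(efi$matrix * 1000, path2, append = TRUE,
                     row.names = FALSE, col.names = FALSE)
  expect_equal(read_efi(path2)$matrix, efi$matrix, tolerance = 1e-9)
})
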