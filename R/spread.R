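#' Spatial spread profiles over the cochlear axis
#'
#' A `spread_profile` describes how the electric field of one electrode decays
#' along the cochlea: a single-sided exponential with vertical offset on each
#' side of the electrode (`v(x) = A * exp(-|x - x_e| / lambda) + c`, fitted
#' separately apically and basally), joined by a linear interpolation over
#' `+/- halfwidth_mm` around the electrode where measured values are dominated
#' by electrode impedance rather than anatomy. Beyond the electrode array the
#' fitted exponential is extrapolated with its offset clamped at >= 0.
#'
#' @name spread_profile
NULL

new_spread_profile <- function(electrode, x_peak,
                               apical, basal, halfwidth_mm = 0.75,
                               flags = character(), resid_rms = NA_real_) {
  structure(
    list(
      electrode = electrode, x_peak = x_peak,
      apical = apical, basal = basal,  # each c(A =, lambda =, offset =)
      halfwidth_mm = halfwidth_mm,
      flags = flags, resid_rms = resid_rms
    ),
    class = "spread_profile"
  )
}

side_value <- function(side, d, clamp_offset = FALSE) {
  off <- if (clamp_offset) max(side[["offset"]], 0) else side[["offset"]]
  side[["A"]] * exp(-d / side[["lambda"]]) + off
}

#' Evaluate a spread profile along the cochlear axis
#'
#' @param profile A `spread_profile`.
#' @param x Positions in mm.
#' @param array_range Optional `c(lo, hi)` in mm giving the extent of the
#'   electrode array; outside it the exponential is extrapolated with its
#'   offset clamped at >= 0.
#' @return Normalized-voltage values (same units as the profile amplitudes).
#' @export
eval_profile <- function(profile, x, array_range = NULL) {
  p <- profile
  hw <- p$halfwidth_mm
  va <- side_value(p$apical, hw)
  vb <- side_value(p$basal, hw)
  out <- numeric(length(x))
  d <- x - p$x_peak
  left <- d < -hw
  right <- d > hw
  mid <- !left & !right
  clamp <- if (is.null(array_range)) {
    rep(FALSE, length(x))
  } else {
    x < array_range[1] | x > array_range[2]
  }
  out[left] <- side_value(p$apical, -d[left])
  out[right] <- side_value(p$basal, d[right])
  if (any(left & clamp)) {
    out[left & clamp] <- side_value(p$apical, -d[left & clamp], clamp_offset = TRUE)
  }
  if (any(right & clamp)) {
    out[right & clamp] <- side_value(p$basal, d[right & clamp], clamp_offset = TRUE)
  }
  if (hw > 0 && any(mid)) {
    out[mid] <- va + (vb - va) * (d[mid] + hw) / (2 * hw)
  } else if (any(mid)) {
    out[mid] <- pmax(va, vb)
  }
  out
}

profile_peak <- function(profile) {
  hw <- profile$halfwidth_mm
  max(side_value(profile$apical, hw), side_value(profile$basal, hw))
}

#' Idealized homogeneous spread profiles
#'
#' One symmetrical double-sided exponential per electrode,
#' `w_e(x) = exp(-|x - x_e| / lambda)`: peak 1 at the electrode, decayed to
#' 1/e at distance `lambda`, zero offsets, identical shape for every electrode
#' (homogeneous array). No interpolation region is used.
#'
#' @param geometry A [cochlea_geometry()].
#' @param lambda_mm Spread width in mm (> 0): distance from the peak to 1/e of
#'   the maximum.
#' @return A `spread_profile_set`.
#' @export
idealized_profiles <- function(geometry, lambda_mm) {
  if (!is.numeric(lambda_mm) || lambda_mm <= 0) {
    abort("`lambda_mm` must be > 0")
  }
  profiles <- lapply(seq_len(geometry$n_electrodes), function(e) {
    side <- c(A = 1, lambda = lambda_mm, offset = 0)
    new_spread_profile(e, geometry$electrode_pos[e], side, side,
                       halfwidth_mm = 0)
  })
  new_spread_profile_set(profiles, geometry, source = "idealized")
}

new_spread_profile_set <- function(profiles, geometry, source) {
  structure(
    list(profiles = profiles, geometry = geometry, source = source),
    class = "spread_profile_set"
  )
}

#' @export
print.spread_profile_set <- function(x, ...) {
  cat(sprintf(
    "<spread_profile_set> %d electrodes (%s)\n",
    length(x$profiles), x$source
  ))
  invisible(x)
}

#' Summarise a profile set as a tibble
#'
#' @param x A `spread_profile_set`.
#' @param ... Unused.
#' @return A tibble with one row per electrode: fitted side parameters, FWHM
#'   and flags.
#' @export
tidy.spread_profile_set <- function(x, ...) {
  purrr::map_dfr(x$profiles, function(p) {
    fw <- profile_fwhm(p, x$geometry)
    tibble(
      electrode = p$electrode, x_peak = p$x_peak,
      a_apical = p$apical[["A"]], lambda_apical = p$apical[["lambda"]],
      offset_apical = p$apical[["offset"]],
      a_basal = p$basal[["A"]], lambda_basal = p$basal[["lambda"]],
      offset_basal = p$basal[["offset"]],
      fwhm = as.numeric(fw), clipped = isTRUE(attr(fw, "clipped")),
      resid_rms = p$resid_rms,
      flags = paste(p$flags, collapse = ",")
    )
  })
}

# initial guesses for a single-sided exponential-plus-offset fit:
# (a) log-linear regression on values above the presumed offset, and
# (b) an offset-free estimate of lambda from ratios of successive
#     differences, v_i - v_{i+1} = A e^(-d_i/l) (1 - e^(-step/l))
init_side_fits <- function(d, v) {
  o <- order(d)
  ds <- d[o]; vs <- v[o]
  c0 <- min(v)
  eps <- max(diff(range(v)), 1e-6) * 1e-3
  y <- log(pmax(v - c0, eps))
  sl <- coef(lm(y ~ d))
  lam_lin <- if (is.finite(sl[2]) && sl[2] < 0) -1 / sl[2] else 3
  lam_lin <- min(max(lam_lin, 0.2), 50)
  inits <- list(list(A = max(exp(sl[1]), eps), lambda = lam_lin, c = c0))

  # zero-offset alternative: plain log-linear regression, exact when c = 0
  if (all(v > 0)) {
    sl0 <- coef(lm(log(v) ~ d))
    if (is.finite(sl0[2]) && sl0[2] < 0) {
      inits <- c(inits, list(list(
        A = unname(exp(sl0[1])),
        lambda = unname(min(max(-1 / sl0[2], 0.05), 50)), c = 0
      )))
    }
  }

  w <- -diff(vs)
  steps <- diff(ds)
  ok <- which(w[-length(w)] > eps & w[-1] > eps)
  if (length(ok)) {
    lam_diff <- median(steps[ok] / log(w[ok] / w[ok + 1]))
    if (is.finite(lam_diff) && lam_diff > 0) {
      lam_diff <- min(max(lam_diff, 0.05), 50)
      A0 <- max((vs[1] - c0) * exp(ds[1] / lam_diff), eps)
      inits <- c(inits, list(list(A = A0, lambda = lam_diff, c = c0)))
    }
  }
  inits
}

# profiled least squares: for fixed lambda the model is linear in (A, c);
# the 1-D profile over log(lambda) is optimized directly. Robust for sides
# with as few as 3 points, where the full Jacobian can be near-singular.
fit_side_profiled <- function(d, v) {
  rss_par <- function(loglam) {
    lam <- exp(loglam)
    X <- cbind(exp(-d / lam), 1)
    co <- tryCatch(qr.solve(X, v), error = function(e) c(NA, NA))
    if (!all(is.finite(co)) || co[1] < 0) co <- c(0, mean(v))
    r <- v - X %*% co
    list(rss = sum(r^2), A = co[1], c = co[2], lambda = lam)
  }
  opt <- stats::optimize(function(l) rss_par(l)$rss,
                         interval = log(c(0.05, 50)), tol = 1e-10)
  best <- rss_par(opt$minimum)
  list(par = c(A = best$A, lambda = best$lambda, offset = best$c),
       resid = sqrt(best$rss / length(v)))
}

# EFI measurement noise is predominantly multiplicative (constant CV), so the
# exponential-plus-offset model is fitted with log-domain residuals when all
# recordings are positive; candidates from several starts plus a profiled
# linear-domain fit are scored on the same criterion and the best is kept
fit_side <- function(d, v) {
  # degenerate: (near-)constant recordings; the offset absorbs everything
  if (diff(range(v)) < 1e-9 * max(abs(v), 1)) {
    return(list(par = c(A = 0, lambda = 1, offset = mean(v)),
                flag = "degenerate", resid = 0))
  }
  use_log <- all(v > 0)
  score <- function(par) {
    m <- par[["A"]] * exp(-d / par[["lambda"]]) + par[["offset"]]
    if (use_log) {
      if (any(m <= 0)) return(Inf)
      rms(log(v) - log(m))
    } else {
      rms(v - m)
    }
  }
  fits <- lapply(init_side_fits(d, v), function(st) {
    st$A <- max(st$A, 1e-9)
    st$c <- max(st$c, 1e-9)
    tryCatch(
      if (use_log) {
        lv <- log(v)
        minpack.lm::nlsLM(
          lv ~ log(A * exp(-d / lambda) + c),
          start = list(A = st$A, lambda = st$lambda, c = st$c),
          lower = c(A = 1e-9, lambda = 1e-3, c = 1e-9),
          upper = c(A = Inf, lambda = 1e3, c = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      } else {
        minpack.lm::nlsLM(
          v ~ A * exp(-d / lambda) + c,
          start = list(A = st$A, lambda = st$lambda, c = st$c),
          lower = c(A = 0, lambda = 1e-3, c = -Inf),
          upper = c(A = Inf, lambda = 1e3, c = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      },
      error = function(e) NULL
    )
  })
  fits <- fits[vapply(fits, function(f) {
    !is.null(f) && all(is.finite(coef(f)))
  }, logical(1))]
  pars <- lapply(fits, function(f) {
    co <- coef(f)
    c(A = unname(co["A"]), lambda = unname(co["lambda"]),
      offset = unname(co["c"]))
  })
  pars <- c(pars, list(fit_side_profiled(d, v)$par))
  resids <- vapply(pars, score, numeric(1))
  best <- pars[[which.min(resids)]]
  list(par = best,
       flag = if (best[["A"]] < 1e-8) "degenerate" else character(),
       resid = min(resids))
}

#' Fit spread profiles to an electrical field imaging map
#'
#' Per stimulating electrode, fits `v(x) = A * exp(-|x - x_e|/lambda) + c` by
#' nonlinear least squares separately to the apical-side and basal-side
#' off-diagonal recordings of the EFI map (the recording at the stimulating
#' electrode is excluded: it is dominated by electrode-tissue impedance).
#' The returned profiles evaluate as the fitted exponential-plus-offset beyond
#' `+/- 0.75 mm` of the stimulating electrode, as a linear interpolation
#' between the two side-fit values inside that region, and as the clamped
#' extrapolated exponential beyond the array.
#'
#' Edge electrodes with fewer than 3 recordings on one side fall back to the
#' mirrored fit of the other side (flagged `"mirrored_*"`).
#'
#' @param efi An [efi_map()] (22 x 22 normalized-voltage matrix, kOhm).
#' @param geometry A [cochlea_geometry()].
#' @param halfwidth_mm Half-width of the interpolation region in mm.
#' @return A `spread_profile_set` with per-electrode fit diagnostics.
#' @export
fit_efi_profiles <- function(efi, geometry, halfwidth_mm = 0.75) {
  m <- efi$matrix
  ne <- geometry$n_electrodes
  stopifnot(nrow(m) == ne, ncol(m) == ne)
  if (!all(is.finite(m))) abort("EFI map contains non-finite entries")
  xs <- geometry$electrode_pos
  profiles <- lapply(seq_len(ne), function(e) {
    v <- m[e, ]
    idx_a <- which(seq_len(ne) < e)
    idx_b <- which(seq_len(ne) > e)
    flags <- character()
    side_a <- side_b <- NULL
    resids <- c()
    if (length(idx_a) >= 3) {
      fa <- fit_side(xs[e] - xs[idx_a], v[idx_a])
      side_a <- fa$par; flags <- c(flags, fa$flag); resids <- c(resids, fa$resid)
    }
    if (length(idx_b) >= 3) {
      fb <- fit_side(xs[idx_b] - xs[e], v[idx_b])
      side_b <- fb$par; flags <- c(flags, fb$flag); resids <- c(resids, fb$resid)
    }
    if (is.null(side_a) && is.null(side_b)) {
      abort(sprintf("electrode %d: fewer than 3 usable points on both sides", e))
    }
    if (is.null(side_a)) { side_a <- side_b; flags <- c(flags, "mirrored_apical") }
    if (is.null(side_b)) { side_b <- side_a; flags <- c(flags, "mirrored_basal") }
    new_spread_profile(e, xs[e], side_a, side_b,
                       halfwidth_mm = halfwidth_mm, flags = flags,
                       resid_rms = mean(resids, na.rm = TRUE))
  })
  new_spread_profile_set(profiles, geometry, source = "efi_fit")
}

# analytic half-maximum crossing on one exponential side; returns distance
# from the peak position, or NA when the side never falls below `level`
side_crossing <- function(side, level, hw, side_max_d) {
  A <- side[["A"]]; lam <- side[["lambda"]]; off <- side[["offset"]]
  if (A <= 0 || level <= off) return(NA_real_)
  d <- lam * log(A / (level - off))
  if (d > side_max_d) return(NA_real_)
  max(d, hw)
}

#' Full width at half maximum of a spread profile
#'
#' Width of the region where the composed profile (side exponentials plus
#' linear interpolation region) is at least half its absolute maximum. The
#' half-max reference level is `max / 2` relative to 0 (offsets included in
#' the curve), not relative to the offset. If a side never falls below
#' half-maximum within the cochlea, that side is clipped at the domain
#' boundary and the result is flagged.
#'
#' @param profile A `spread_profile`.
#' @param geometry A [cochlea_geometry()] providing the domain `[0, length]`.
#' @return FWHM in mm with attribute `clipped` (logical).
#' @export
#' @examples
#' g <- cochlea_geometry()
#' p <- idealized_profiles(g, 2)$profiles[[11]]
#' profile_fwhm(p, g) # 2 * 2 * log(2) = 2.77 mm
profile_fwhm <- function(profile, geometry) {
  p <- profile
  hw <- p$halfwidth_mm
  va <- side_value(p$apical, hw)
  vb <- side_value(p$basal, hw)
  m <- max(va, vb)
  if (!is.finite(m) || m <= 0) abort("profile maximum is not positive")
  level <- m / 2
  L <- geometry$length_mm
  clipped <- FALSE

  # apical (left) crossing
  if (va >= level) {
    d <- side_crossing(p$apical, level, hw, side_max_d = p$x_peak)
    if (is.na(d)) { x_left <- 0; clipped <- TRUE } else x_left <- p$x_peak - d
  } else {
    # crossing inside the linear interpolation region
    x_left <- p$x_peak - hw + (level - va) / (vb - va) * 2 * hw
  }
  # basal (right) crossing
  if (vb >= level) {
    d <- side_crossing(p$basal, level, hw, side_max_d = L - p$x_peak)
    if (is.na(d)) { x_right <- L; clipped <- TRUE } else x_right <- p$x_peak + d
  } else {
    x_right <- p$x_peak + hw - (level - vb) / (va - vb) * 2 * hw
  }
  structure(x_right - x_left, clipped = clipped)
}

#' FWHM table for a profile set
#'
#' @param profiles A `spread_profile_set`.
#' @return Tibble with `electrode`, `fwhm` (mm) and `clipped`.
#' @export
fwhm_table <- function(profiles) {
  purrr::map_dfr(profiles$profiles, function(p) {
    fw <- profile_fwhm(p, profiles$geometry)
    tibble(electrode = p$electrode, fwhm = as.numeric(fw),
           clipped = isTRUE(attr(fw, "clipped")))
  })
}

#' Peak-normalized fiber weights of a profile set
#'
#' Evaluates every profile at the fiber positions and divides by its composed
#' maximum, making idealized and EFI-fitted profiles commensurable as
#' excitation weights in `[0, 1]`.
#'
#' @param profiles A `spread_profile_set`.
#' @param geometry A [cochlea_geometry()]; defaults to the set's own.
#' @return Matrix fibers x electrodes.
#' @export
profile_weights <- function(profiles, geometry = profiles$geometry) {
  arr <- range(geometry$electrode_pos)
  vapply(profiles$profiles, function(p) {
    eval_profile(p, geometry$fiber_pos, array_range = arr) / profile_peak(p)
  }, numeric(geometry$n_fibers))
}

#' Spread pulse stimulation onto the auditory-nerve fibers
#'
#' Converts an electrodogram into a fiber x time drive matrix on the
#' auditory-nerve simulation grid: the drive a fiber receives from a pulse on
#' electrode e is the pulse current times the peak-normalized profile weight
#' at the fiber position; temporally overlapping pulses add linearly. Each
#' biphasic pulse is rectified to its cathodic-phase drive: the pulse current
#' is deposited for `phase_width_us` starting at the pulse time.
#'
#' @param electrodogram An [ace_encode()] result.
#' @param profiles A `spread_profile_set`.
#' @param geometry A [cochlea_geometry()].
#' @param time_step_us Simulation time step in microseconds.
#' @param duration_s Optional total duration; defaults to the electrodogram's.
#' @return Matrix fibers x time steps (uA-equivalent drive) with attributes
#'   `time_step_us` and `fiber_pos`.
#' @export
spread_excitation <- function(electrodogram, profiles, geometry,
                              time_step_us = 10, duration_s = NULL) {
  if (geometry$n_electrodes != length(profiles$profiles)) {
    abort("profile set does not match geometry")
  }
  params <- attr(electrodogram, "params")
  phase_us <- params$phase_width_us %||% 25
  dt <- time_step_us * 1e-6
  dur <- duration_s %||% attr(electrodogram, "duration")
  n_t <- max(1L, ceiling(dur / dt))
  # charge-conserving deposit: full bins plus a fractional final bin so the
  # integrated drive equals current * phase_width at any time step
  n_full <- floor(phase_us / time_step_us)
  frac <- phase_us / time_step_us - n_full
  bin_w <- c(rep(1, n_full), if (frac > 1e-9) frac)
  drive_e <- matrix(0, geometry$n_electrodes, n_t)
  if (nrow(electrodogram) > 0) {
    t0 <- pmin(floor(electrodogram$time / dt) + 1L, n_t)
    for (k in seq_along(bin_w)) {
      idx <- pmin(t0 + k - 1L, n_t)
      # accumulate currents; a matrix-index assignment would drop coincident
      # pulses, so go through a flat tabulation
      flat <- (idx - 1L) * geometry$n_electrodes + electrodogram$electrode
      acc <- rowsum(electrodogram$current * bin_w[k], flat)
      drive_e[as.integer(rownames(acc))] <-
        drive_e[as.integer(rownames(acc))] + acc[, 1]
    }
  }
  w <- profile_weights(profiles, geometry)
  structure(w %*% drive_e,
            time_step_us = time_step_us, fiber_pos = geometry$fiber_pos)
}
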