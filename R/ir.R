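#' Group auditory-nerve fibers into place channels
#'
#' Partitions the cochlear axis into contiguous, non-overlapping place groups:
#' one group per electrode bounded by the arithmetic midpoints between
#' neighbouring electrode positions, and constant-width 0.75 mm groups beyond
#' the most apical and most basal electrodes. The residual 0.25 mm at each
#' cochlear extreme is merged into the terminal group, so the default
#' geometry (35 mm, 22 electrodes at 0.75 mm pitch, centered) yields exactly
#' 46 groups: 12 apical + 22 electrode + 12 basal.
#'
#' @param geometry A [cochlea_geometry()].
#' @param expected_groups Expected total group count (errors with the computed
#'   count if not met); `NULL` disables the check.
#' @return A `place_grouping`: tibble with `group`, `lo`, `hi` (mm) and
#'   `electrode` (`NA` for beyond-array groups), plus attribute `fiber_group`
#'   mapping each fiber to its group.
#' @export
build_grouping <- function(geometry = cochlea_geometry(),
                           expected_groups = 46) {
  xs <- geometry$electrode_pos
  pitch <- geometry$pitch_mm
  width <- 0.75
  lo_arr <- xs[1] - pitch / 2
  hi_arr <- xs[length(xs)] + pitch / 2
  mids <- (xs[-1] + xs[-length(xs)]) / 2
  elec_edges <- c(lo_arr, mids, hi_arr)

  n_ap <- floor(lo_arr / width)
  n_ba <- floor((geometry$length_mm - hi_arr) / width)
  # beyond-array edges; the residual at the cochlear extremes is merged into
  # the terminal groups (first apical edge is 0, last basal edge is length)
  ap_edges <- c(0, lo_arr - width * rev(seq_len(n_ap - 1)), lo_arr)
  ba_edges <- c(hi_arr + width * seq_len(n_ba - 1), geometry$length_mm)
  edges <- unique(c(ap_edges, elec_edges[-1], ba_edges))
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  electrode <- c(rep(NA_integer_, n_ap), seq_along(xs), rep(NA_integer_, n_ba))
  n_groups <- length(lo)
  if (!is.null(expected_groups) && n_groups != expected_groups) {
    abort(sprintf("grouping yields %d groups, expected %d",
                  n_groups, expected_groups))
  }
  g <- tibble(group = seq_len(n_groups), lo = lo, hi = hi,
              electrode = electrode)
  fiber_group <- findInterval(geometry$fiber_pos, c(lo, geometry$length_mm),
                              rightmost.closed = TRUE)
  fiber_group <- pmin(pmax(fiber_group, 1L), n_groups)
  structure(g, class = c("place_grouping", class(g)),
            fiber_group = fiber_group, geometry = geometry)
}

#' Integration parameters of the internal representation
#'
#' @param integration_tau_ms Leaky-integration time constant (ms).
#' @param masking_tau_ms Forward-masking decay time constant (ms).
#' @param masking_strength Forward-masking strength in `[0, 1]`.
#' @param gain Output gain (from [calibrate_gain()]; 1 if uncalibrated).
#' @param frame_rate Frame update rate in Hz (fixed at 500 by convention).
#' @return An object of class `ir_params`.
#' @export
ir_params <- function(integration_tau_ms = 10, masking_tau_ms = 100,
                      masking_strength = 0.5, gain = 1, frame_rate = 500) {
  stopifnot(integration_tau_ms > 0, masking_tau_ms > 0,
            masking_strength >= 0, masking_strength <= 1, gain > 0)
  structure(
    list(integration_tau_ms = integration_tau_ms,
         masking_tau_ms = masking_tau_ms,
         masking_strength = masking_strength,
         gain = gain, frame_rate = frame_rate),
    class = "ir_params"
  )
}

#' Temporally integrate spike trains into an internal representation
#'
#' Per place group, spike counts in 2 ms frames are smoothed by a first-order
#' leaky integrator (`y_t = beta * y_{t-1} + (1 - beta) * x_t`,
#' `beta = exp(-frame / tau)`), then a forward-masking trace - accumulating
#' with past smoothed output and decaying with `masking_tau_ms` - is
#' subtracted, scaled by `masking_strength` and floored at 0 (smooth-then-mask
#' order). The result, scaled by `gain`, is the internal representation: a
#' place x time matrix at the frame rate, amplitudes calibrated to roughly
#' 0-50.
#'
#' @param raster A [simulate_population()] result.
#' @param grouping A [build_grouping()] result.
#' @param params An [ir_params()].
#' @param duration_s Optional duration override (s).
#' @return An `internal_representation`: groups x frames matrix with
#'   attributes `frame_rate`, `grouping`, `params`.
#' @export
integrate_spikes <- function(raster, grouping, params = ir_params(),
                             duration_s = NULL) {
  n_g <- nrow(grouping)
  fr <- params$frame_rate
  dur <- duration_s %||% raster$duration
  n_f <- max(1L, ceiling(dur * fr))
  counts <- matrix(0, n_g, n_f)
  fiber_group <- attr(grouping, "fiber_group")
  if (length(raster$spikes) && sum(lengths(raster$spikes)) > 0) {
    g <- rep(fiber_group[seq_along(raster$spikes)], lengths(raster$spikes))
    tt <- unlist(raster$spikes)
    fi <- pmin(floor(tt * fr) + 1L, n_f)
    flat <- (fi - 1L) * n_g + g
    acc <- rowsum(rep(1, length(flat)), flat)
    counts[as.integer(rownames(acc))] <- acc[, 1]
  }
  beta <- exp(-(1000 / fr) / params$integration_tau_ms)
  gamma <- exp(-(1000 / fr) / params$masking_tau_ms)
  sm <- t(apply(counts, 1, function(x) {
    as.numeric(stats::filter((1 - beta) * x, beta, method = "recursive"))
  }))
  if (params$masking_strength > 0) {
    mask <- t(apply(sm, 1, function(y) {
      lagged <- c(0, y[-length(y)])
      as.numeric(stats::filter((1 - gamma) * lagged, gamma,
                               method = "recursive"))
    }))
    out <- pmax(sm - params$masking_strength * mask, 0)
  } else {
    out <- sm
  }
  structure(out * params$gain,
            class = "internal_representation",
            frame_rate = fr, grouping = grouping, params = params)
}

#' @export
print.internal_representation <- function(x, ...) {
  cat(sprintf(
    "<internal_representation> %d rows x %d frames @ %g Hz, max %.1f\n",
    nrow(x), ncol(x), attr(x, "frame_rate"), max(x)
  ))
  invisible(x)
}

#' Write / read an internal representation as delimited text
#'
#' Plain text: header lines with the frame rate and the place-group edges,
#' then the place x time matrix (one row per place channel).
#'
#' @param ir An `internal_representation`.
#' @param path File path.
#' @return `path` invisibly (writer) / an `internal_representation` (reader;
#'   the grouping is restored as edge positions only).
#' @export
write_ir <- function(ir, path) {
  grouping <- attr(ir, "grouping")
  edges <- if (!is.null(grouping)) c(grouping$lo, grouping$hi[nrow(grouping)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate_hz: %g", attr(ir, "frame_rate")), con)
  writeLines(paste("# group_edges_mm:", paste(edges, collapse = " ")), con)
  utils::write.table(unclass(ir), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ir
#' @export
read_ir <- function(path) {
  hdr <- readLines(path, n = 2)
  fr <- as.numeric(sub(".*frame_rate_hz:\\s*", "", hdr[1]))
  edges <- as.numeric(strsplit(sub(".*group_edges_mm:\\s*", "", hdr[2]),
                               " ")[[1]])
  m <- as.matrix(utils::read.table(path, skip = 2))
  dimnames(m) <- NULL
  structure(m, class = "internal_representation",
            frame_rate = fr, group_edges = edges)
}

#' Apply multiplicative internal noise to an internal representation
#'
#' Multiplies each place-time bin independently by Gaussian noise with mean 1
#' and standard deviation `sigma` (no clipping: negative bins pass through to
#' the recognizer). `sigma = 0` returns the input unchanged. The internal
#' noise is the model's coarse stand-in for individual cognitive limitations.
#'
#' @param ir An `internal_representation` (or plain matrix).
#' @param sigma Noise standard deviation (>= 0), typically 0.025-0.3.
#' @param seed Integer seed.
#' @return The perturbed representation (same class/attributes).
#' @export
apply_internal_noise <- function(ir, sigma, seed = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    abort("`sigma` must be a single number >= 0")
  }
  if (sigma == 0) return(ir)
  set.seed(seed)
  noisy <- ir * matrix(rnorm(length(ir), 1, sigma), nrow(ir), ncol(ir))
  attributes(noisy) <- attributes(ir)
  noisy
}

#' Calibrate the internal-representation gain
#'
#' Chooses the gain so that the 99th percentile of IR amplitudes over
#' calibration material at reference level equals 50, anchoring the
#' representation to its conventional 0-50 amplitude range.
#'
#' @param irs A list of uncalibrated (gain 1) internal representations, or a
#'   single one; at least ~10 s of material is recommended.
#' @param target Amplitude the 99th percentile is mapped to.
#' @param probs Percentile used for calibration.
#' @return The gain (dimensionless scalar).
#' @export
calibrate_gain <- function(irs, target = 50, probs = 0.99) {
  if (is.matrix(irs)) irs <- list(irs)
  vals <- unlist(lapply(irs, as.numeric))
  q <- quantile(vals, probs, names = FALSE)
  if (!is.finite(q) || q <= 0) {
    abort("calibration material is silent; cannot calibrate gain")
  }
  target / q
}
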