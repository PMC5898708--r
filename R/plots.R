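#' Plot an electrodogram
#'
#' Pulse raster: time against electrode (apex at the bottom), point size and
#' colour encoding pulse current.
#'
#' @param object An `electrodogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.electrodogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$electrode,
                               colour = .data$current)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::scale_y_continuous(breaks = seq(2, attr(object, "n_electrodes"),
                                             by = 4)) +
    ggplot2::labs(x = "time (s)", y = "electrode (1 = apical)",
                  colour = "current (µA)") +
    ggplot2::theme_minimal()
}

#' Plot an internal representation
#'
#' Heatmap of the place x time matrix (46 rows at 500 Hz frames by default).
#'
#' @param object An `internal_representation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.internal_representation <- function(object, ...) {
  fr <- attr(object, "frame_rate")
  d <- tidyr::expand_grid(row = seq_len(nrow(object)),
                          frame = seq_len(ncol(object)))
  d$value <- as.numeric(unclass(object)[cbind(d$row, d$frame)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame / fr, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "place channel (apical first)",
                  fill = "amplitude") +
    ggplot2::theme_minimal()
}

#' Plot a train-by-test score matrix
#'
#' Tile map of word-correct percentages over the training-SNR x testing-SNR
#' plane; the 50% iso-score contour of the column envelope defines the SRT.
#'
#' @param object A `score_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.score_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$test_snr, y = .data$train_snr,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = "testing SNR (dB)", y = "training SNR (dB)",
                  fill = "words correct (%)") +
    ggplot2::theme_minimal()
}

#' Plot a spread/internal-noise sweep
#'
#' Median predicted SRT against spread width, one line per internal-noise sd.
#'
#' @param object A `ci_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ci_sweep <- function(object, ...) {
  ggplot2::ggplot(summarise_sweep(object),
                  ggplot2::aes(x = .data$lambda, y = .data$srt_median,
                               colour = factor(.data$sigma_int))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "spatial spread λ (mm)",
                  y = "predicted SRT (dB SNR)",
                  colour = "σ_int") +
    ggplot2::theme_minimal()
}

#' Plot spread profiles along the cochlear axis
#'
#' @param profiles A `spread_profile_set`.
#' @param normalize Plot peak-normalized weights instead of kOhm values.
#' @return A ggplot.
#' @export
plot_spread_profiles <- function(profiles, normalize = FALSE) {
  g <- profiles$geometry
  x <- seq(0, g$length_mm, length.out = 400)
  arr <- range(g$electrode_pos)
  d <- purrr::map_dfr(profiles$profiles, function(p) {
    v <- eval_profile(p, x, array_range = arr)
    if (normalize) v <- v / profile_peak(p)
    tibble(electrode = p$electrode, x = x, value = v)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$value,
                                  group = .data$electrode)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "cochlear position (mm, apex = 0)",
                  y = if (normalize) "weight" else "normalized voltage (kΩ)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
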