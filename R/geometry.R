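#' One-dimensional cochlea geometry
#'
#' Describes the simplified straight cochlea used throughout the model: a
#' 35 mm axis with a 22-electrode array at 0.75 mm pitch positioned centrally
#' (electrode 1 most apical at 9.625 mm, electrode 22 at 25.375 mm) and
#' auditory-nerve fibers equally distributed along the entire length.
#'
#' @param length_mm Cochlear duct length in mm.
#' @param n_electrodes Number of intracochlear electrodes.
#' @param pitch_mm Electrode centre-to-centre spacing in mm.
#' @param n_fibers Number of modelled auditory-nerve fibers.
#' @return An object of class `cochlea_geometry` with electrode and fiber
#'   positions in mm (apical to basal, ascending).
#' @export
#' @examples
#' g <- cochlea_geometry()
#' g$electrode_pos[c(1, 22)] # 9.625, 25.375
cochlea_geometry <- function(length_mm = 35, n_electrodes = 22,
                             pitch_mm = 0.75, n_fibers = 1000) {
  stopifnot(length_mm > 0, n_electrodes >= 2, pitch_mm > 0, n_fibers >= 1)
  span <- (n_electrodes - 1) * pitch_mm
  if (span >= length_mm) abort("electrode array longer than the cochlea")
  first <- (length_mm - span) / 2
  structure(
    list(
      length_mm = length_mm,
      n_electrodes = n_electrodes,
      pitch_mm = pitch_mm,
      electrode_pos = first + (seq_len(n_electrodes) - 1) * pitch_mm,
      n_fibers = n_fibers,
      fiber_pos = seq(0, length_mm, length.out = n_fibers)
    ),
    class = "cochlea_geometry"
  )
}

#' @export
print.cochlea_geometry <- function(x, ...) {
  cat(sprintf(
    "<cochlea_geometry> %g mm, %d electrodes (pitch %g mm, %g-%g mm), %d fibers\n",
    x$length_mm, x$n_electrodes, x$pitch_mm,
    min(x$electrode_pos), max(x$electrode_pos), x$n_fibers
  ))
  invisible(x)
}
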