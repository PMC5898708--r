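#' Electrical field imaging (EFI) map
#'
#' Container for an intracochlear potential map: the voltage recorded on every
#' electrode while stimulating each electrode in monopolar mode, normalized by
#' the stimulation current. The normalized voltage has impedance units; maps
#' are stored in kOhm. Row = stimulating electrode (1 = most apical), column =
#' recording electrode. Diagonal entries are dominated by the electrode-tissue
#' impedance and are excluded from profile fitting.
#'
#' @param matrix Square numeric matrix of non-negative normalized voltages.
#' @param unit `"kohm"` (storage unit) or `"ohm"` (converted on input).
#' @return An object of class `efi_map`.
#' @export
efi_map <- function(matrix, unit = c("kohm", "ohm")) {
  unit <- match.arg(unit)
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) abort("EFI map must be square")
  if (any(!is.finite(m))) abort("EFI map contains non-finite entries")
  if (any(m < 0)) abort("EFI map entries must be non-negative")
  if (unit == "ohm") m <- m / 1000
  dimnames(m) <- NULL
  structure(list(matrix = m, n_electrodes = nrow(m)), class = "efi_map")
}

#' @export
print.efi_map <- function(x, ...) {
  cat(sprintf("<efi_map> %d x %d (kOhm), diagonal excluded from fits\n",
              x$n_electrodes, x$n_electrodes))
  invisible(x)
}

#' Read / write EFI maps as delimited text
#'
#' Plain whitespace-delimited text with a single header line declaring the
#' unit (`# unit: ohm` or `# unit: kohm`), then the square matrix, row =
#' stimulating electrode (1 = apical).
#'
#' @param path File path.
#' @return An `efi_map` (reader) or `path` invisibly (writer).
#' @export
read_efi <- function(path) {
  header <- readLines(path, n = 1)
  unit <- if (grepl("unit:\\s*ohm", header, ignore.case = TRUE) &&
              !grepl("kohm", header, ignore.case = TRUE)) "ohm" else "kohm"
  m <- as.matrix(utils::read.table(path, skip = 1))
  efi_map(m, unit = unit)
}

#' @rdname read_efi
#' @param efi An `efi_map`.
#' @export
write_efi <- function(efi, path) {
  writeLines("# unit: kohm", path)
  utils::write.table(efi$matrix, path, append = TRUE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Synthesize an EFI map with known ground truth
#'
#' Generates a 22 x 22 normalized-voltage map from per-electrode exponential
#' decays with offsets: entry (e, m) is
#' `A_e * exp(-|x_m - x_e| / lambda_e) + c_e`, times multiplicative lognormal
#' noise with coefficient of variation `noise_cv`. The decay length
#' `lambda_e` is interpolated linearly from `lambda_apical_mm` (electrode 1)
#' to `lambda_basal_mm` (electrode 22), emulating the trend of wider spatial
#' spread at apical electrodes. Diagonal entries are inflated by a large
#' electrode-impedance term so the fitter's diagonal-exclusion rule is
#' exercised.
#'
#' @param geometry A [cochlea_geometry()].
#' @param lambda_apical_mm,lambda_basal_mm Decay lengths in mm (> 0).
#' @param peak_kohm Exponential amplitude `A` in kOhm.
#' @param offset_kohm Vertical offset `c` in kOhm (`0 <= offset < peak`).
#' @param noise_cv Coefficient of variation of multiplicative noise (>= 0).
#' @param seed Integer seed; the generator is a pure function of
#'   `(seed, arguments)`.
#' @return An `efi_map` with attribute `truth` (tibble of per-electrode
#'   `lambda`, `A`, `offset`).
#' @export
synth_efi <- function(geometry = cochlea_geometry(),
                      lambda_apical_mm = 4, lambda_basal_mm = 2,
                      peak_kohm = 2, offset_kohm = 0.2,
                      noise_cv = 0, seed = 1) {
  stopifnot(lambda_apical_mm > 0, lambda_basal_mm > 0, noise_cv >= 0,
            peak_kohm > offset_kohm, offset_kohm >= 0)
  ne <- geometry$n_electrodes
  xs <- geometry$electrode_pos
  lambdas <- seq(lambda_apical_mm, lambda_basal_mm, length.out = ne)
  m <- matrix(0, ne, ne)
  for (e in seq_len(ne)) {
    m[e, ] <- peak_kohm * exp(-abs(xs - xs[e]) / lambdas[e]) + offset_kohm
  }
  set.seed(seed)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    m <- m * matrix(stats::rlnorm(ne * ne, -sdlog^2 / 2, sdlog), ne, ne)
  }
  # electrode-tissue impedance dominates the diagonal
  diag(m) <- (peak_kohm + offset_kohm) * 5 + diag(m)
  out <- efi_map(m)
  attr(out, "truth") <- tibble(
    electrode = seq_len(ne), lambda = lambdas,
    A = peak_kohm, offset = offset_kohm
  )
  out
}
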