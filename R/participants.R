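#' Synthesize a participant cohort table
#'
#' Generates a cohort with the statistical structure of a CI study population:
#' text-reception thresholds (TRT) from a truncated normal
#' `N(49, 9^2)` on `[20, 80]`, anamnesis fields (durations of moderate and
#' severe hearing loss, hearing-aid use, supplied `b1`/`b2` adjustments)
#' sampled so that the auditory-performance score spans roughly
#' `[-30, +6] %`, and measured SRTs generated as a fixed linear function of
#' TRT (`-0.1 dB per TRT %`) plus Gaussian noise (sd 1.5 dB), so the TRT-SRT
#' correlation is negative by construction.
#'
#' @param n Cohort size (>= 3).
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `trt`, `dur_mhl`, `dur_shl`,
#'   `hearing_aid_use`, `b1`, `b2`, `ap`, `srt`.
#' @export
synth_participants <- function(n = 14, seed = 1) {
  if (n < 3) abort("need n >= 3 participants")
  set.seed(seed)
  trt <- numeric(0)
  while (length(trt) < n) {
    draw <- rnorm(2 * n, 49, 9)
    trt <- c(trt, draw[draw >= 20 & draw <= 80])
  }
  trt <- trt[seq_len(n)]
  dur_mhl <- runif(n, 0, 30)
  dur_shl <- runif(n, 0, 25)
  ha <- sample(c("none", "one_side", "both_sides"), n, replace = TRUE)
  b1 <- runif(n, -2, 4)
  b2 <- runif(n, -2, 4)
  ap <- auditory_performance(dur_mhl, dur_shl, ha, b1, b2)
  srt <- 7.8 - 0.1 * trt + rnorm(n, 0, 1.5)
  tibble(
    id = sprintf("p%03d", seq_len(n)),
    trt = trt, dur_mhl = dur_mhl, dur_shl = dur_shl,
    hearing_aid_use = ha, b1 = b1, b2 = b2,
    ap = unname(ap), srt = srt
  )
}

#' Read / write participant tables as delimited text
#'
#' Comma-separated with a header; columns as documented in
#' [synth_participants()].
#'
#' @param participants Tibble of participants.
#' @param path File path.
#' @return Tibble (reader) / `path` invisibly (writer).
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(id = "character")))
}
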