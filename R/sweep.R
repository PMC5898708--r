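#' Sweep predicted SRTs over spatial spread and internal noise
#'
#' Runs the full pipeline for every combination of idealized spread width
#' `lambda` and internal-noise sd `sigma_int`, over one or more seeds.
#' Front-end simulations are cached per (lambda, seed) and reused across
#' `sigma_int` values, since internal noise is applied to the internal
#' representations after simulation. Stage failures are caught and reported
#' per cell; the sweep continues.
#'
#' @param corpus A [synth_corpus()] result.
#' @param noise Noise waveform.
#' @param config A [ci_config()].
#' @param lambdas Spread widths in mm.
#' @param sigmas Internal-noise standard deviations.
#' @param seeds Integer seeds (one pipeline run per seed).
#' @return A `ci_sweep` tibble: `lambda`, `sigma_int`, `seed`, `srt`, `flag`,
#'   with a provenance attribute (config hash, seeds).
#' @export
run_sweep <- function(corpus, noise, config, lambdas, sigmas, seeds = 1:3) {
  cells <- tidyr::expand_grid(lambda = lambdas, sigma_int = sigmas,
                              seed = seeds)
  rows <- vector("list", nrow(cells))
  cache_key <- ""
  pre <- NULL
  for (i in seq_len(nrow(cells))) {
    lam <- cells$lambda[i]; sig <- cells$sigma_int[i]; sd_i <- cells$seed[i]
    key <- paste(lam, sd_i)
    rows[[i]] <- tryCatch({
      if (!identical(key, cache_key)) {
        profiles <- idealized_profiles(config$geometry, lam)
        pre <- precompute_pipeline_irs(corpus, noise, config, seed = sd_i,
                                       profiles = profiles)
        cache_key <- key
      }
      m <- run_snr_matrix(corpus, noise, config, seed = sd_i,
                          precomputed = pre, sigma_int = sig)
      est <- estimate_srt(m)
      tibble(lambda = lam, sigma_int = sig, seed = sd_i,
             srt = est$srt, flag = est$flag)
    }, error = function(e) {
      tibble(lambda = lam, sigma_int = sig, seed = sd_i,
             srt = NA_real_, flag = paste0("error: ", conditionMessage(e)))
    })
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ci_sweep", class(out))
  attr(out, "provenance") <- sweep_provenance(config, seeds)
  out
}

sweep_provenance <- function(config, seeds) {
  list(
    config_hash = rlang::hash(config[setdiff(names(config), "gain")]),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("cisrt")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
}

#' Median SRT and test-retest spread per sweep cell
#'
#' `srt_sd` is the standard deviation of the predicted SRT across seeds at a
#' fixed configuration - the model's test-retest spread.
#'
#' @param sweep A [run_sweep()] result.
#' @return Tibble with `lambda`, `sigma_int`, `srt_median`, `srt_sd`,
#'   `n_defined`.
#' @export
summarise_sweep <- function(sweep) {
  sweep |>
    dplyr::group_by(.data$lambda, .data$sigma_int) |>
    dplyr::summarise(
      srt_median = median(.data$srt, na.rm = TRUE),
      srt_sd = sd(.data$srt, na.rm = TRUE),
      n_defined = sum(is.finite(.data$srt)),
      .groups = "drop"
    )
}

#' Individualized SRT predictions for a participant cohort
#'
#' Predicts one SRT per participant with the pipeline individualized to the
#' chosen degree: internal noise mapped from TRT and/or AP
#' (`"sigma_trt"`, `"sigma_ap"`, `"sigma_both"`), spatial spread fitted from
#' per-participant EFI maps (`"spread_only"`), or both (`"full"`). Cohort
#' metrics (Pearson r, p, RMS error, bias = mean predicted minus measured)
#' are computed over participants with a defined predicted SRT; undefined
#' predictions are flagged and excluded.
#'
#' @param corpus A [synth_corpus()] result.
#' @param noise Noise waveform.
#' @param config A [ci_config()]; `config$lambda_mm` is the non-individualized
#'   spread, `config$sigma_int` the non-individualized internal noise.
#' @param participants Tibble with columns `id`, `trt`, `ap`, `srt`
#'   (measured).
#' @param efi_maps Named list of [efi_map()]s keyed by participant id
#'   (required for spread-individualized modes).
#' @param mode Individualization mode.
#' @param seed Integer seed.
#' @return A `ci_individualized` list: `predictions` tibble (per participant)
#'   and `evaluation` (one-row tibble from [srt_evaluation()]).
#' @export
run_individualized <- function(corpus, noise, config, participants,
                               efi_maps = NULL,
                               mode = c("sigma_trt", "sigma_ap", "sigma_both",
                                        "spread_only", "full"),
                               seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(participants)
  stopifnot(all(c("id", "srt") %in% names(participants)))
  sigmas <- switch(mode,
    sigma_trt = map_sigma(participants$trt),
    sigma_ap = map_sigma(participants$ap),
    sigma_both = combine_sigmas(map_sigma(participants$trt),
                                map_sigma(participants$ap)),
    spread_only = rep(config$sigma_int, n),
    full = combine_sigmas(map_sigma(participants$trt),
                          map_sigma(participants$ap))
  )
  use_efi <- mode %in% c("spread_only", "full")
  if (use_efi) {
    missing <- setdiff(participants$id, names(efi_maps %||% list()))
    if (length(missing)) {
      abort(paste0("EFI maps missing for: ", paste(missing, collapse = ", ")))
    }
  }
  rows <- purrr::map(seq_len(n), function(i) {
    id <- participants$id[i]
    profiles <- if (use_efi) {
      fit_efi_profiles(efi_maps[[id]], config$geometry)
    } else {
      idealized_profiles(config$geometry, config$lambda_mm)
    }
    res <- tryCatch({
      pre <- precompute_pipeline_irs(corpus, noise, config,
                                     seed = child_seed(seed, "part", i),
                                     profiles = profiles)
      m <- run_snr_matrix(corpus, noise, config,
                          precomputed = pre, sigma_int = sigmas[i])
      estimate_srt(m)
    }, error = function(e) {
      tibble(srt = NA_real_, criterion = 50,
             flag = paste0("error: ", conditionMessage(e)))
    })
    tibble(id = id, sigma_int = sigmas[i], srt_pred = res$srt,
           flag = res$flag, srt_measured = participants$srt[i])
  })
  predictions <- dplyr::bind_rows(rows)
  structure(
    list(
      predictions = predictions,
      evaluation = srt_evaluation(predictions$srt_pred,
                                  predictions$srt_measured),
      mode = mode,
      provenance = sweep_provenance(config, seed)
    ),
    class = "ci_individualized"
  )
}

#' @export
print.ci_individualized <- function(x, ...) {
  cat(sprintf("<ci_individualized> mode '%s', %d participants\n",
              x$mode, nrow(x$predictions)))
  print(x$evaluation)
  invisible(x)
}
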