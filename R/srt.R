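#' Precompute internal representations for a full SNR protocol
#'
#' Runs the front end for every (repetition, SNR, sentence) combination of
#' the protocol: each sentence is mixed with a random temporal passage of the
#' noise at the given SNR and pushed through ACE, spatial spread, the nerve
#' population and temporal integration. Internal noise is not applied, so one
#' precomputed set can be reused across internal-noise strengths.
#'
#' @param corpus A [synth_corpus()] result.
#' @param noise Noise waveform (e.g. [synth_noise()]).
#' @param config A [ci_config()].
#' @param seed Integer master seed (all stage seeds derive from it).
#' @param profiles Optional `spread_profile_set` (default idealized at
#'   `config$lambda_mm`).
#' @return A `pipeline_irs` object: sentences, raw IR features and bookkeeping.
#' @export
precompute_pipeline_irs <- function(corpus, noise, config, seed = 1,
                                    profiles = NULL) {
  profiles <- profiles %||% idealized_profiles(config$geometry,
                                               config$lambda_mm)
  gain <- config$gain %||%
    calibrate_pipeline_gain(corpus, config, profiles, seed = seed)
  prot <- config$protocol
  sent <- corpus_sentences(corpus, prot$n_sentences,
                           seed = child_seed(seed, "sentences"))
  irs <- vector("list", prot$repetitions)
  for (r in seq_len(prot$repetitions)) {
    irs[[r]] <- vector("list", length(prot$snr_grid))
    for (j in seq_along(prot$snr_grid)) {
      snr <- prot$snr_grid[j]
      irs[[r]][[j]] <- lapply(seq_len(nrow(sent)), function(i) {
        mixed <- mix_at_snr(sent$signal[[i]], noise, snr,
                            offset_seed = child_seed(seed, "mix", r, j, i))
        unclass(frontend_ir(mixed, config, profiles,
                            seed = child_seed(seed, "an", r, j, i),
                            gain = gain))
      })
    }
  }
  structure(
    list(sentences = sent, irs = irs, gain = gain, protocol = prot,
         config = config, seed = seed),
    class = "pipeline_irs"
  )
}

#' @export
print.pipeline_irs <- function(x, ...) {
  cat(sprintf(
    "<pipeline_irs> %d sentences x %d repetitions x %d SNRs (gain %.3g)\n",
    nrow(x$sentences), length(x$irs), length(x$protocol$snr_grid), x$gain
  ))
  invisible(x)
}

ir_features <- function(ir) t(ir) # frames x place-channels

#' Compute the training-SNR by testing-SNR word-score matrix
#'
#' For each training SNR, whole-word models are trained embedded on all
#' training repetitions at that SNR; the held-out repetition is decoded at
#' every testing SNR under the closed grammar, yielding a word-correct
#' percentage per (train, test) cell. Internal noise at `config$sigma_int`
#' (overridable) is applied to every internal representation before training
#' and testing.
#'
#' @param corpus A [synth_corpus()] result.
#' @param noise Noise waveform.
#' @param config A [ci_config()].
#' @param seed Integer master seed.
#' @param profiles Optional `spread_profile_set`.
#' @param precomputed Optional [precompute_pipeline_irs()] result to reuse.
#' @param sigma_int Internal-noise sd override.
#' @return A `score_matrix`: train x test matrix of word-correct % with
#'   attributes `snr_grid`, `protocol`, `sigma_int`, `seed`, `gain`.
#' @export
run_snr_matrix <- function(corpus, noise, config, seed = 1, profiles = NULL,
                           precomputed = NULL, sigma_int = NULL) {
  pre <- precomputed %||%
    precompute_pipeline_irs(corpus, noise, config, seed, profiles)
  sigma <- sigma_int %||% config$sigma_int
  prot <- pre$protocol
  sent <- pre$sentences
  n_snr <- length(prot$snr_grid)
  vocab <- corpus$vocabulary
  truth <- sent$words

  noisy <- lapply(seq_len(prot$repetitions), function(r) {
    lapply(seq_len(n_snr), function(j) {
      lapply(seq_len(nrow(sent)), function(i) {
        ir_features(apply_internal_noise(
          pre$irs[[r]][[j]][[i]], sigma,
          seed = child_seed(pre$seed, "int_noise", sigma, r, j, i)
        ))
      })
    })
  })
  train_reps <- seq_len(prot$repetitions - 1)
  test_rep <- prot$repetitions
  scores <- matrix(
    NA_real_, n_snr, n_snr,
    dimnames = list(train = prot$snr_grid, test = prot$snr_grid)
  )
  for (jt in seq_len(n_snr)) {
    feats <- unlist(lapply(train_reps, function(r) noisy[[r]][[jt]]),
                    recursive = FALSE)
    trans <- rep(truth, length(train_reps))
    models <- train_word_models(feats, trans, config$hmm,
                                vocabulary = unlist(vocab))
    for (je in seq_len(n_snr)) {
      rec <- recognize_sentences(models, noisy[[test_rep]][[je]], vocab,
                                 truth = truth)
      scores[jt, je] <- rec$word_correct_pct
    }
  }
  structure(scores,
            class = c("score_matrix", "matrix"),
            snr_grid = prot$snr_grid, protocol = prot,
            sigma_int = sigma, seed = pre$seed, gain = pre$gain)
}

#' Tidy a score matrix
#'
#' @param x A `score_matrix`.
#' @param ... Unused.
#' @return Tibble with `train_snr`, `test_snr`, `score`.
#' @export
tidy.score_matrix <- function(x, ...) {
  grid <- attr(x, "snr_grid")
  d <- tidyr::expand_grid(train_snr = grid, test_snr = grid)
  d$score <- as.numeric(unclass(x)[cbind(match(d$train_snr, grid),
                                         match(d$test_snr, grid))])
  d
}

#' Extract the speech reception threshold from a score matrix
#'
#' The envelope score at each testing SNR is the maximum over all training
#' SNRs ("best-matching training SNR"). The SRT is the linear interpolation
#' at the criterion between the lowest adjacent pair of testing SNRs whose
#' envelope brackets the criterion. If the envelope never reaches the
#' criterion the SRT is undefined (`NA`, flagged `"undefined"`); if the
#' envelope is already at criterion at the grid floor the SRT is the grid
#' floor, flagged `"at_grid_floor"`.
#'
#' @param score_matrix A [run_snr_matrix()] result (or plain matrix with an
#'   `snr_grid` attribute / `snr_grid` argument).
#' @param criterion Word-correct criterion in % (default 50).
#' @param snr_grid Testing SNR grid (taken from the attribute by default).
#' @return One-row tibble: `srt` (dB SNR or `NA`), `criterion`, `flag`.
#' @export
estimate_srt <- function(score_matrix, criterion = 50, snr_grid = NULL) {
  grid <- snr_grid %||% attr(score_matrix, "snr_grid")
  if (is.null(grid)) abort("no SNR grid available")
  if (is.unsorted(grid, strictly = TRUE)) abort("SNR grid must be sorted")
  env <- apply(unclass(score_matrix), 2, max)
  hit <- which(env >= criterion)
  if (!length(hit)) {
    return(tibble(srt = NA_real_, criterion = criterion, flag = "undefined"))
  }
  j <- hit[1]
  if (j == 1) {
    return(tibble(srt = grid[1], criterion = criterion,
                  flag = "at_grid_floor"))
  }
  s1 <- env[j - 1]; s2 <- env[j]
  srt <- grid[j - 1] + (criterion - s1) / (s2 - s1) * (grid[j] - grid[j - 1])
  tibble(srt = srt, criterion = criterion, flag = "ok")
}

#' Predict one SRT with the full pipeline
#'
#' Convenience wrapper: [run_snr_matrix()] followed by [estimate_srt()].
#'
#' @inheritParams run_snr_matrix
#' @param criterion Word-correct criterion in %.
#' @return A list with `srt` (the [estimate_srt()] tibble) and `matrix`.
#' @export
run_srt <- function(corpus, noise, config, seed = 1, profiles = NULL,
                    precomputed = NULL, sigma_int = NULL, criterion = 50) {
  m <- run_snr_matrix(corpus, noise, config, seed, profiles, precomputed,
                      sigma_int)
  list(srt = estimate_srt(m, criterion), matrix = m)
}
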