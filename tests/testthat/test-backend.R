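# synthetic feature-space corpus: each word is a distinct low-dimensional
# trajectory plus Gaussian noise; exercises training/decoding independent of
# the audio front end
synth_feature_sentences <- function(n_sent, vocab_per_slot, n_slots = 1,
                                    dim = 8, frames_per_word = 20,
                                    noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  vocab <- lapply(seq_len(n_slots), function(s) {
    sprintf("s%d_w%02d", s, seq_len(vocab_per_slot))
  })
  proto <- lapply(unlist(vocab), function(w) matrix(rnorm(2 * dim, 0, 2), 2))
  names(proto) <- unlist(vocab)
  sil_frames <- 8
  # balanced schedule guarantees every word occurs in training material
  schedule <- lapply(seq_len(n_slots), function(s) {
    unlist(lapply(seq_len(ceiling(n_sent / vocab_per_slot)), function(b) {
      vocab[[s]][sample.int(vocab_per_slot)]
    }))[seq_len(n_sent)]
  })
  make <- function(i) {
    words <- vapply(seq_len(n_slots), function(s) schedule[[s]][i], "")
    feats <- list(matrix(rnorm(sil_frames * dim, 0, noise_sd), sil_frames))
    for (w in words) {
      tr <- proto[[w]]
      frac <- seq(0, 1, length.out = frames_per_word)
      m <- (1 - frac) %o% tr[1, ] + frac %o% tr[2, ]
      feats <- c(feats, list(m + matrix(rnorm(length(m), 0, noise_sd),
                                        nrow(m))))
    }
    feats <- c(feats, list(matrix(rnorm(sil_frames * dim, 0, noise_sd),
                                  sil_frames)))
    list(words = words, feat = do.call(rbind, feats))
  }
  sents <- lapply(seq_len(n_sent), function(i) make(i))
  list(features = lapply(sents, `[[`, "feat"),
       transcripts = lapply(sents, `[[`, "words"),
       vocab = vocab)
}

test_that("embedded training is deterministic and covers the vocabulary", {
  sy <- synth_feature_sentences(20, 5, seed = 3)
  m1 <- train_word_models(sy$features, sy$transcripts, hmm_params(seed = 1),
                          vocabulary = unlist(sy$vocab))
  m2 <- train_word_models(sy$features, sy$transcripts, hmm_params(seed = 1),
                          vocabulary = unlist(sy$vocab))
  expect_identical(m1$models, m2$models)
  # one model per word plus silence
  expect_identical(sort(names(m1$models)), sort(c("sil", unlist(sy$vocab))))
  expect_identical(nrow(m1$models[["s1_w01"]]$mean), 6L)
  expect_identical(nrow(m1$models$sil$mean), 3L)
  # states of distinct words have distinct means
  mu1 <- m1$models[["s1_w01"]]$mean
  mu2 <- m1$models[["s1_w02"]]$mean
  expect_gt(min(sqrt(rowSums((mu1 - mu2)^2))), 0)
  # missing-word coverage errors with the absent words listed
  expect_error(
    train_word_models(sy$features[1:2], sy$transcripts[1:2],
                      vocabulary = c(unlist(sy$vocab), "s1_w99")),
    "s1_w99"
  )
})

test_that("matched decoding is near-perfect, shuffled labels are at chance", {
  sy <- synth_feature_sentences(60, 10, seed = 5)
  models <- train_word_models(sy$features, sy$transcripts,
                              vocabulary = unlist(sy$vocab))
  rec <- recognize_sentences(models, sy$features, sy$vocab,
                             truth = sy$transcripts)
  expect_gt(rec$word_correct_pct, 90)
  # every decoded sentence fills every slot
  expect_identical(nrow(rec$decoded), 60L * length(sy$vocab))
  expect_false(any(is.na(rec$decoded$decoded)))

  # label shuffling destroys the mapping: accuracy ~ chance = 10%. One
  # shuffle leaves a per-word lottery (quantized accuracy), so chance is
  # estimated over 20 shuffles decoding 25 fresh sentences each (500 words)
  sy2 <- synth_feature_sentences(100, 10, seed = 6)
  set.seed(9)
  correct <- integer(0)
  for (k in 1:20) {
    shuffled <- sy$transcripts[sample(length(sy$transcripts))]
    models_sh <- train_word_models(sy$features, shuffled,
                                   vocabulary = unlist(sy$vocab))
    idx <- sample(length(sy2$features), 25)
    rec_sh <- recognize_sentences(models_sh, sy2$features[idx], sy$vocab,
                                  truth = sy2$transcripts[idx])
    correct <- c(correct, rec_sh$decoded$correct)
  }
  expect_lt(abs(100 * mean(correct) - 10), 5)
})

test_that("multi-slot grammar decodes one word per slot in order", {
  sy <- synth_feature_sentences(30, 4, n_slots = 3, seed = 11)
  models <- train_word_models(sy$features, sy$transcripts,
                              vocabulary = unlist(sy$vocab))
  rec <- recognize_sentences(models, sy$features[1:10], sy$vocab,
                             truth = sy$transcripts[1:10])
  dec <- rec$decoded
  expect_identical(nrow(dec), 30L)
  # slot labels come from the slot's own vocabulary
  for (s in 1:3) {
    expect_true(all(dec$decoded[dec$slot == s] %in% sy$vocab[[s]]))
  }
  expect_gt(rec$word_correct_pct, 80)
})

test_that("SRT extraction interpolates the 50% iso-score envelope", {
  grid <- seq(-12, 3, by = 3)
  m <- matrix(10, 6, 6)
  # envelope rises through 50% between -3 dB (40%) and 0 dB (60%)
  m[3, ] <- c(10, 20, 30, 40, 60, 90)
  est <- estimate_srt(m, snr_grid = grid)
  expect_equal(est$srt, -1.5)
  expect_identical(est$flag, "ok")

  # never reaches criterion: undefined
  est2 <- estimate_srt(matrix(20, 6, 6), snr_grid = grid)
  expect_true(is.na(est2$srt))
  expect_identical(est2$flag, "undefined")

  # at criterion already at the grid floor: flagged floor
  est3 <- estimate_srt(matrix(100, 6, 6), snr_grid = grid)
  expect_equal(est3$srt, -12)
  expect_identical(est3$flag, "at_grid_floor")

  # the envelope is the max across training SNRs
  m4 <- matrix(0, 2, 3)
  m4[1, ] <- c(0, 60, 60); m4[2, ] <- c(60, 0, 0)
  est4 <- estimate_srt(m4, snr_grid = c(-6, -3, 0))
  expect_equal(est4$srt, -6)
  expect_identical(est4$flag, "at_grid_floor")
  expect_error(estimate_srt(m, snr_grid = c(0, -3, 3)), "sorted")
})

test_that("score matrices are well-formed on a miniature protocol", {
  corp <- tiny_corpus()
  noise <- tiny_noise()
  cfg <- ci_config("desk",
                   protocol = snr_protocol(c(-9, -3, 3), repetitions = 2,
                                           n_sentences = 20),
                   geometry = cochlea_geometry(n_fibers = 60))
  m <- run_snr_matrix(corp, noise, cfg, seed = 2)
  expect_identical(dim(unclass(m)), c(3L, 3L))
  expect_true(all(m >= 0 & m <= 100))
  td <- tidy(m)
  expect_identical(nrow(td), 9L)
  est <- estimate_srt(m)
  expect_true(est$flag %in% c("ok", "undefined", "at_grid_floor"))
})
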