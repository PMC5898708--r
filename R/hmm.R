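#' Whole-word HMM parameters
#'
#' Left-to-right whole-word hidden Markov models with a fixed number of states
#' per word, exactly one diagonal-covariance Gaussian per state, and
#' three-state start/stop silence models. Training is embedded (sentence
#' level): models are flat-started from a uniform segmentation and refined by
#' segmental Viterbi re-estimation under the known transcription, so no word
#' boundaries are ever supplied.
#'
#' @param states_per_word States per word model.
#' @param silence_states States of the silence model.
#' @param n_iter Segmental re-estimation iterations.
#' @param var_floor_frac Variance floor as a fraction of the global variance.
#'   The default is deliberately strong: with single-Gaussian states trained
#'   on few repetitions, maximum-likelihood variances are badly underestimated
#'   and the resulting overconfident models respond to estimation noise
#'   rather than to the input degradations under study; flooring at a
#'   substantial fraction of the global variance removes that pathology.
#' @param seed Integer seed (training is deterministic; the seed is recorded
#'   for provenance).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(states_per_word = 6, silence_states = 3, n_iter = 6,
                       var_floor_frac = 0.3, seed = 1) {
  stopifnot(states_per_word >= 1, silence_states >= 1, n_iter >= 1)
  structure(
    list(states_per_word = states_per_word, silence_states = silence_states,
         n_iter = n_iter, var_floor_frac = var_floor_frac, seed = seed),
    class = "hmm_params"
  )
}

# frames x states matrix of diagonal-Gaussian log densities
gaussian_loglik <- function(X, mu, var) {
  # X: T x D, mu/var: S x D
  const <- -0.5 * (ncol(X) * log(2 * pi) + rowSums(log(var)))
  quad <- X^2 %*% t(1 / (2 * var)) - X %*% t(mu / var) +
    matrix(rowSums(mu^2 / (2 * var)), nrow(X), nrow(mu), byrow = TRUE)
  sweep(-quad, 2, const, "+")
}

# state inventory of a model set: returns list(mu, var, log_self, log_adv,
# index) with index[[model]] = global state ids
model_inventory <- function(models) {
  mu <- do.call(rbind, lapply(models, `[[`, "mean"))
  var <- do.call(rbind, lapply(models, `[[`, "var"))
  ls <- unlist(lapply(models, `[[`, "log_self"))
  la <- unlist(lapply(models, `[[`, "log_adv"))
  sizes <- vapply(models, function(m) nrow(m$mean), integer(1))
  ends <- cumsum(sizes)
  index <- purrr::map2(ends - sizes + 1, ends, seq)
  names(index) <- names(models)
  list(mu = mu, var = var, log_self = ls, log_adv = la, index = index)
}

# chain of model names for an embedded transcription
transcript_chain <- function(words) c("sil", words, "sil")

# Viterbi forced alignment of one sentence to its transcription chain.
# Returns the frame -> (model, state-within-model) alignment.
align_chain <- function(feat, chain, inv) {
  state_ids <- unlist(inv$index[chain], use.names = FALSE)
  K <- length(state_ids)
  ll <- gaussian_loglik(feat, inv$mu[state_ids, , drop = FALSE],
                        inv$var[state_ids, , drop = FALSE])
  arcs_from <- c(seq_len(K), seq_len(K - 1))
  arcs_to <- c(seq_len(K), seq_len(K - 1) + 1L)
  arcs_lp <- c(inv$log_self[state_ids], inv$log_adv[state_ids[-K]])
  res <- viterbi_decode(ll, arcs_from, arcs_to, arcs_lp,
                        init_states = 1L, init_logp = 0,
                        final_states = K)
  chain_model <- rep(chain, vapply(inv$index[chain], length, integer(1)))
  chain_state <- unlist(lapply(inv$index[chain], seq_along), use.names = FALSE)
  list(model = chain_model[res$path], state = chain_state[res$path],
       logprob = res$logprob)
}

accumulate_stats <- function(acc, feat, model, state) {
  key <- paste(model, state, sep = "#")
  for (k in unique(key)) {
    rows <- which(key == k)
    Xk <- feat[rows, , drop = FALSE]
    if (is.null(acc[[k]])) {
      acc[[k]] <- list(n = 0, sum = 0, sumsq = 0, self = 0, adv = 0)
    }
    acc[[k]]$n <- acc[[k]]$n + nrow(Xk)
    acc[[k]]$sum <- acc[[k]]$sum + colSums(Xk)
    acc[[k]]$sumsq <- acc[[k]]$sumsq + colSums(Xk^2)
  }
  # transition counts: self when consecutive frames share (model, state)
  same <- key[-1] == key[-length(key)]
  for (k in unique(key)) {
    rows <- which(key[-length(key)] == k)
    acc[[k]]$self <- acc[[k]]$self + sum(same[rows])
    acc[[k]]$adv <- acc[[k]]$adv + sum(!same[rows])
  }
  acc
}

#' Train whole-word HMMs from sentence-level material
#'
#' Embedded training: each training sentence is aligned to the state chain
#' `silence + word models + silence` of its known transcription; Gaussian
#' means/variances and self/advance transition probabilities are re-estimated
#' from the alignment (segmental Viterbi training, flat-started from a
#' uniform segmentation). Deterministic given the inputs.
#'
#' @param features List of feature matrices (frames x dims), one per sentence.
#' @param transcripts List of character vectors (the words of each sentence).
#' @param params An [hmm_params()].
#' @param vocabulary Optional character vector of all words that must be
#'   covered; training errors listing absent words otherwise.
#' @return A `word_models` object: named list of word (and `sil`) models with
#'   `mean`, `var` (states x dims), `log_self`, `log_adv`.
#' @export
train_word_models <- function(features, transcripts, params = hmm_params(),
                              vocabulary = NULL) {
  stopifnot(length(features) == length(transcripts), length(features) >= 1)
  words_seen <- unique(unlist(transcripts))
  if (!is.null(vocabulary)) {
    missing <- setdiff(vocabulary, words_seen)
    if (length(missing)) {
      abort(paste0("no training material for: ",
                   paste(missing, collapse = ", ")))
    }
  }
  counts <- table(unlist(transcripts))
  if (length(features) >= 2 && any(counts < 2)) {
    warn("some words have fewer than 2 training occurrences")
  }
  D <- ncol(features[[1]])
  g_mean <- colMeans(do.call(rbind, features))
  g_var <- apply(do.call(rbind, features), 2, stats::var)
  g_var[g_var <= 0] <- 1e-6
  floor_var <- params$var_floor_frac * g_var

  n_states <- c(sil = params$silence_states,
                setNames(rep(params$states_per_word, length(words_seen)),
                         words_seen))
  # flat start: uniform segmentation of every sentence across its chain
  acc <- list()
  for (i in seq_along(features)) {
    chain <- transcript_chain(transcripts[[i]])
    sts <- unlist(lapply(chain, function(m) {
      paste(m, seq_len(n_states[[m]]), sep = "#")
    }))
    Tn <- nrow(features[[i]])
    assign_idx <- pmin(floor((seq_len(Tn) - 1) / Tn * length(sts)) + 1,
                       length(sts))
    ms <- do.call(rbind, strsplit(sts[assign_idx], "#", fixed = TRUE))
    acc <- accumulate_stats(acc, features[[i]], ms[, 1], as.integer(ms[, 2]))
  }
  models <- stats_to_models(acc, n_states, g_mean, g_var, floor_var)

  for (it in seq_len(params$n_iter)) {
    inv <- model_inventory(models)
    acc <- list()
    for (i in seq_along(features)) {
      al <- align_chain(features[[i]], transcript_chain(transcripts[[i]]), inv)
      acc <- accumulate_stats(acc, features[[i]], al$model, al$state)
    }
    models <- stats_to_models(acc, n_states, g_mean, g_var, floor_var)
  }
  structure(list(models = models, params = params, dims = D),
            class = "word_models")
}

stats_to_models <- function(acc, n_states, g_mean, g_var, floor_var) {
  models <- list()
  for (m in names(n_states)) {
    S <- n_states[[m]]
    mu <- matrix(rep(g_mean, each = S), S)
    va <- matrix(rep(g_var, each = S), S)
    self_p <- rep(0.6, S)
    for (s in seq_len(S)) {
      a <- acc[[paste(m, s, sep = "#")]]
      if (!is.null(a) && a$n > 0) {
        mu[s, ] <- a$sum / a$n
        if (a$n > 1) va[s, ] <- pmax(a$sumsq / a$n - mu[s, ]^2, floor_var)
        trans_n <- a$self + a$adv
        if (trans_n > 0) self_p[s] <- min(max(a$self / trans_n, 0.05), 0.95)
      } else {
        va[s, ] <- g_var
      }
    }
    models[[m]] <- list(mean = mu, var = va,
                        log_self = log(self_p), log_adv = log(1 - self_p))
  }
  models
}

#' @export
print.word_models <- function(x, ...) {
  cat(sprintf("<word_models> %d word models + silence, %d-dim features\n",
              length(x$models) - 1, x$dims))
  invisible(x)
}

# decoding graph for the closed grammar: sil, then per slot all candidate
# words in parallel, then sil; returns arcs and per-state (slot, word) labels
build_grammar_graph <- function(model_set, slots_vocab) {
  models <- model_set$models
  inv_states <- list() # global numbering while laying out instances
  labels <- list()
  arcs <- list(from = integer(), to = integer(), lp = numeric())
  add_arc <- function(f, t, lp) {
    arcs$from <<- c(arcs$from, f); arcs$to <<- c(arcs$to, t)
    arcs$lp <<- c(arcs$lp, lp)
  }
  nxt <- 0L
  lay <- function(model_name, slot, word) {
    m <- models[[model_name]]
    S <- nrow(m$mean)
    ids <- nxt + seq_len(S)
    nxt <<- nxt + S
    for (s in seq_len(S)) {
      add_arc(ids[s], ids[s], m$log_self[s])
      if (s < S) add_arc(ids[s], ids[s + 1], m$log_adv[s])
    }
    labels[[length(labels) + 1]] <<- tibble(
      state = ids, model = model_name, slot = slot, word = word,
      mstate = seq_len(S)
    )
    list(entry = ids[1], exit = ids[S], exit_lp = m$log_adv[S])
  }
  sil1 <- lay("sil", 0L, NA_character_)
  prev_exits <- list(list(exit = sil1$exit, lp = sil1$exit_lp))
  for (s in seq_along(slots_vocab)) {
    entries <- list()
    for (w in slots_vocab[[s]]) {
      if (is.null(models[[w]])) abort(paste0("no model for word ", w))
      node <- lay(w, s, w)
      for (pe in prev_exits) add_arc(pe$exit, node$entry, pe$lp)
      entries[[length(entries) + 1]] <- list(exit = node$exit,
                                             lp = node$exit_lp)
    }
    prev_exits <- entries
  }
  sil2 <- lay("sil", length(slots_vocab) + 1L, NA_character_)
  for (pe in prev_exits) add_arc(pe$exit, sil2$entry, pe$lp)
  lab <- dplyr::bind_rows(labels)
  list(arcs = arcs, labels = lab,
       init = sil1$entry, final = sil2$exit, n_states = nxt)
}

#' Recognize sentences under the closed matrix grammar
#'
#' Best-path Viterbi decoding of each sentence through the grammar
#' `silence - slot 1 word - ... - slot K word - silence`, where each slot
#' offers its full closed vocabulary. Word boundaries are found by the
#' decoder; nothing is segmented in advance. The score is the percentage of
#' presented words recognized in the correct slot.
#'
#' @param model_set A [train_word_models()] result.
#' @param features List of feature matrices (frames x dims), one per sentence.
#' @param slots_vocab List (one element per slot) of candidate word labels.
#' @param truth Optional list of true word vectors for scoring.
#' @return A list: `decoded` (tibble sentence x slot with decoded words, and
#'   `correct` when truth is given) and `word_correct_pct` (or `NA`).
#' @export
recognize_sentences <- function(model_set, features, slots_vocab,
                                truth = NULL) {
  if (ncol(features[[1]]) != model_set$dims) {
    abort("feature dimensionality does not match the trained models")
  }
  graph <- build_grammar_graph(model_set, slots_vocab)
  ord <- order(graph$labels$state)
  lab <- graph$labels[ord, ]
  mu <- do.call(rbind, purrr::map2(lab$model, lab$mstate, function(m, s) {
    model_set$models[[m]]$mean[s, , drop = FALSE]
  }))
  va <- do.call(rbind, purrr::map2(lab$model, lab$mstate, function(m, s) {
    model_set$models[[m]]$var[s, , drop = FALSE]
  }))
  n_slots <- length(slots_vocab)
  rows <- purrr::imap(features, function(feat, i) {
    ll <- gaussian_loglik(feat, mu, va)
    res <- viterbi_decode(ll, graph$arcs$from, graph$arcs$to, graph$arcs$lp,
                          init_states = graph$init, init_logp = 0,
                          final_states = graph$final)
    path_lab <- lab[res$path, ]
    dec <- character(n_slots)
    for (s in seq_len(n_slots)) {
      w <- unique(path_lab$word[path_lab$slot == s])
      dec[s] <- if (length(w) == 1) w else NA_character_
    }
    tibble(sentence = i, slot = seq_len(n_slots), decoded = dec,
           logprob = res$logprob)
  })
  decoded <- dplyr::bind_rows(rows)
  pct <- NA_real_
  if (!is.null(truth)) {
    decoded$truth <- unlist(truth)
    decoded$correct <- !is.na(decoded$decoded) &
      decoded$decoded == decoded$truth
    pct <- 100 * mean(decoded$correct)
  }
  list(decoded = decoded, word_correct_pct = pct)
}
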