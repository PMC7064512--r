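# Synthetic study generator: a Markov language with known next-word
# probabilities, cloze responders sampling from the true distribution,
# and gaze durations drawn from a known crossed-random-intercept model.
# Its role is to give every downstream stage a verifiable ground truth.

#' Build a generative toy language with known conditional probabilities
#'
#' The language is an order-`order` Markov chain over a synthetic
#' vocabulary of pronounceable consonant-vowel strings (lengths 1-12
#' letters, so length-based covariates vary). For every context length
#' k = 0..`order` and every context, the next-word distribution is an
#' independent draw from a symmetric Dirichlet with parameter
#' `concentration`: small values give peaked (highly predictable)
#' languages, large values give flat ones. Tokens near a text start use
#' the shorter-context tables, so the true predictability of *every*
#' sampled token is known exactly. The 10% most frequent words (by the
#' order-0 table) are designated stopwords for the embedding scorer's
#' without-stopwords option.
#'
#' @param vocab_size number of word types (>= 10).
#' @param order Markov order (0 = context-independent unigram language).
#' @param concentration positive Dirichlet parameter.
#' @param zipf_s Zipf exponent of the Dirichlet base weights: the
#'   Dirichlet parameter for word of frequency rank r is proportional
#'   to `concentration / r^zipf_s`, so word frequencies are Zipfian and
#'   frequent words carry genuinely higher conditional probabilities
#'   across contexts — the frequency/predictability covariation real
#'   lexicons show. `zipf_s = 0` gives the symmetric Dirichlet.
#' @param seed integer seed.
#' @param sent_mean,sent_min,sent_max sentence length distribution (words).
#' @return a `generative_language` with fields `vocabulary`, `order`,
#'   `cond_probs` (one row-stochastic matrix per context length, rows
#'   keyed by space-joined contexts), `sentence_length_dist`, `stopwords`.
#' @export
make_language <- function(vocab_size, order = 2L, concentration = 0.2,
                          zipf_s = 1, seed = 1L, sent_mean = 12,
                          sent_min = 3, sent_max = 30) {
  check_number(vocab_size, "vocab_size", min = 10)
  check_number(order, "order", min = 0)
  check_number(zipf_s, "zipf_s", min = 0)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration <= 0) {
    stop_param("`concentration` must be a positive real")
  }
  with_seed(seed, {
    vocab <- make_vocabulary(vocab_size)
    base <- (1 / seq_len(vocab_size)^zipf_s)
    shape <- vocab_size * concentration * base / sum(base)
    cond_probs <- vector("list", order + 1L)
    for (k in 0:order) {
      ctxs <- context_keys(vocab, k)
      cond_probs[[k + 1L]] <- rdirichlet_rows(length(ctxs), shape,
                                              list(ctxs, vocab))
    }
    unigram <- cond_probs[[1L]][1L, ]
    n_stop <- max(1L, floor(vocab_size * 0.10))
    stopwords <- names(sort(unigram, decreasing = TRUE))[seq_len(n_stop)]
    structure(list(vocabulary = vocab, order = as.integer(order),
                   cond_probs = cond_probs,
                   sentence_length_dist = list(mean = sent_mean,
                                               min = sent_min,
                                               max = sent_max),
                   concentration = concentration, seed = as.integer(seed),
                   stopwords = stopwords),
              class = "generative_language")
  })
}

# Dirichlet rows sampled in log space: log X for X ~ Gamma(a) is drawn
# as log Gamma(a + 1) + log(U) / a (an exact augmentation), which stays
# finite for the tiny shapes a peaked language needs, where plain rgamma
# underflows to 0. Zeros after normalization are clamped to the smallest
# positive double so every stored probability is positive.
rdirichlet_rows <- function(n, shape, dimnames) {
  V <- length(shape)
  g <- matrix(rgamma(n * V, shape = rep(shape + 1, each = n)), n, V)
  lx <- log(g) + log(matrix(runif(n * V), n, V)) / rep(shape, each = n)
  lx <- lx - apply(lx, 1L, max)
  m <- exp(lx)
  m[m == 0] <- .Machine$double.xmin
  m <- m / rowSums(m)
  dimnames(m) <- dimnames
  m
}

# unique CV-syllable word strings, lengths spread over 1..12 letters
make_vocabulary <- function(n) {
  cons <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t")
  vows <- c("a", "e", "i", "o", "u")
  words <- character(0)
  target_len <- rep(seq_len(12), length.out = n)
  while (length(words) < n) {
    k <- n - length(words)
    len <- target_len[seq_len(k)]
    cand <- vapply(len, function(L) {
      syl <- paste0(sample(cons, ceiling(L / 2), replace = TRUE),
                    sample(vows, ceiling(L / 2), replace = TRUE))
      substr(paste(syl, collapse = ""), 1L, L)
    }, character(1))
    words <- unique(c(words, cand))
  }
  sample(words[seq_len(n)])
}

context_keys <- function(vocab, k) {
  if (k == 0L) return("")
  grids <- rev(expand.grid(rep(list(vocab), k), stringsAsFactors = FALSE))
  do.call(paste, grids)
}

#' @export
print.generative_language <- function(x, ...) {
  cat(sprintf("<generative_language> |V|=%d, order %d, concentration %g\n",
              length(x$vocabulary), x$order, x$concentration))
  invisible(x)
}

# True conditional P(w | last min(j, order) words); contexts never cross
# text boundaries (position j is 0-based within text).
lang_prob_row <- function(lang, ctx_words) {
  k <- length(ctx_words)
  m <- lang$cond_probs[[k + 1L]]
  if (k == 0L) return(m[1L, ])
  m[paste(ctx_words, collapse = " "), ]
}

#' Sample a tokenized corpus from a generative language
#'
#' Draws `n_texts` documents of `words_per_text` tokens each from the
#' Markov chain (the chain state persists across sentence boundaries;
#' sentences only partition the layout). Every token is annotated with
#' its exact generative next-word probability `true_pred`.
#'
#' @param lang a `generative_language`.
#' @param n_texts,words_per_text corpus dimensions.
#' @param seed integer seed.
#' @param config tokenizer configuration (controls line wrapping).
#' @return a `tokenized_corpus` whose token table carries a `true_pred`
#'   column in (0, 1].
#' @export
sample_corpus <- function(lang, n_texts, words_per_text, seed = 1L,
                          config = tokenizer_config()) {
  check_number(n_texts, "n_texts", min = 1)
  check_number(words_per_text, "words_per_text", min = 0)
  V <- length(lang$vocabulary)
  # cumulative rows once per table for inverse-CDF sampling
  cums <- lapply(lang$cond_probs, function(m)
    matrix(apply(m, 1L, cumsum), ncol = nrow(m),
           dimnames = list(NULL, rownames(m))))
  with_seed(seed, {
    all_tok <- vector("list", n_texts)
    for (tx in seq_len(n_texts)) {
      n <- as.integer(words_per_text)
      if (n == 0L) {
        all_tok[[tx]] <- list(words = character(0), true_pred = numeric(0))
        next
      }
      idx <- integer(n); tp <- numeric(n)
      u <- runif(n)
      for (j in seq_len(n)) {
        k <- min(j - 1L, lang$order)
        col <- if (k == 0L) 1L else
          match(paste(lang$vocabulary[idx[(j - k):(j - 1L)]],
                      collapse = " "),
                colnames(cums[[k + 1L]]))
        cum <- cums[[k + 1L]][, col]
        idx[j] <- findInterval(u[j], cum) + 1L
        tp[j] <- lang$cond_probs[[k + 1L]][col, idx[j]]
      }
      all_tok[[tx]] <- list(words = lang$vocabulary[idx], true_pred = tp)
    }
    # carve into sentences and build documents
    texts <- character(n_texts)
    preds <- vector("list", n_texts)
    for (tx in seq_len(n_texts)) {
      w <- all_tok[[tx]]$words
      if (length(w) == 0L) { texts[tx] <- ""; preds[[tx]] <- numeric(0); next }
      lens <- sample_sentence_lengths(length(w), lang$sentence_length_dist)
      ends <- cumsum(lens)
      starts <- c(1L, head(ends, -1L) + 1L)
      sents <- vapply(seq_along(lens), function(s)
        paste0(paste(w[starts[s]:ends[s]], collapse = " "), "."), character(1))
      texts[tx] <- paste(sents, collapse = " ")
      preds[[tx]] <- all_tok[[tx]]$true_pred
    }
    corpus <- tokenize_corpus(texts, config)
    corpus$tokens[, true_pred := unlist(preds)]
    corpus
  })
}

sample_sentence_lengths <- function(n_words, dist) {
  lens <- integer(0); total <- 0L
  while (total < n_words) {
    L <- round(rnorm(1L, dist$mean, dist$mean / 3))
    L <- as.integer(min(max(L, dist$min), dist$max))
    L <- min(L, n_words - total)
    lens <- c(lens, L); total <- total + L
  }
  lens[lens > 0L]
}

#' Simulate cloze-task responses with known ground truth
#'
#' Each of `responses_per_word` simulated responders guesses the token
#' from the mixture `(1 - guess_noise) * P(w | context) + guess_noise *
#' uniform`, where `P` is the generative conditional actually used to
#' sample that token. `guess_noise = 0` gives responders with perfect
#' knowledge of the language; `guess_noise = 1` gives uniform guessing.
#'
#' @param lang a `generative_language`.
#' @param corpus a corpus sampled from `lang` (needs `true_pred` tokens).
#' @param responses_per_word responders per token (>= 1).
#' @param guess_noise mixture weight in \[0, 1\].
#' @param seed integer seed.
#' @return a cloze response table `(text_id, token_idx, response)`.
#' @export
sample_cloze_responses <- function(lang, corpus, responses_per_word,
                                   guess_noise = 0, seed = 1L) {
  check_number(responses_per_word, "responses_per_word", min = 1)
  check_number(guess_noise, "guess_noise", min = 0, max = 1)
  tok <- corpus$tokens
  V <- length(lang$vocabulary)
  with_seed(seed, {
    out <- vector("list", nrow(tok))
    word_idx <- match(tok$norm, lang$vocabulary)
    if (anyNA(word_idx)) stop_param("corpus contains words outside the language")
    for (i in seq_len(nrow(tok))) {
      j <- tok$tok_text[i]                       # 0-based within text
      k <- min(j, lang$order)
      ctx <- if (k == 0L) character(0) else tok$norm[(i - k):(i - 1L)]
      p <- (1 - guess_noise) * lang_prob_row(lang, ctx) + guess_noise / V
      counts <- as.vector(rmultinom(1L, responses_per_word, p))
      out[[i]] <- data.table(text_id = tok$text_id[i],
                             token_idx = j,
                             response = rep(lang$vocabulary, counts))
    }
    rbindlist(out)
  })
}

#' Gaze-generation configuration
#'
#' Coefficients of the generative model for log gaze duration: a linear
#' predictor over centered covariates (`launch_site`, `length`, `freq`,
#' `length:freq`, `rpl`, `rpt`, `rps`, `pred_n`, `pred_n1` plus
#' `(Intercept)`), Gaussian random intercepts for subject, text and word
#' token, and a Gaussian residual. Unnamed coefficients default to 0.
#'
#' @param beta named numeric vector of fixed-effect coefficients.
#' @param sigma_subj,sigma_text,sigma_word,sigma_resid nonnegative SDs.
#' @param n_subjects number of simulated readers (>= 2).
#' @param texts_per_subject number of texts each reader reads (`NULL` =
#'   all texts), assigned pseudo-randomly as in a reading study.
#' @param skip_prob_fn function(pred_centered, length_letters) returning
#'   per-token skip probabilities; the default skips short, predictable
#'   words more often, purely to create realistic missingness.
#' @param length_inverse use 1/length as the `length` covariate.
#' @param seed integer seed.
#' @return a `gaze_config` list.
#' @export
gaze_config <- function(beta = default_gaze_beta(),
                        sigma_subj = 0.15, sigma_text = 0.05,
                        sigma_word = 0.08, sigma_resid = 0.35,
                        n_subjects = 30L, texts_per_subject = NULL,
                        skip_prob_fn = default_skip_prob,
                        length_inverse = TRUE, seed = 1L) {
  for (nm in c("sigma_subj", "sigma_text", "sigma_word", "sigma_resid")) {
    check_number(get(nm), nm, min = 0)
  }
  check_number(n_subjects, "n_subjects", min = 2)
  structure(list(beta = beta, sigma_subj = sigma_subj,
                 sigma_text = sigma_text, sigma_word = sigma_word,
                 sigma_resid = sigma_resid,
                 n_subjects = as.integer(n_subjects),
                 texts_per_subject = texts_per_subject,
                 skip_prob_fn = skip_prob_fn,
                 length_inverse = isTRUE(length_inverse),
                 seed = as.integer(seed)),
            class = "gaze_config")
}

#' @rdname gaze_config
#' @export
default_gaze_beta <- function() {
  c("(Intercept)" = 5.50, launch_site = 0.010, length = -0.30,
    freq = -0.030, "length:freq" = 0.020, rpl = -0.050, rpt = -0.100,
    rps = 0.030, pred_n = -0.030, pred_n1 = -0.010)
}

#' @rdname gaze_config
#' @export
default_skip_prob <- function(pred_centered, length_letters) {
  plogis(-1.2 + 0.30 * pred_centered - 0.20 * (length_letters - 5))
}

#' Simulate first-pass gaze durations from a known mixed model
#'
#' For every subject and every non-skipped token, the log gaze duration
#' is the configured linear predictor over centered covariates plus
#' subject, text and word-token random intercepts plus Gaussian noise;
#' durations are returned in milliseconds. Skipping is an independent
#' Bernoulli per subject x token; the launch site is the length of the
#' previous fixated word plus unit-Gaussian jitter.
#'
#' @param corpus a `tokenized_corpus`.
#' @param features its [compute_features()] table.
#' @param pred_n,pred_n1 numeric vectors aligned to the corpus tokens
#'   (typically logit predictability of the token and of the next token;
#'   `NA` entries contribute 0 to the linear predictor).
#' @param cfg a [gaze_config()].
#' @return a fixation table `(subj_id, text_id, token_idx, dur_ms,
#'   launch_site)` with an attribute `truth` recording the coefficients
#'   and SDs used.
#' @export
sample_gaze <- function(corpus, features, pred_n, pred_n1, cfg) {
  tok <- corpus$tokens
  n <- nrow(tok)
  if (length(pred_n) != n || length(pred_n1) != n) {
    stop_param("pred vectors must align with the corpus tokens (",
               n, " tokens)")
  }
  stopifnot(nrow(features) == n)
  len_cov <- if (cfg$length_inverse) features$inv_length else features$length
  ctr <- function(x) x - mean(x, na.rm = TRUE)
  X <- data.table(length = ctr(len_cov), freq = ctr(features$log_freq),
                  rpl = ctr(features$rpl), rpt = ctr(features$rpt),
                  rps = ctr(features$rps),
                  pred_n = ctr(pred_n), pred_n1 = ctr(pred_n1))
  X[, `length:freq` := length * freq]
  beta <- cfg$beta
  bval <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  base_lp <- bval("(Intercept)")
  for (nm in setdiff(names(X), "launch_site")) {
    v <- X[[nm]]
    v[is.na(v)] <- 0
    base_lp <- base_lp + bval(nm) * v
  }
  text_ids <- sort(unique(tok$text_id))
  with_seed(cfg$seed, {
    u_subj <- rnorm(cfg$n_subjects, 0, cfg$sigma_subj)
    u_text <- setNames(rnorm(length(text_ids), 0, cfg$sigma_text), text_ids)
    u_word <- rnorm(n, 0, cfg$sigma_word)
    p_skip <- cfg$skip_prob_fn(ctr(ifelse(is.na(pred_n), 0, pred_n)),
                               features$length)
    rows <- vector("list", cfg$n_subjects)
    for (s in seq_len(cfg$n_subjects)) {
      read_texts <- if (is.null(cfg$texts_per_subject)) text_ids else
        sort(sample(text_ids, min(cfg$texts_per_subject, length(text_ids))))
      keep <- tok$text_id %in% read_texts &
        runif(n) >= p_skip
      idx <- which(keep)
      if (length(idx) == 0L) next
      # launch site: previous fixated word's length + jitter, per text
      prev_len <- numeric(length(idx))
      dtx <- data.table(i = idx, text = tok$text_id[idx],
                        len = features$length[idx])
      dtx[, prev_len := shift(len, fill = 0), by = text]
      ls <- dtx$prev_len + rnorm(length(idx))
      rows[[s]] <- data.table(subj_id = s, text_id = tok$text_id[idx],
                              token_idx = tok$tok_text[idx], i = idx,
                              launch_site = ls)
    }
    fx <- rbindlist(rows)
    ls_c <- fx$launch_site - mean(fx$launch_site)
    lp <- base_lp[fx$i] + bval("launch_site") * ls_c +
      u_subj[fx$subj_id] + u_text[as.character(fx$text_id)] +
      u_word[fx$i] + rnorm(nrow(fx), 0, cfg$sigma_resid)
    fx[, dur_ms := exp(lp)]
    fx[, i := NULL]
    setcolorder(fx, c("subj_id", "text_id", "token_idx", "dur_ms",
                      "launch_site"))
    structure(fx[], truth = list(beta = beta,
                                 sigma = c(subj = cfg$sigma_subj,
                                           text = cfg$sigma_text,
                                           word = cfg$sigma_word,
                                           resid = cfg$sigma_resid)))
  })
}
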