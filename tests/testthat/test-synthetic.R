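test_that("language construction obeys its probability invariants", {
  lang <- make_language(12, 2, 0.3, seed = 3)
  for (m in lang$cond_probs) {
    expect_true(all(m >= 0))
    expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  }
  expect_length(lang$cond_probs, 3L)   # context lengths 0, 1, 2
  expect_equal(nrow(lang$cond_probs[[3]]), 144L)
  expect_length(lang$vocabulary, 12L)
  expect_true(all(lang$stopwords %in% lang$vocabulary))
  expect_error(make_language(12, 2, 0), "positive")
  expect_error(make_language(5, 2, 0.3), "vocab_size")
})

test_that("order-0 language is context-independent", {
  lang <- make_language(10, 0, 0.5, seed = 1)
  expect_length(lang$cond_probs, 1L)
  co <- sample_corpus(lang, 1, 500, seed = 2)
  uni <- lang$cond_probs[[1]][1, ]
  expect_equal(co$tokens$true_pred,
               unname(uni[co$tokens$norm]))
})

test_that("vanishing concentration approaches a one-hot language", {
  lang <- make_language(15, 2, 1e-4, seed = 5)
  co <- sample_corpus(lang, 1, 400, seed = 6)
  expect_gt(mean(co$tokens$true_pred), 0.98)
})

test_that("conditional entropies match an independent recomputation", {
  lang <- make_language(200, 2, 0.1, seed = 7)
  m <- lang$cond_probs[[3]]
  h_vectorized <- -rowSums(m * log(m))
  idx <- c(1L, 57L, 4000L, nrow(m))
  for (i in idx) {
    h_direct <- 0
    for (p in m[i, ]) h_direct <- h_direct - p * log(p)
    expect_equal(h_vectorized[[i]], h_direct, tolerance = 1e-12)
  }
  expect_true(all(h_vectorized >= 0))
})

test_that("sampled corpora carry exact generative predictabilities", {
  lang <- make_language(20, 2, 0.15, seed = 7)
  expect_equal(nrow(sample_corpus(lang, 1, 0, seed = 1)$tokens), 0L)
  co <- sample_corpus(lang, 3, 250, seed = 1)
  tok <- co$tokens
  expect_true(all(tok$true_pred > 0 & tok$true_pred <= 1))
  # spot-check against direct table lookup
  for (i in c(1L, 2L, 100L, nrow(tok))) {
    k <- min(tok$tok_text[i], lang$order)
    ctx <- if (k == 0) character(0) else tok$norm[(i - k):(i - 1)]
    expect_equal(tok$true_pred[i],
                 unname(gazepred:::lang_prob_row(lang, ctx)[tok$norm[i]]))
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  lang <- make_language(15, 2, 0.2, seed = 9)
  a <- sample_corpus(lang, 2, 150, seed = 4)
  b <- sample_corpus(lang, 2, 150, seed = 4)
  expect_identical(a$tokens, b$tokens)
  ra <- sample_cloze_responses(lang, a, 10, 0.2, seed = 5)
  rb <- sample_cloze_responses(lang, b, 10, 0.2, seed = 5)
  expect_identical(ra, rb)
  f <- compute_features(a, build_frequency_table(a))
  tl <- true_logits(a)
  cfg <- gaze_config(n_subjects = 4, seed = 6)
  expect_identical(
    as.data.frame(sample_gaze(a, f, tl$n, tl$n1, cfg)),
    as.data.frame(sample_gaze(a, f, tl$n, tl$n1, cfg)))
})

test_that("empirical trigram frequencies converge to the conditionals", {
  lang <- make_language(15, 2, 0.15, seed = 11)
  co <- sample_corpus(lang, 2, 50000, seed = 12)
  w <- co$tokens$norm
  dt <- data.table::data.table(ctx = paste(head(w, -2), head(w[-1], -1)),
                               w = tail(w, -2))
  cnt <- dt[, .N, by = .(ctx, w)]
  cnt[, ctx_n := sum(N), by = ctx]
  big <- cnt[ctx_n >= 500]
  expect_gt(nrow(big), 10)
  truth <- lang$cond_probs[[3]][cbind(big$ctx, big$w)]
  expect_lt(mean(abs(big$N / big$ctx_n - truth)), 0.02)
})

test_that("uniform guessing and perfect knowledge bound the cloze responses", {
  lang <- make_language(12, 2, 0.1, seed = 13)
  co <- sample_corpus(lang, 1, 100, seed = 14)
  ru <- sample_cloze_responses(lang, co, 200, guess_noise = 1, seed = 15)
  correct <- merge(ru, co$tokens[, .(text_id, token_idx = tok_text, norm)],
                   by = c("text_id", "token_idx"))
  acc <- mean(correct$response == correct$norm)
  expect_lt(abs(acc - 1 / 12), 3 * sqrt((1 / 12) * (11 / 12) / nrow(correct)))

  onehot <- make_language(12, 2, 1e-5, seed = 16)
  co2 <- sample_corpus(onehot, 1, 100, seed = 17)
  r0 <- sample_cloze_responses(onehot, co2, 5, guess_noise = 0, seed = 18)
  correct2 <- merge(r0, co2$tokens[, .(text_id, token_idx = tok_text, norm)],
                    by = c("text_id", "token_idx"))
  expect_gt(mean(correct2$response == correct2$norm), 0.999)
})

test_that("gaze durations reproduce the linear predictor exactly when noiseless", {
  study <- fixture_study(n_texts = 2, words = 120)
  tl <- true_logits(study$test)
  beta <- c("(Intercept)" = 5, launch_site = 0, length = 0, freq = 0,
            "length:freq" = 0, rpl = 0, rpt = 0, rps = 0,
            pred_n = 0, pred_n1 = 0)
  cfg <- gaze_config(beta = beta, sigma_subj = 0, sigma_text = 0,
                     sigma_word = 0, sigma_resid = 0, n_subjects = 3,
                     seed = 21)
  fx <- sample_gaze(study$test, study$features, tl$n, tl$n1, cfg)
  expect_equal(fx$dur_ms, rep(exp(5), nrow(fx)))

  beta2 <- beta
  beta2[c("length", "freq", "pred_n")] <- c(-0.4, -0.05, -0.03)
  cfg2 <- gaze_config(beta = beta2, sigma_subj = 0, sigma_text = 0,
                      sigma_word = 0, sigma_resid = 0, n_subjects = 3,
                      seed = 22)
  fx2 <- sample_gaze(study$test, study$features, tl$n, tl$n1, cfg2)
  # independent recomputation of the linear predictor
  f <- study$features
  key <- paste(study$test$tokens$text_id, study$test$tokens$tok_text)
  i <- match(paste(fx2$text_id, fx2$token_idx), key)
  ctr <- function(x) x - mean(x, na.rm = TRUE)
  pn <- ctr(tl$n)[i]
  lp <- 5 - 0.4 * ctr(f$inv_length)[i] - 0.05 * ctr(f$log_freq)[i] -
    0.03 * ifelse(is.na(pn), 0, pn)
  expect_equal(log(fx2$dur_ms), lp, tolerance = 1e-12)
})

test_that("a negative predictability coefficient shows in the sampled gaze", {
  lang <- make_language(25, 2, 0.1, seed = 31)
  co <- sample_corpus(lang, 1, 10000, seed = 32)
  f <- compute_features(co, build_frequency_table(co))
  tl <- true_logits(co)
  beta <- c("(Intercept)" = 5.5, pred_n = -0.05)
  cfg <- gaze_config(beta = beta, sigma_subj = 0, sigma_text = 0,
                     sigma_word = 0, sigma_resid = 0.2, n_subjects = 2,
                     seed = 33)
  fx <- sample_gaze(co, f, tl$n, tl$n1, cfg)
  i <- match(paste(fx$text_id, fx$token_idx),
             paste(co$tokens$text_id, co$tokens$tok_text))
  expect_lt(cor(tl$n[i], log(fx$dur_ms)), 0)
})

test_that("misaligned predictability vectors are rejected", {
  study <- fixture_study(n_texts = 2, words = 50)
  tl <- true_logits(study$test)
  cfg <- gaze_config(n_subjects = 2, seed = 1)
  expect_error(
    sample_gaze(study$test, study$features, tl$n[-1], tl$n1, cfg),
    "align")
})
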