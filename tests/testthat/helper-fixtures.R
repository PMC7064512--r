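# Shared small fixtures, built in code at test time.

# corpus whose surface text round-trips through the tokenizer
fixture_corpus <- function(texts = c("uno dos tres cuatro cinco. uno dos.",
                                     "tres cuatro. cinco seis siete ocho.")) {
  tokenize_corpus(texts)
}

# a small study: language, test corpus, training corpus, features
fixture_study <- function(vocab = 30, conc = 0.12, seed = 7,
                          n_texts = 4, words = 300,
                          train_texts = 12, train_words = 2000) {
  lang <- make_language(vocab, 2, conc, seed = seed)
  test_corpus <- sample_corpus(lang, n_texts, words, seed = seed + 1)
  train_corpus <- sample_corpus(lang, train_texts, train_words,
                                seed = seed + 2)
  freq <- build_frequency_table(train_corpus)
  list(lang = lang, test = test_corpus, train = train_corpus,
       freq = freq, features = compute_features(test_corpus, freq))
}

# true logit predictability for word N and word N+1, aligned to tokens
true_logits <- function(corpus) {
  tl <- logit(corpus$tokens$true_pred)
  tl1 <- c(tl[-1], NA)
  tl1[diff(c(corpus$tokens$text_id, Inf)) != 0] <- NA
  list(n = tl, n1 = tl1)
}

# residual-scale white noise aligned with a model frame
with_white_noise <- function(frame, seed) {
  set.seed(seed)
  rnorm(nrow(frame), 0, sd(frame$y))
}
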