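test_that("additive cache smoothing matches its closed form", {
  cache <- new_cache(delta = 0, base_vocab = letters[1:5])
  cache <- cache_add(cache, c("a", "a", "b", rep("c", 7)))
  expect_equal(p_cache(cache, "a"), 0.2)   # MLE when delta = 0

  cache2 <- new_cache(delta = 0.5, base_vocab = c("a", "b", "c", "d"))
  cache2 <- cache_add(cache2, c(rep("a", 3), rep("b", 7)))
  expect_equal(p_cache(cache2, "a"), 3.5 / 12, tolerance = 1e-12)
  expect_equal(p_cache(cache2, "a"), 0.29167, tolerance = 1e-4)

  # empty cache is uniform over the vocabulary
  cache3 <- new_cache(delta = 0.00015, base_vocab = paste0("w", 1:1000))
  expect_equal(p_cache(cache3, "w1"), 0.001, tolerance = 1e-12)

  cache4 <- new_cache(delta = 0, base_vocab = letters[1:3])
  expect_error(p_cache(cache4, "a"), "degenerate")
})

test_that("the cache vocabulary absorbs novel in-text words", {
  cache <- new_cache(delta = 0.1, base_vocab = c("a", "b"))
  cache <- cache_add(cache, c("a", "zz"))
  # V grows to 3: base vocab plus the novel word
  expect_equal(p_cache(cache, "zz"), 1.1 / (0.1 * 3 + 2))
})

test_that("linear interpolation matches its closed form and bounds", {
  expect_equal(p_combined(0, 0.2, 0.1), 0.1)
  expect_equal(p_combined(1, 0.2, 0.1), 0.2)
  expect_equal(p_combined(0.15, 0.2, 0.1), 0.115, tolerance = 1e-12)
  expect_error(p_combined(1.5, 0.2, 0.1), "lambda")
  expect_error(p_combined(-0.1, 0.2, 0.1), "lambda")
})

test_that("good-turing discounts follow (r+1) N_{r+1} / N_r with fallbacks", {
  coc <- data.table::data.table(r = c(1, 2), N = c(3, 1))
  expect_equal(gazepred:::gt_discount(c(1, 2), coc, 5),
               c(2 * 1 / 3, 2))          # N_3 missing: r = 2 undiscounted
  expect_equal(gazepred:::gt_discount(1, coc, 5), 0.6667, tolerance = 1e-4)
  coc2 <- data.table::data.table(r = c(1, 2, 7), N = c(10, 4, 1))
  d <- gazepred:::gt_discount(c(1, 2, 7), coc2, 5)
  expect_equal(d[1], 2 * 4 / 10)
  expect_equal(d[3], 7)                  # above gt_max_r: untouched
  expect_true(all(d <= c(1, 2, 7)))      # discounting removes mass
})

test_that("a unigram model is maximum likelihood", {
  co <- tokenize_corpus("a a b.")
  m <- train_ngram(co, 1)
  expect_equal(p_ngram(m, "a"), 2 / 3)
  expect_equal(p_ngram(m, "b"), 1 / 3)
})

test_that("katz probabilities match the brute-force oracle exactly", {
  # 3-word vocabulary, 20 tokens, repeated and unseen patterns
  sents <- list(c("a", "b", "a"), c("b", "c", "a", "b"),
                c("a", "b", "c", "a"), c("c", "c", "a"),
                c("b", "a", "b", "a", "c", "b"))
  txt <- paste(vapply(sents, paste, "", collapse = " "), ".",
               sep = "", collapse = " ")
  co <- tokenize_corpus(txt)
  for (n_order in 2:3) {
    m <- train_ngram(co, n_order)
    om <- oracle_katz_model(sents, n_order)
    ctxs <- list(character(0), "a", "b", "c",
                 c("a", "b"), c("b", "a"), c("c", "c"), c("a", "c"),
                 c("<s>", "a"), c("<s>", "<s>"))
    for (ctx in ctxs) {
      use <- if (length(ctx) > n_order - 1)
        tail(ctx, n_order - 1) else ctx
      dist <- p_ngram_dist(m, ctx)
      for (w in c("a", "b", "c")) {
        # pad as the model does, then consult the oracle
        padded <- if (length(use) < n_order - 1)
          c(rep("<s>", n_order - 1 - length(use)), use) else use
        expect_equal(p_ngram(m, w, ctx),
                     oracle_katz_p(om, w, padded),
                     tolerance = 1e-12)
        expect_equal(unname(dist[w]), p_ngram(m, w, ctx),
                     tolerance = 1e-12)
      }
      expect_equal(sum(dist), 1, tolerance = 1e-8)
    }
  }
})

test_that("high-count n-grams are undiscounted count ratios", {
  sents <- rep("x y z w.", 10)               # the 4-gram occurs 10 times
  co <- tokenize_corpus(paste(sents, collapse = " "))
  m <- train_ngram(co, 4)
  expect_equal(p_ngram(m, "w", c("x", "y", "z")), 1)
  # entirely unseen context backs off all the way to the unigram MLE
  # (an empty context, by contrast, means sentence start and is padded)
  expect_equal(p_ngram(m, "x", c("w", "w", "w")), 10 / 40)
})

test_that("every context distribution is normalized on a sampled corpus", {
  lang <- make_language(12, 2, 0.2, seed = 51)
  co <- sample_corpus(lang, 2, 400, seed = 52)
  m <- train_ngram(co, 3)
  V <- lang$vocabulary
  set.seed(53)
  some_ctx <- c(list(character(0)),
                lapply(1:12, function(i) sample(V, 2, replace = TRUE)),
                lapply(1:5, function(i) sample(V, 1)))
  for (ctx in some_ctx) {
    expect_equal(sum(p_ngram_dist(m, ctx)), 1, tolerance = 1e-8)
  }
})

test_that("score_text implements score-then-update cache over running text", {
  tr <- tokenize_corpus(c("a b c d. b c a. q.", "d c b a. a b."))
  m <- train_ngram(tr, 2)
  co <- tokenize_corpus("a b a b zz.")
  expect_error(score_text(m, co, 0.001, 0.15), "out-of-vocabulary")
  m2 <- train_ngram(tr, 2, unk_singletons = TRUE)  # "q" becomes <unk>
  s <- score_text(m2, co, 0.001, 0.15)
  V0 <- length(m2$vocab)
  # first token: empty cache, uniform 1/V
  expect_equal(s$p_cache[1], 1 / V0)
  # third token "a": cache = {a, b}, count 1, N = 2
  expect_equal(s$p_cache[3], (1 + 0.001) / (0.001 * V0 + 2))
  # novel word "zz": maps to <unk> for the n-gram, enters V for the cache
  expect_equal(s$p_cache[5], 0.001 / (0.001 * (V0 + 0) + 4))
  # lambda = 0 reduces to the pure n-gram
  s0 <- score_text(m2, co, 0.001, 0)
  expect_equal(s0$p_combined, s0$p_ngram)
  # scalar scoring agrees with the vectorized path
  expect_equal(s0$p_ngram[4], p_ngram(m2, "b", c("a", "b", "a")))
  # repeated-word cache boost for small delta
  expect_gt(s$p_combined[3], s0$p_combined[3])
})

test_that("the cache never lets a word predict itself", {
  tr <- tokenize_corpus("a b. b a.")
  m <- train_ngram(tr, 2)
  co <- tokenize_corpus("a a.")
  s <- score_text(m, co, 0.001, 0.5)
  # second "a" sees a cache containing only the first "a"
  expect_equal(s$p_cache[2], (1 + 0.001) / (0.001 * length(m$vocab) + 1))
  # first "a" sees an empty cache: its own occurrence is not counted
  expect_equal(s$p_cache[1], 1 / length(m$vocab))
})

test_that("grid search reports the full grid and a sensible argmax", {
  study <- fixture_study(n_texts = 2, words = 200)
  m <- train_ngram(study$train, 3)
  tl <- logit(study$test$tokens$true_pred)
  ev <- function(p, corpus) cor(log(p), tl)
  one <- grid_search(m, study$test, ev, delta_grid = 2e-4,
                     lambda_grid = 0.15)
  expect_equal(nrow(one), 1L)
  expect_equal(attr(one, "best")$lambda, 0.15)
  expect_error(grid_search(m, study$test, ev, numeric(0), 0.1),
               "non-empty")

  g <- grid_search(m, study$test, ev, delta_grid = c(5e-05, 1.5e-4, 5e-4),
                   lambda_grid = c(0.05, 0.15, 0.3, 0.6))
  expect_equal(nrow(g), 12L)
  # the published optimum lies inside the default searched grids
  d_grid <- eval(formals(grid_search)$delta_grid)
  l_grid <- eval(formals(grid_search)$lambda_grid)
  expect_true(min(d_grid) <= 0.00015 && 0.00015 <= max(d_grid))
  expect_true(min(l_grid) <= 0.15 && 0.15 <= max(l_grid))
  # grid values match scoring done by hand from the parts
  s <- score_text(m, study$test, 5e-05, 0.05)
  expect_equal(g$criterion[g$delta == 5e-05 & g$lambda == 0.05],
               ev(s$p_combined, study$test))
})

test_that("arpa files round-trip the model", {
  dir <- withr::local_tempdir()
  lang <- make_language(12, 2, 0.2, seed = 61)
  co <- sample_corpus(lang, 2, 300, seed = 62)
  m <- train_ngram(co, 3)
  p <- file.path(dir, "model.arpa")
  write_arpa(m, p)
  m2 <- read_arpa(p)
  expect_equal(m2$order, 3L)
  expect_equal(m2$vocab, m$vocab)
  test <- sample_corpus(lang, 1, 150, seed = 63)
  s1 <- score_text(m, test, 1e-4, 0.15)
  s2 <- score_text(m2, test, 1e-4, 0.15)
  expect_equal(s2$p_combined, s1$p_combined, tolerance = 1e-6)
  for (ctx in list(character(0), lang$vocabulary[1:2])) {
    expect_equal(sum(p_ngram_dist(m2, ctx)), 1, tolerance = 1e-5)
  }
})
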