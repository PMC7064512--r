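# Katz back-off N-gram language model with Good-Turing discounting, the
# additively smoothed in-text cache unigram, and their linear
# interpolation. The back-off model is trained on an independent corpus;
# the cache sees only the text previously read, so the combined score is
# a running-text predictability estimate.

S_TOKEN <- "<s>"
UNK_TOKEN <- "<unk>"

#' Train a Katz back-off N-gram model
#'
#' Counts k-grams for k = 1..`n_order` over sentence-padded token
#' streams (each sentence is prefixed with `n_order - 1` `<s>` markers;
#' k-grams never cross sentence boundaries and `<s>` is never a
#' predicted word). Counts r <= `gt_max_r` are replaced by the
#' Good-Turing discounted count `r* = (r + 1) N_{r+1} / N_r` computed
#' from the counts-of-counts; larger counts are left undiscounted, as is
#' any r whose counts-of-counts are degenerate (`N_{r+1} = 0` or
#' `r* > r`). The mass removed by discounting is redistributed through
#' back-off weights chosen so that every context's conditional
#' distribution sums to 1. The unigram level is maximum likelihood over
#' the training vocabulary.
#'
#' @param corpus a `tokenized_corpus` (non-empty).
#' @param n_order model order N (>= 1; 4 is a typical optimum for
#'   running-text predictability).
#' @param gt_max_r discount counts up to this value (default 5).
#' @param unk_singletons map words seen exactly once in training to an
#'   `<unk>` type, giving held-out out-of-vocabulary words a probability.
#' @return a `katz_ngram_model`.
#' @export
train_ngram <- function(corpus, n_order, gt_max_r = 5L,
                        unk_singletons = FALSE) {
  check_number(n_order, "n_order", min = 1)
  tok <- corpus$tokens
  if (nrow(tok) == 0L) stop_param("corpus is empty")
  n_order <- as.integer(n_order)

  words <- tok$norm
  if (unk_singletons) {
    cnt <- table(words)
    singletons <- names(cnt)[cnt == 1L]
    words[words %in% singletons] <- UNK_TOKEN
  }
  x <- pad_sentences(words, tok$text_id, tok$sent_id, n_order)

  vocab <- sort(unique(words))
  counts <- count_ngrams(x, n_order)
  probs <- vector("list", n_order)
  alpha <- vector("list", n_order)
  coc <- vector("list", n_order)

  # order 1: maximum likelihood over the vocabulary
  uni <- counts[[1L]]
  coc[[1L]] <- uni[, .N, by = .(r = count)][order(r)]
  probs[[1L]] <- uni[, .(ctx = "", w, p = count / sum(count))]
  setkey(probs[[1L]], ctx, w)

  for (k in seq_len(n_order)[-1L]) {
    dt <- counts[[k]]
    coc[[k]] <- dt[, .N, by = .(r = count)][order(r)]
    dt[, dcount := gt_discount(count, coc[[k]], gt_max_r)]
    dt[, ctx_total := sum(count), by = ctx]
    dt[, p := dcount / ctx_total]
    # probability mass of the backed-off distribution over the words seen
    # in each context, needed for the back-off weights
    low <- katz_p_vec(probs, alpha, strip_first(dt$ctx), dt$w, k - 1L)
    stats <- dt[, .(num = 1 - sum(p), den = 1 - sum(low[.I])), by = ctx]
    degen <- stats[den <= 1e-12 | num <= 0, ctx]
    if (length(degen) > 0L) {
      # nothing (or nothing usable) to redistribute: fall back to the
      # undiscounted conditional for these contexts
      dt[ctx %in% degen, p := count / ctx_total]
    }
    a <- stats[!ctx %in% degen, .(ctx, alpha = num / den)]
    probs[[k]] <- dt[, .(ctx, w, p)]
    setkey(probs[[k]], ctx, w)
    alpha[[k]] <- rbind(a, data.table(ctx = degen, alpha = 0))
    setkey(alpha[[k]], ctx)
  }

  structure(list(order = n_order, vocab = vocab, probs = probs,
                 alpha = alpha, counts_of_counts = coc,
                 gt_max_r = as.integer(gt_max_r),
                 unk = isTRUE(unk_singletons)),
            class = "katz_ngram_model")
}

#' @export
print.katz_ngram_model <- function(x, ...) {
  sizes <- vapply(x$probs, nrow, integer(1))
  cat(sprintf("<katz_ngram_model> order %d, |V|=%d, ngrams: %s\n",
              x$order, length(x$vocab), paste(sizes, collapse = "/")))
  invisible(x)
}

# one global vector: each sentence prefixed by (n_order - 1) <s> markers,
# so no k-gram with k <= n_order can cross a sentence boundary
pad_sentences <- function(words, text_id, sent_id, n_order) {
  if (n_order == 1L) return(words)
  pad <- n_order - 1L
  grp <- cumsum(!duplicated(data.table(text_id, sent_id)))
  sizes <- tabulate(grp)
  total <- length(words) + length(sizes) * pad
  x <- rep(S_TOKEN, total)
  off <- cumsum(c(0L, head(sizes + pad, -1L)))
  pos <- off[grp] + pad + unlist(lapply(sizes, seq_len))
  x[pos] <- words
  x
}

count_ngrams <- function(x, n_order) {
  n <- length(x)
  counts <- vector("list", n_order)
  lagged <- lapply((n_order - 1L):0L, function(l) shift(x, l))
  for (k in seq_len(n_order)) {
    cols <- lagged[(n_order - k + 1L):n_order]
    valid <- cols[[k]] != S_TOKEN
    for (j in seq_len(k)) valid <- valid & !is.na(cols[[j]])
    if (k == 1L) {
      dt <- data.table(w = cols[[1L]][valid])
      counts[[k]] <- dt[, .(count = .N), by = w]
    } else {
      ctx <- do.call(paste, cols[seq_len(k - 1L)])
      dt <- data.table(ctx = ctx[valid], w = cols[[k]][valid])
      counts[[k]] <- dt[, .(count = .N), by = .(ctx, w)]
    }
  }
  counts
}

# Good-Turing discounted counts from a counts-of-counts table; degenerate
# rows (missing N_{r+1}, or a discount that fails r* <= r) fall back to
# the raw count.
gt_discount <- function(r, coc, gt_max_r) {
  nr <- setNames(coc$N, coc$r)
  out <- as.numeric(r)
  for (rv in unique(r[r <= gt_max_r])) {
    n_r <- nr[as.character(rv)]
    n_r1 <- nr[as.character(rv + 1L)]
    if (is.na(n_r) || is.na(n_r1) || n_r1 == 0) next
    r_star <- (rv + 1) * n_r1 / n_r
    if (r_star <= 0 || r_star > rv) next
    out[r == rv] <- r_star
  }
  out
}

strip_first <- function(ctx) sub("^\\S+\\s*", "", ctx)

# Vectorized Katz probability at order k for aligned (context, word)
# pairs; contexts are space-joined strings of exactly k-1 words ("" at
# k = 1). Query vectors are renamed before the joins so they cannot
# shadow the lookup tables' own columns.
katz_p_vec <- function(probs, alpha, ctx_q, w_q, k) {
  if (k == 1L) {
    empty_q <- rep("", length(w_q))
    p_out <- probs[[1L]][.(empty_q, w_q), p]
    p_out[is.na(p_out)] <- 0          # out-of-vocabulary word
    return(p_out)
  }
  p_out <- probs[[k]][.(ctx_q, w_q), p]
  miss <- is.na(p_out)
  if (any(miss)) {
    ctx_m <- ctx_q[miss]
    a <- alpha[[k]][.(ctx_m), alpha]
    a[is.na(a)] <- 1          # entirely unseen context: pure back-off
    p_out[miss] <- a * katz_p_vec(probs, alpha, strip_first(ctx_m),
                                  w_q[miss], k - 1L)
  }
  p_out
}

# trim/pad a raw context to exactly k-1 words; sentence-initial positions
# are padded with <s> to mirror training
ctx_key <- function(context, k) {
  if (k == 1L) return("")
  context <- tail(context, k - 1L)
  if (length(context) < k - 1L) {
    context <- c(rep(S_TOKEN, k - 1L - length(context)), context)
  }
  paste(context, collapse = " ")
}

#' Katz back-off probability of a word given its context
#'
#' @param model a `katz_ngram_model`.
#' @param word target word (normalized form).
#' @param context character vector of preceding tokens in order; only
#'   the last `n_order - 1` are used, and sentence-initial positions are
#'   `<s>`-padded to mirror training.
#' @return a probability. Out-of-vocabulary targets map to `<unk>` when
#'   the model was trained with one, otherwise raise an error.
#' @export
p_ngram <- function(model, word, context = character(0)) {
  word <- map_oov(model, word)
  katz_p_vec(model$probs, model$alpha,
             ctx_key(map_oov(model, context), model$order),
             word, model$order)
}

map_oov <- function(model, w) {
  oov <- !(w %in% model$vocab) & w != S_TOKEN
  if (any(oov)) {
    if (!model$unk) {
      stop_param("out-of-vocabulary word(s): ",
                 paste(unique(w[oov]), collapse = ", "),
                 " (train with unk_singletons = TRUE to map them to <unk>)")
    }
    w[oov] <- UNK_TOKEN
  }
  w
}

#' Full conditional distribution over the vocabulary
#'
#' Enumerates P(w | context) for every vocabulary word; useful for
#' normalization checks and for comparing against generative truth.
#'
#' @inheritParams p_ngram
#' @return named probability vector over `model$vocab`.
#' @export
p_ngram_dist <- function(model, context = character(0)) {
  key <- ctx_key(map_oov(model, context), model$order)
  setNames(katz_p_vec(model$probs, model$alpha,
                      rep(key, length(model$vocab)), model$vocab,
                      model$order),
           model$vocab)
}

# ---- cache model (additively smoothed in-text unigram) ----

#' Additively smoothed cache unigram over the text read so far
#'
#' `new_cache()` starts an empty cache; `cache_add()` feeds it one or
#' more read words; `p_cache()` evaluates the additive-smoothing
#' probability `(c(w) + delta) / (delta * V + N)`, where `c(w)` is the
#' word's count in the cache, `N` the number of cached tokens and `V`
#' the vocabulary size (base vocabulary plus any novel words read so
#' far). An empty cache with `delta > 0` is uniform at `1 / V`; with
#' `delta = 0` and an empty cache the probability is undefined and an
#' error is raised.
#'
#' @param delta smoothing constant (>= 0).
#' @param base_vocab vocabulary counted in `V` before any text is read
#'   (typically the training vocabulary of the companion N-gram model).
#' @param cache a `cache_model`; `words` words to add.
#' @param word word to score.
#' @return `p_cache()` a probability; the others a `cache_model`.
#' @export
new_cache <- function(delta, base_vocab = character(0)) {
  check_number(delta, "delta", min = 0)
  structure(list(counts = integer(0), n = 0L,
                 base_vocab = unique(base_vocab), extra = character(0),
                 delta = delta),
            class = "cache_model")
}

#' @rdname new_cache
#' @export
cache_add <- function(cache, words) {
  for (w in words) {
    cache$counts[w] <- (if (w %in% names(cache$counts))
      cache$counts[[w]] else 0L) + 1L
    cache$n <- cache$n + 1L
    if (!(w %in% cache$base_vocab)) cache$extra <- union(cache$extra, w)
  }
  cache
}

#' @rdname new_cache
#' @export
p_cache <- function(cache, word) {
  V <- length(cache$base_vocab) + length(cache$extra)
  if (cache$delta == 0 && cache$n == 0L) {
    stop_param("degenerate cache: delta = 0 with an empty cache")
  }
  cw <- if (word %in% names(cache$counts)) cache$counts[[word]] else 0L
  (cw + cache$delta) / (cache$delta * V + cache$n)
}

#' Linear interpolation of cache and N-gram probabilities
#'
#' `lambda * p_cache + (1 - lambda) * p_ngram`.
#'
#' @param lambda interpolation weight in \[0, 1\].
#' @param p_cache,p_ngram probabilities in \[0, 1\] (vectorized).
#' @return interpolated probabilities.
#' @export
p_combined <- function(lambda, p_cache, p_ngram) {
  check_number(lambda, "lambda", min = 0, max = 1)
  lambda * p_cache + (1 - lambda) * p_ngram
}

#' Score running text with the N-gram+cache model
#'
#' For each token, in reading order: the Katz N-gram probability from
#' the (sentence-padded) preceding context, the cache probability from
#' the text previously read, and their interpolation. The cache is
#' reset at every text start and updated with each word only *after*
#' that word is scored, so a word never predicts itself. The cache
#' vocabulary V is the model's training vocabulary plus any novel words
#' already read in the current text; `<s>` markers are never cached.
#'
#' @param model a `katz_ngram_model` trained on an independent corpus.
#' @param corpus the `tokenized_corpus` to score.
#' @param delta cache smoothing constant.
#' @param lambda interpolation weight.
#' @return data.table `(text_id, token_idx, p_ngram, p_cache,
#'   p_combined)` aligned with the corpus tokens.
#' @export
score_text <- function(model, corpus, delta, lambda) {
  check_number(delta, "delta", min = 0)
  check_number(lambda, "lambda", min = 0, max = 1)
  tok <- copy(corpus$tokens)
  w <- map_oov(model, tok$norm)
  # N-gram part: padded per sentence, vectorized over all tokens
  x <- pad_sentences(w, tok$text_id, tok$sent_id, model$order)
  word_pos <- which(x != S_TOKEN)
  if (model$order > 1L) {
    lagged <- lapply((model$order - 1L):1L, function(l) shift(x, l))
    ctx <- do.call(paste, lagged)[word_pos]
  } else {
    ctx <- rep("", length(word_pos))
  }
  png <- katz_p_vec(model$probs, model$alpha, ctx, x[word_pos], model$order)
  # cache part, from running within-text statistics
  cache <- cache_stats(tok, model$vocab)
  pc <- (cache$c_prior + delta) / (delta * cache$V + cache$n_prior)
  if (delta == 0) pc[cache$n_prior == 0L] <- 0   # empty cache, no smoothing
  data.table(text_id = tok$text_id, token_idx = tok$tok_text,
             p_ngram = png, p_cache = pc,
             p_combined = lambda * pc + (1 - lambda) * png)
}

# running cache statistics per token: prior count of the word, tokens
# read so far, and the cache vocabulary size (training vocab + novel
# in-text words already read)
cache_stats <- function(tok, vocab) {
  tok[, c_prior := seq_len(.N) - 1L, by = .(text_id, norm)]
  tok[, n_prior := seq_len(.N) - 1L, by = text_id]
  tok[, novel_first := (seq_len(.N) == 1L), by = .(text_id, norm)]
  tok[, novel_first := novel_first & !(norm %in% vocab)]
  tok[, v_extra := cumsum(shift(novel_first, fill = FALSE)), by = text_id]
  list(c_prior = tok$c_prior, n_prior = tok$n_prior,
       V = length(vocab) + tok$v_extra)
}

#' Grid search over the cache smoothing and interpolation parameters
#'
#' Evaluates a scalar criterion (any `eval_fn(p_combined, corpus)`,
#' e.g. a correlation with cloze predictability or an LMM t-value) over
#' the full delta x lambda grid and reports the argmax by absolute
#' criterion. The N-gram and cache statistics are computed once and
#' reused across the grid.
#'
#' @param model a `katz_ngram_model`.
#' @param corpus the held-out corpus to score.
#' @param eval_fn function of `(p_combined, corpus)` returning a scalar.
#' @param delta_grid,lambda_grid non-empty numeric grids; the default
#'   grids span delta in \[5e-05, 5e-04\] and lambda in \[0.05, 0.6\].
#' @return data.table `(delta, lambda, criterion)` with attribute `best`
#'   holding the argmax row.
#' @export
grid_search <- function(model, corpus, eval_fn,
                        delta_grid = seq(5e-05, 5e-04, length.out = 10),
                        lambda_grid = seq(0.05, 0.60, by = 0.05)) {
  if (length(delta_grid) == 0L || length(lambda_grid) == 0L) {
    stop_param("delta_grid and lambda_grid must be non-empty")
  }
  base <- score_text(model, corpus, delta = delta_grid[1], lambda = 0)
  cache <- cache_stats(copy(corpus$tokens), model$vocab)
  grid <- CJ(delta = delta_grid, lambda = lambda_grid)
  crit <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pc <- (cache$c_prior + grid$delta[i]) /
      (grid$delta[i] * cache$V + cache$n_prior)
    if (grid$delta[i] == 0) pc[cache$n_prior == 0L] <- 0
    pcomb <- grid$lambda[i] * pc + (1 - grid$lambda[i]) * base$p_ngram
    crit[i] <- eval_fn(pcomb, corpus)
  }
  grid[, criterion := crit]
  best <- grid[which.max(abs(criterion))]
  structure(grid[], best = best)
}
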