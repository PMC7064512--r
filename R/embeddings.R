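# Word embeddings: LSA training (tf-idf word-by-document matrix, rank-d
# SVD truncation) and cosine-similarity context scores over a running
# text, with mean / resultant variants and a with/without-stopwords
# context definition. Pre-trained skipgram/FastText vectors are consumed
# from word2vec text files (see read_vectors()); their training is a
# library concern, not reimplemented here.

new_embedding_space <- function(vectors, provenance) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  structure(list(vectors = vectors, d = ncol(vectors),
                 provenance = provenance),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space> |V|=%d, d=%d (%s)\n",
              nrow(x$vectors), x$d, x$provenance))
  invisible(x)
}

#' Train LSA word vectors on a corpus
#'
#' Builds the word-by-document count matrix, applies tf-idf weighting
#' (tf = raw count, idf = log(n_docs / document frequency)), and
#' truncates it to rank `d` by singular value decomposition. Word
#' vectors are the left singular vectors, scaled by the singular values
#' by default (rows of U S), so that at full rank cosine similarities
#' equal those of the tf-idf rows exactly.
#'
#' @param corpus a `tokenized_corpus` with at least 2 documents.
#' @param d target dimension (clamped to the matrix rank, with a
#'   warning, if it exceeds it).
#' @param tfidf apply tf-idf weighting before the SVD.
#' @param idf `"classic"` uses `log(n_docs / df)`; `"smooth"` uses
#'   `log(n_docs / df) + 1`, which keeps words that occur in every
#'   document (idf 0 under the classic form) in the space — useful for
#'   small closed-vocabulary corpora where the classic weighting zeroes
#'   the whole matrix.
#' @param scale_singular scale left singular vectors by the singular
#'   values (unscaled U is also meaningful; the scaled version is the
#'   default because it preserves full-rank geometry).
#' @return an `embedding_space` with provenance `"lsa"`.
#' @export
train_lsa <- function(corpus, d = 300L, tfidf = TRUE,
                      idf = c("classic", "smooth"),
                      scale_singular = TRUE) {
  check_number(d, "d", min = 1)
  idf <- match.arg(idf)
  tok <- corpus$tokens
  docs <- sort(unique(tok$text_id))
  if (length(docs) < 2L) stop_param("LSA needs at least 2 documents")
  cnt <- tok[, .N, by = .(norm, text_id)]
  vocab <- sort(unique(cnt$norm))
  M <- matrix(0, length(vocab), length(docs),
              dimnames = list(vocab, as.character(docs)))
  M[cbind(match(cnt$norm, vocab), match(cnt$text_id, docs))] <- cnt$N
  if (tfidf) {
    df <- rowSums(M > 0)
    w <- log(length(docs) / df) + if (idf == "smooth") 1 else 0
    M <- M * w
    if (all(M == 0)) {
      stop_param("tf-idf matrix is identically zero (every word occurs ",
                 "in every document); use idf = \"smooth\" or tfidf = FALSE")
    }
  }
  r <- min(dim(M))
  if (d > r) {
    warning(sprintf("d = %d exceeds the matrix rank bound %d; clamped", d, r))
    d <- r
  }
  s <- svd(M, nu = d, nv = 0)
  vec <- if (scale_singular) s$u %*% diag(s$d[seq_len(d)], d, d) else s$u
  rownames(vec) <- vocab
  # words with an all-zero tf-idf row (e.g. present in every document
  # under idf = 0) carry no information; drop them from the space
  zero <- rowSums(abs(vec)) == 0
  if (any(zero)) vec <- vec[!zero, , drop = FALSE]
  new_embedding_space(vec, "lsa")
}

cosine <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Cosine-similarity context predictability scores
#'
#' For the token at position i of each text, the context is the `window`
#' preceding tokens of that text (truncated at the text start; under
#' `stopword_policy = "without"` the `window` preceding *content* words,
#' i.e. stopwords are excluded before counting). The score is the mean
#' cosine similarity between the target vector and each context vector
#' (`variant = "mean"`), or the cosine between the target and the sum of
#' the context vectors (`variant = "resultant"`); the two coincide at
#' `window = 1`. Out-of-vocabulary context words are skipped (or raise
#' an error under `oov_policy = "fail"`); a token that is itself
#' out-of-vocabulary, or whose usable context is empty (e.g. the first
#' token of a text), gets `NA` and becomes an incomplete case
#' downstream.
#'
#' @param space an `embedding_space`.
#' @param corpus the `tokenized_corpus` to score.
#' @param window context size w (>= 1).
#' @param variant `"mean"` or `"resultant"`.
#' @param stopword_policy `"with"` (all tokens) or `"without"` (content
#'   words only; requires `stopwords`).
#' @param stopwords character vector of stopword forms.
#' @param oov_policy `"skip"` or `"fail"`.
#' @return numeric vector of scores in \[-1, 1\] aligned with the corpus
#'   tokens.
#' @export
cs_score <- function(space, corpus, window, variant = c("mean", "resultant"),
                     stopword_policy = c("with", "without"),
                     stopwords = character(0),
                     oov_policy = c("skip", "fail")) {
  check_number(window, "window", min = 1)
  variant <- match.arg(variant)
  stopword_policy <- match.arg(stopword_policy)
  oov_policy <- match.arg(oov_policy)
  if (stopword_policy == "without" && length(stopwords) == 0L) {
    stop_param("stopword_policy = \"without\" needs a stopword list")
  }
  tok <- corpus$tokens
  idx <- match(tok$norm, rownames(space$vectors))
  if (oov_policy == "fail" && anyNA(idx)) {
    stop_param("out-of-vocabulary word(s): ",
               paste(unique(tok$norm[is.na(idx)])[1:5], collapse = ", "))
  }
  V <- space$vectors
  norms <- sqrt(rowSums(V * V))
  out <- rep(NA_real_, nrow(tok))
  is_stop <- tok$norm %in% stopwords
  text_start <- which(!duplicated(tok$text_id))
  starts <- rep(NA_integer_, nrow(tok))
  starts[text_start] <- text_start
  starts <- cummax(ifelse(is.na(starts), 0L, starts))
  for (i in seq_len(nrow(tok))) {
    ti <- idx[i]
    if (is.na(ti)) next
    lo <- starts[i]
    if (i == lo) next                       # first token: empty context
    ctx <- (lo:(i - 1L))
    if (stopword_policy == "without") ctx <- ctx[!is_stop[ctx]]
    ctx <- tail(ctx, window)
    ci <- idx[ctx]
    ci <- ci[!is.na(ci)]
    if (length(ci) == 0L) next
    tv <- V[ti, ]
    if (variant == "mean") {
      sims <- (V[ci, , drop = FALSE] %*% tv) / (norms[ci] * norms[ti])
      out[i] <- mean(sims)
    } else {
      out[i] <- cosine(tv, colSums(V[ci, , drop = FALSE]))
    }
  }
  out
}

#' Sweep the context window for cosine-similarity scores
#'
#' Evaluates a scalar criterion for every combination of window size,
#' variant and stopword policy, and reports the full table with the
#' maximal-|criterion| combination as attribute `best`.
#'
#' @param space an `embedding_space`.
#' @param corpus the corpus to score.
#' @param eval_fn function of `(scores, corpus)` returning a scalar
#'   (e.g. correlation with cloze predictability).
#' @param windows non-empty vector of window sizes; the default spans
#'   1-150.
#' @param variants,stopword_policies combinations to evaluate.
#' @param stopwords stopword list for the without-stopwords policy.
#' @return data.table `(window, variant, stopword_policy, criterion)`.
#' @export
window_sweep <- function(space, corpus, eval_fn,
                         windows = c(1, 2, 3, 5, 9, 15, 25, 50, 100, 150),
                         variants = c("mean", "resultant"),
                         stopword_policies = "with",
                         stopwords = character(0)) {
  if (length(windows) == 0L) stop_param("windows must be non-empty")
  grid <- CJ(window = as.integer(windows), variant = variants,
             stopword_policy = stopword_policies)
  crit <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- cs_score(space, corpus, grid$window[i], grid$variant[i],
                   grid$stopword_policy[i], stopwords)
    crit[i] <- eval_fn(sc, corpus)
  }
  grid[, criterion := crit]
  best <- grid[which.max(abs(criterion))]
  structure(grid[], best = best)
}
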