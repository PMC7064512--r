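# Cloze-task aggregation: per-token proportion of correct guesses
# (cloze predictability), the answer-count inclusion filter, empirical
# logit transform, and covariation summaries against word properties.

#' Aggregate cloze responses into per-token predictability
#'
#' A response is counted correct iff its normalized form (under the
#' corpus tokenizer configuration) equals the token's normalized form;
#' predictability is the proportion of correct answers. Tokens with
#' fewer than `min_answers` responses are flagged `included = FALSE`
#' (their `pred` is still reported when at least one answer exists;
#' tokens with zero answers get `NA`, not a propagating NaN).
#'
#' @param responses a cloze response table `(text_id, token_idx,
#'   response)`; every `(text_id, token_idx)` must exist in the corpus.
#' @param corpus a `tokenized_corpus`.
#' @param min_answers inclusion threshold on the number of answers
#'   (default 8: words with fewer answers are not analyzed).
#' @return a `cloze_pred` table: one row per corpus token with
#'   `n_answers`, `n_correct`, `pred`, `logit_pred` (empirical logit,
#'   finite for every answered token) and `included`.
#' @export
aggregate_cloze <- function(responses, corpus, min_answers = 8L) {
  check_number(min_answers, "min_answers", min = 1)
  tok <- corpus$tokens[, .(text_id, token_idx = tok_text, norm)]
  resp <- copy(responses)
  bad <- !resp[, paste(text_id, token_idx)] %in%
    tok[, paste(text_id, token_idx)]
  if (any(bad)) {
    stop_param(sprintf("response row %d references a token absent from the corpus",
                       which(bad)[1]))
  }
  resp[, resp_norm := normalize_word(response, corpus$config)]
  agg <- resp[tok, on = c("text_id", "token_idx")]
  agg <- agg[, .(n_answers = sum(!is.na(response)),
                 n_correct = sum(!is.na(response) & resp_norm == norm)),
             by = .(text_id, token_idx)]
  agg[, pred := ifelse(n_answers > 0L, n_correct / n_answers, NA_real_)]
  agg[, logit_pred := ifelse(n_answers > 0L,
                             empirical_logit(n_correct, n_answers),
                             NA_real_)]
  agg[, included := n_answers >= min_answers]
  setkey(agg, text_id, token_idx)
  structure(agg[], class = c("cloze_pred", class(agg)),
            min_answers = as.integer(min_answers))
}

#' Logit-transformed cloze predictability
#'
#' Returns the empirical-logit predictability for included tokens:
#' `logit((n_correct + 0.5) / (n_answers + 1))`, so proportions of 0 and
#' 1 map to finite values. Excluded tokens give `NA`.
#'
#' @param pred_table a `cloze_pred` table from [aggregate_cloze()].
#' @return numeric vector aligned with the table rows.
#' @export
cloze_logit <- function(pred_table) {
  ifelse(pred_table$included, pred_table$logit_pred, NA_real_)
}

#' Covariation of cloze predictability with word properties
#'
#' Bins included tokens by each requested feature and reports the mean
#' empirical-logit predictability with its standard error per bin — the
#' standard sanity check that more frequent, shorter, repeated and
#' late-in-sentence words are more predictable. Integer-valued features
#' (e.g. repetition) are binned by value (capped at `max_levels`);
#' continuous features by quantile into `n_bins` bins. Empty bins are
#' dropped.
#'
#' @param pred_table a `cloze_pred` table.
#' @param features the matching [compute_features()] table.
#' @param vars feature columns to summarize.
#' @param n_bins quantile bins for continuous features.
#' @param max_levels cap for value-binned integer features.
#' @return data.table `(variable, bin, bin_value, mean_logit_pred, sem, n)`.
#' @export
covariation_summary <- function(pred_table, features,
                                vars = c("repetition", "log_freq",
                                         "inv_length", "rps"),
                                n_bins = 5L, max_levels = 6L) {
  dt <- merge(as.data.table(pred_table),
              features, by.x = c("text_id", "token_idx"),
              by.y = c("text_id", "tok_text"))
  dt <- dt[included == TRUE & is.finite(logit_pred)]
  out <- vector("list", length(vars))
  for (vi in seq_along(vars)) {
    v <- vars[vi]
    if (!v %in% names(dt)) stop_param("unknown feature column: ", v)
    x <- dt[[v]]
    if (all(x == round(x)) && length(unique(x)) <= max_levels * 3L) {
      bin_val <- pmin(x, max_levels)
      bin_lab <- as.character(bin_val)
    } else {
      qs <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
      if (length(qs) < 2L) { bin_val <- rep(1, length(x)); bin_lab <- "1" }
      else {
        cutf <- cut(x, qs, include.lowest = TRUE)
        bin_val <- tapply(x, cutf, mean)[as.integer(cutf)]
        bin_lab <- as.character(as.integer(cutf))
      }
    }
    s <- dt[, .(bin_value = mean(get(v)),
                mean_logit_pred = mean(logit_pred),
                sem = sd(logit_pred) / sqrt(.N), n = .N),
            by = .(bin = bin_lab)]
    s[, variable := v]
    out[[vi]] <- s
  }
  rbindlist(out)[, .(variable, bin, bin_value, mean_logit_pred, sem, n)]
}

#' Write and read cloze predictability tables
#' @param pred_table a `cloze_pred` table; `path` a file path.
#' @return the path (write) or a data.table (read).
#' @export
write_cloze_pred <- function(pred_table, path) {
  write_tsv(as.data.table(pred_table)[
    , .(text_id, token_idx, n_answers, n_correct, pred, logit_pred,
        included)], path)
}

#' @rdname write_cloze_pred
#' @export
read_cloze_pred <- function(path) {
  df <- read_tsv_checked(path, c("text_id", "token_idx", "n_answers",
                                 "n_correct", "pred", "logit_pred",
                                 "included"),
                         c("text_id", "token_idx", "n_answers", "n_correct",
                           "pred", "logit_pred"))
  df[, `:=`(text_id = as.integer(text_id), token_idx = as.integer(token_idx),
            n_answers = as.integer(n_answers),
            n_correct = as.integer(n_correct),
            included = included == "TRUE")]
  df[]
}
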