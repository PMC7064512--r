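# Tokenization and per-token covariate construction.
#
# A tokenized corpus is the single source of truth for word identity and
# position: every downstream table (cloze, fixations, predictability
# scores) refers to tokens by (text_id, token index within text), 0-based.

#' Tokenizer configuration
#'
#' @param lowercase lowercase normalized forms (default `TRUE`).
#' @param strip_accents transliterate accented letters to ASCII. Off by
#'   default: Spanish orthography distinguishes e.g. "si"/"sí".
#' @param wrap_width characters per display line used to reconstruct line
#'   membership by greedy wrapping, emulating the on-screen layout that
#'   defines the relative-position-in-line covariate.
#' @return a `tokenizer_config` list.
#' @export
tokenizer_config <- function(lowercase = TRUE, strip_accents = FALSE,
                             wrap_width = 60L) {
  check_number(wrap_width, "wrap_width", min = 1)
  structure(list(lowercase = isTRUE(lowercase),
                 strip_accents = isTRUE(strip_accents),
                 wrap_width = as.integer(wrap_width)),
            class = "tokenizer_config")
}

normalize_word <- function(x, config) {
  x <- gsub("^[^[:alnum:]À-ÿ]+|[^[:alnum:]À-ÿ]+$", "", x)
  if (config$lowercase) x <- tolower(x)
  if (config$strip_accents) {
    x <- chartr("áéíóúüñÁÉÍÓÚÜÑ",
                "aeiouunAEIOUUN", x)
  }
  x
}

#' Tokenize raw text into sentences, words and display lines
#'
#' Sentences are split on terminal punctuation (`.`, `!`, `?`, `…`);
#' word tokens are whitespace-delimited with surrounding punctuation
#' stripped; line membership comes from greedy wrapping of the surface
#' stream at `config$wrap_width` characters. All indices are 0-based
#' within their scope. Empty input yields a zero-row fragment.
#'
#' @param raw_text a single UTF-8 string (one document).
#' @param config a [tokenizer_config()].
#' @param text_id integer id stamped on every token.
#' @return a `data.table` with columns `text_id`, `sent_id`, `line_id`,
#'   `tok_text`, `tok_sent`, `tok_line`, `surface`, `norm`.
#' @export
tokenize <- function(raw_text, config = tokenizer_config(), text_id = 1L) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  raw_text <- gsub("[\r\n]+", " ", raw_text)
  sents <- strsplit(raw_text, "(?<=[.!?…])[.!?…]*\\s+", perl = TRUE)[[1]]
  sents <- sents[nzchar(trimws(sents))]
  if (length(sents) == 0L) return(empty_token_table())

  out <- vector("list", length(sents))
  for (s in seq_along(sents)) {
    surf <- strsplit(trimws(sents[s]), "\\s+")[[1]]
    norm <- normalize_word(surf, config)
    keep <- nzchar(norm)
    surf <- surf[keep]; norm <- norm[keep]
    if (length(surf) == 0L) next
    out[[s]] <- data.table(sent_id = s - 1L,
                           tok_sent = seq_along(surf) - 1L,
                           surface = surf, norm = norm)
  }
  tok <- rbindlist(out)
  if (nrow(tok) == 0L) return(empty_token_table())
  tok[, text_id := as.integer(text_id)]
  tok[, tok_text := seq_len(.N) - 1L]
  # renumber sentences consecutively in case some came out empty
  tok[, sent_id := as.integer(factor(sent_id, levels = unique(sent_id))) - 1L]
  assign_lines(tok, config$wrap_width)
  setcolorder(tok, c("text_id", "sent_id", "line_id", "tok_text",
                     "tok_sent", "tok_line", "surface", "norm"))
  tok[]
}

empty_token_table <- function() {
  data.table(text_id = integer(), sent_id = integer(), line_id = integer(),
             tok_text = integer(), tok_sent = integer(), tok_line = integer(),
             surface = character(), norm = character())
}

# Greedy wrap: a token goes on the current line if it fits (with a joining
# space) inside `width` characters, else it opens a new line.
assign_lines <- function(tok, width) {
  n <- nrow(tok)
  line_id <- integer(n); tok_line <- integer(n)
  cur_line <- 0L; cur_len <- 0L; cur_pos <- 0L
  w <- nchar(tok$surface)
  for (i in seq_len(n)) {
    need <- if (cur_len == 0L) w[i] else cur_len + 1L + w[i]
    if (cur_len > 0L && need > width) {
      cur_line <- cur_line + 1L; cur_len <- w[i]; cur_pos <- 0L
    } else {
      cur_len <- need; cur_pos <- if (cur_len == w[i]) 0L else cur_pos + 1L
    }
    line_id[i] <- cur_line; tok_line[i] <- cur_pos
  }
  tok[, `:=`(line_id = line_id, tok_line = tok_line)]
  invisible(tok)
}

#' Build a tokenized corpus from document strings
#'
#' @param texts character vector, one document per element.
#' @param config a [tokenizer_config()].
#' @return a `tokenized_corpus`: list with `tokens` (one row per token,
#'   see [tokenize()]), `n_texts` and the `config` used.
#' @export
tokenize_corpus <- function(texts, config = tokenizer_config()) {
  stopifnot(is.character(texts))
  tabs <- lapply(seq_along(texts), function(i) tokenize(texts[i], config, i))
  new_corpus(rbindlist(tabs), length(texts), config)
}

new_corpus <- function(tokens, n_texts, config) {
  structure(list(tokens = tokens, n_texts = as.integer(n_texts),
                 config = config),
            class = "tokenized_corpus")
}

#' @export
print.tokenized_corpus <- function(x, ...) {
  cat(sprintf("<tokenized_corpus> %d texts, %d tokens, %d types\n",
              x$n_texts, nrow(x$tokens), length(unique(x$tokens$norm))))
  invisible(x)
}

#' Count word frequencies in a corpus
#'
#' @param corpus a `tokenized_corpus`.
#' @return a `frequency_table`: data.table `(word, count)` plus a `total`
#'   attribute with the token count.
#' @export
build_frequency_table <- function(corpus) {
  ft <- corpus$tokens[, .(count = .N), by = .(word = norm)][order(word)]
  structure(ft, total = sum(ft$count), class = c("frequency_table",
                                                 class(ft)))
}

#' Per-token covariates for reading analyses
#'
#' Computes, for every token: length in letters and its inverse; log10
#' frequency per million tokens from `freq` (out-of-vocabulary words get a
#' floor count so the log stays finite); the repetition number (how many
#' times the same normalized word already occurred earlier in the same
#' text); and the relative positions in sentence (`rps`), line (`rpl`) and
#' text (`rpt`), each rescaled to \[0, 1\] as `index / (scope_length - 1)`
#' with a single-word scope mapped to 0.
#'
#' @param corpus a `tokenized_corpus`.
#' @param freq a `frequency_table` (any source corpus).
#' @param oov_floor count assigned to words absent from `freq`.
#' @return data.table aligned row-for-row with `corpus$tokens`, columns
#'   `text_id`, `tok_text`, `length`, `inv_length`, `log_freq`,
#'   `repetition`, `rps`, `rpl`, `rpt`.
#' @export
compute_features <- function(corpus, freq, oov_floor = 1) {
  check_number(oov_floor, "oov_floor", min = 1e-9)
  tok <- copy(corpus$tokens)
  total <- attr(freq, "total")
  cnt <- setNames(freq$count, freq$word)[tok$norm]
  cnt[is.na(cnt)] <- oov_floor
  rel_pos <- function(i, n) if (n > 1L) i / (n - 1L) else rep(0, length(i))
  tok[, length := nchar(norm)]
  tok[, inv_length := 1 / length]
  tok[, log_freq := log10(cnt * 1e6 / total)]
  tok[, repetition := seq_len(.N) - 1L, by = .(text_id, norm)]
  tok[, rps := rel_pos(tok_sent, .N), by = .(text_id, sent_id)]
  tok[, rpl := rel_pos(tok_line, .N), by = .(text_id, line_id)]
  tok[, rpt := rel_pos(tok_text, .N), by = text_id]
  tok[, .(text_id, tok_text, length, inv_length, log_freq, repetition,
          rps, rpl, rpt)]
}
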