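# Readers and writers for the plain-text interchange formats: corpus
# directories (one document per .txt file), TSV tables with header rows
# (frequency, cloze responses, fixations), and word2vec-text vector files.
# Every writer round-trips through its reader.

read_tsv_checked <- function(path, required, numeric_cols = character()) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, colClasses = "character",
                   fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_param(sprintf("file '%s' is missing required column(s): %s",
                       path, paste(missing, collapse = ", ")))
  }
  for (col in numeric_cols) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      stop_param(sprintf("file '%s': non-numeric value '%s' in column '%s' at data row %d",
                         path, df[[col]][bad[1]], col, bad[1]))
    }
    df[[col]] <- val
  }
  setDT(df)
  df
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write and read corpus text files
#'
#' One plain-text file per document, one sentence per line, surface tokens
#' joined by single spaces with a terminal period, so that re-tokenizing
#' recovers the same token stream.
#'
#' @param corpus a `tokenized_corpus`.
#' @param dir directory for the `text_###.txt` files (created if needed).
#' @param config tokenizer configuration used when reading back.
#' @param files optional explicit file list for `read_corpus` (default:
#'   all `.txt` files in `dir`, sorted).
#' @return `write_corpus` returns the file paths; `read_corpus` a
#'   `tokenized_corpus`.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sort(unique(corpus$tokens$text_id))
  paths <- character(length(ids))
  for (i in seq_along(ids)) {
    tt <- corpus$tokens[text_id == ids[i]]
    # strip any terminal punctuation the surface forms already carry, so
    # repeated write/read cycles stay byte-identical
    lines <- tt[, .(line = paste0(sub("[.!?…]+$", "",
                                      paste(surface, collapse = " ")),
                                  ".")),
                by = sent_id]$line
    paths[i] <- file.path(dir, sprintf("text_%03d.txt", ids[i]))
    writeLines(lines, paths[i], useBytes = TRUE)
  }
  invisible(paths)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir, config = tokenizer_config(), files = NULL) {
  if (is.null(files)) {
    files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  }
  if (length(files) == 0L) stop_param("no corpus files found in ", dir)
  texts <- vapply(files, function(f)
    paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
    character(1))
  tokenize_corpus(unname(texts), config)
}

#' Read and write word-frequency tables
#'
#' TSV with header `word<TAB>count`; counts must be positive integers.
#' @param freq a `frequency_table`; `path` a file path.
#' @return the table (read) or the path, invisibly (write).
#' @export
write_frequency_table <- function(freq, path) {
  write_tsv(data.table(word = freq$word, count = freq$count), path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  df <- read_tsv_checked(path, c("word", "count"), "count")
  bad <- which(df$count < 1)
  if (length(bad) > 0L) {
    stop_param(sprintf("file '%s': count < 1 at data row %d", path, bad[1]))
  }
  df[, count := as.integer(count)]
  structure(df[, .(word, count)], total = sum(df$count),
            class = c("frequency_table", class(df)))
}

#' Read and write cloze response tables
#'
#' TSV with header `text_id<TAB>token_idx<TAB>response`; `token_idx` is
#' the 0-based token index within the text.
#' @param responses a data.table of responses; `path` a file path.
#' @return the table (read) or the path, invisibly (write).
#' @export
write_cloze_table <- function(responses, path) {
  write_tsv(responses[, .(text_id, token_idx, response)], path)
}

#' @rdname write_cloze_table
#' @export
read_cloze_table <- function(path) {
  df <- read_tsv_checked(path, c("text_id", "token_idx", "response"),
                         c("text_id", "token_idx"))
  df[, `:=`(text_id = as.integer(text_id), token_idx = as.integer(token_idx))]
  df[, .(text_id, token_idx, response)]
}

#' Read and write fixation tables
#'
#' TSV with header `subj_id<TAB>text_id<TAB>token_idx<TAB>dur_ms<TAB>launch_site`.
#' Gaze durations must be strictly positive; a violating row is rejected
#' by row number.
#' @param fixations a data.table of fixations; `path` a file path.
#' @return the table (read) or the path, invisibly (write).
#' @export
write_fixation_table <- function(fixations, path) {
  write_tsv(fixations[, .(subj_id, text_id, token_idx, dur_ms, launch_site)],
            path)
}

#' @rdname write_fixation_table
#' @export
read_fixation_table <- function(path) {
  df <- read_tsv_checked(path,
                         c("subj_id", "text_id", "token_idx", "dur_ms",
                           "launch_site"),
                         c("text_id", "token_idx", "dur_ms", "launch_site"))
  bad <- which(!(df$dur_ms > 0))
  if (length(bad) > 0L) {
    stop_param(sprintf("file '%s': non-positive gaze duration at data row %d",
                       path, bad[1]))
  }
  df[, `:=`(text_id = as.integer(text_id), token_idx = as.integer(token_idx))]
  df[, subj_id := utils::type.convert(subj_id, as.is = TRUE)]
  df[, .(subj_id, text_id, token_idx, dur_ms, launch_site)]
}

#' Read and write word vectors in word2vec text format
#'
#' First line `"<vocab_size> <dim>"`, then one `word v1 ... v_d` row per
#' word. Duplicate words keep their first occurrence (with a warning); a
#' row whose float count disagrees with the header dimension is a format
#' error naming the line.
#'
#' @param path file path.
#' @param space an `embedding_space` (see [train_lsa()]).
#' @param digits significant digits written per component.
#' @return `read_vectors` returns an `embedding_space` with provenance
#'   `"loaded"`.
#' @export
read_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L) stop_param("empty vector file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop_param("vector file must start with a 'count dim' header: ", path)
  }
  d <- hdr[2]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- rows[lengths(rows) > 0L]
  words <- character(length(rows))
  mat <- matrix(NA_real_, length(rows), d)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != d + 1L) {
      stop_param(sprintf("file '%s': row at line %d has %d values, expected %d",
                         path, i + 1L, length(r) - 1L, d))
    }
    words[i] <- r[1]
    mat[i, ] <- as.numeric(r[-1])
  }
  dup <- duplicated(words)
  if (any(dup)) {
    warning(sprintf("%d duplicate word(s) in '%s'; first occurrence kept",
                    sum(dup), path))
    mat <- mat[!dup, , drop = FALSE]
    words <- words[!dup]
  }
  rownames(mat) <- words
  new_embedding_space(mat, "loaded")
}

#' @rdname read_vectors
#' @export
write_vectors <- function(space, path, digits = 8) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  m <- space$vectors
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(rownames(m)[i],
          paste(formatC(m[i, ], digits = digits, format = "g"),
                collapse = " "))
  }, character(1))
  writeLines(c(paste(nrow(m), ncol(m)), body), path, useBytes = TRUE)
  invisible(path)
}
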