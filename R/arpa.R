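# ARPA back-off format: the standard interchange representation for
# back-off N-gram models (log10 conditional probabilities; a back-off
# weight attached to each n-gram that serves as a context one order up).
# Enables cross-checks against external language-model toolkits.

#' Write a Katz model in ARPA back-off format
#'
#' Each line holds `log10(p)  w1 ... wk  [log10(bow)]`; the back-off
#' weight column is present when the k-gram acts as a context at order
#' k+1. Contexts absent from the file have an implicit back-off weight
#' of 1.
#'
#' @param model a `katz_ngram_model`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_arpa <- function(model, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  fmt <- function(x) formatC(x, digits = 7, format = "f")
  ngs <- lapply(seq_len(model$order), function(k) {
    dt <- model$probs[[k]]
    if (k == 1L) dt$w else paste(dt$ctx, dt$w)
  })
  # contexts that carry a back-off weight without being probability
  # entries themselves (<s>-prefixed): pseudo-entries at log10 p = -99
  extras <- lapply(seq_len(model$order), function(k) {
    if (k >= model$order) return(character(0))
    setdiff(model$alpha[[k + 1L]]$ctx, ngs[[k]])
  })
  writeLines("\\data\\", con)
  for (k in seq_len(model$order)) {
    writeLines(sprintf("ngram %d=%d", k,
                       length(ngs[[k]]) + length(extras[[k]])), con)
  }
  for (k in seq_len(model$order)) {
    writeLines("", con)
    writeLines(sprintf("\\%d-grams:", k), con)
    dt <- model$probs[[k]]
    line <- paste0(fmt(log10(dt$p)), "\t", ngs[[k]])
    if (k < model$order) {
      a <- model$alpha[[k + 1L]][.(ngs[[k]]), alpha]
      has_bow <- !is.na(a)
      bow <- ifelse(a > 0, log10(a), -99)   # -99: conventional log10(0)
      line[has_bow] <- paste0(line[has_bow], "\t", fmt(bow[has_bow]))
      if (length(extras[[k]]) > 0L) {
        ae <- model$alpha[[k + 1L]][.(extras[[k]]), alpha]
        bowe <- ifelse(ae > 0, log10(ae), -99)
        line <- c(line, paste0(fmt(-99), "\t", extras[[k]], "\t",
                               fmt(bowe)))
      }
    }
    writeLines(line, con)
  }
  writeLines("", con)
  writeLines("\\end\\", con)
  invisible(path)
}

#' Read an ARPA back-off model
#'
#' Reconstructs a `katz_ngram_model` usable with [p_ngram()] and
#' [score_text()] from an ARPA file. Counts-of-counts tables are not
#' part of the format and are left empty.
#'
#' @param path an ARPA file.
#' @param unk treat the model as having an `<unk>` type (defaults to
#'   whether `<unk>` occurs in the unigrams).
#' @return a `katz_ngram_model`.
#' @export
read_arpa <- function(path, unk = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  hdr <- grep("^ngram \\d+=", lines, value = TRUE)
  if (length(hdr) == 0L) stop_param("not an ARPA file (no \\data\\ header): ",
                                    path)
  order <- max(as.integer(sub("^ngram (\\d+)=.*", "\\1", hdr)))
  probs <- vector("list", order)
  alpha <- vector("list", order)
  for (k in seq_len(order)) {
    start <- which(lines == sprintf("\\%d-grams:", k))
    if (length(start) != 1L) stop_param("missing \\", k, "-grams: section")
    end <- start
    while (end < length(lines) && !grepl("^\\\\", lines[end + 1L])) {
      end <- end + 1L
    }
    body <- lines[(start + 1L):end]
    body <- body[nzchar(body)]
    parts <- strsplit(body, "[\t ]+")
    nf <- lengths(parts)
    bad <- which(nf < k + 1L | nf > k + 2L)
    if (length(bad) > 0L) {
      stop_param(sprintf("malformed %d-gram line: '%s'", k, body[bad[1]]))
    }
    logp <- as.numeric(vapply(parts, `[`, character(1), 1L))
    wmat <- t(vapply(parts, function(p) p[2:(k + 1L)], character(k)))
    if (k == 1L) wmat <- matrix(wmat, ncol = 1L)
    w <- wmat[, k]
    ctx <- if (k == 1L) rep("", length(w)) else
      apply(wmat[, seq_len(k - 1L), drop = FALSE], 1L, paste,
            collapse = " ")
    probs[[k]] <- data.table(ctx = ctx, w = w, p = 10^logp)
    setkey(probs[[k]], ctx, w)
    bow <- vapply(parts, function(p)
      if (length(p) == k + 2L) as.numeric(p[k + 2L]) else NA_real_,
      numeric(1))
    if (k < order) {
      ng <- if (k == 1L) w else paste(ctx, w)
      has <- !is.na(bow)
      alpha[[k + 1L]] <- data.table(ctx = ng[has], alpha = 10^bow[has])
      setkey(alpha[[k + 1L]], ctx)
    }
  }
  vocab <- sort(setdiff(probs[[1L]]$w, S_TOKEN))
  structure(list(order = order, vocab = vocab, probs = probs,
                 alpha = alpha, counts_of_counts = vector("list", order),
                 gt_max_r = NA_integer_,
                 unk = if (is.null(unk)) UNK_TOKEN %in% vocab else
                   isTRUE(unk)),
            class = "katz_ngram_model")
}
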