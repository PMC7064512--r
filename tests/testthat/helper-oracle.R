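# Straight-line reference implementation of Good-Turing discounted Katz
# back-off, written independently of the package's vectorized machinery.
# Only usable on tiny corpora; serves as the oracle for the back-off
# probabilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_katz_model <- function(sents, n_order, gt_max_r = 5) {
  grams <- vector("list", n_order)
  for (k in seq_len(n_order)) {
    cnt <- list()
    for (s in sents) {
      padded <- c(rep("<s>", n_order - 1), s)
      for (i in seq_along(padded)) {
        if (i < k || padded[i] == "<s>") next
        g <- paste(padded[(i - k + 1):i], collapse = " ")
        cnt[[g]] <- (cnt[[g]] %||% 0) + 1
      }
    }
    grams[[k]] <- unlist(cnt)
  }
  list(grams = grams, n_order = n_order, gt_max_r = gt_max_r,
       vocab = sort(unique(unlist(sents))))
}

oracle_discount <- function(counts, gt_max_r) {
  nr <- table(counts)
  d <- as.numeric(counts)
  for (i in seq_along(d)) {
    r <- d[i]
    if (r > gt_max_r) next
    n_r <- nr[as.character(r)]
    n_r1 <- nr[as.character(r + 1)]
    if (is.na(n_r) || is.na(n_r1)) next
    r_star <- (r + 1) * n_r1 / n_r
    if (r_star > 0 && r_star <= r) d[i] <- r_star
  }
  names(d) <- names(counts)
  d
}

oracle_katz_p <- function(om, w, ctx) {
  k <- length(ctx) + 1L
  if (k == 1L) {
    uni <- om$grams[[1L]]
    p <- uni[w]
    if (is.na(p)) p <- 0
    return(unname(p) / sum(uni))
  }
  cnts <- om$grams[[k]]
  keys <- strsplit(names(cnts), " ", fixed = TRUE)
  ctx_of <- vapply(keys, function(x) paste(head(x, -1L), collapse = " "), "")
  w_of <- vapply(keys, function(x) tail(x, 1L), "")
  in_ctx <- ctx_of == paste(ctx, collapse = " ")
  if (!any(in_ctx)) return(oracle_katz_p(om, w, ctx[-1L]))
  d <- oracle_discount(cnts, om$gt_max_r)
  ctx_total <- sum(cnts[in_ctx])
  p_seen <- d[in_ctx] / ctx_total
  seen_w <- w_of[in_ctx]
  num <- 1 - sum(p_seen)
  den <- 1 - sum(vapply(seen_w, function(sw)
    oracle_katz_p(om, sw, ctx[-1L]), numeric(1)))
  if (den <= 1e-12 || num <= 0) {
    if (w %in% seen_w) {
      return(unname(cnts[in_ctx][match(w, seen_w)]) / ctx_total)
    }
    return(0)
  }
  if (w %in% seen_w) return(unname(p_seen[match(w, seen_w)]))
  (num / den) * oracle_katz_p(om, w, ctx[-1L])
}
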