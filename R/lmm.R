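# Linear mixed model evaluation: the fixation analysis frame, the model
# roster over predictability scores, maximum-likelihood fits with
# crossed random intercepts for subject, text and word, AIC and
# likelihood-ratio comparisons, and the fixed-effect-removal residual
# analysis.

BASELINE_TERMS <- c("launch_site", "length", "freq", "length:freq",
                    "rpl", "rpt", "rps")

#' Build the fixation analysis frame
#'
#' Joins fixations with per-token covariates and predictability scores,
#' applies the standard exclusion rules — words shorter than three
#' letters, and the first and last word of every sentence and of every
#' display line — takes the natural log of gaze duration as the
#' response, attaches every requested predictability score for the
#' fixated word N (`<name>_n`) and for the next word in the text
#' (`<name>_n1`), keeps only complete cases across every column any
#' roster model uses, and finally centers every covariate over the
#' retained rows (so a fitted intercept estimates the mean log
#' duration).
#'
#' @param fixations a fixation table `(subj_id, text_id, token_idx,
#'   dur_ms, launch_site)`.
#' @param corpus the `tokenized_corpus` the fixations refer to.
#' @param features its [compute_features()] table.
#' @param preds named list of numeric vectors aligned with the corpus
#'   tokens (e.g. `list(cloze = ..., ngram = ...)`); each contributes
#'   centered columns `<name>_n` and `<name>_n1`.
#' @param length_inverse use 1/length as the `length` covariate (the
#'   inverse-length convention); `FALSE` uses letters.
#' @param min_length exclude words with fewer letters than this.
#' @return a `model_frame` data.frame with response `y`, centered
#'   covariates, grouping factors `sujid`, `textid`, `wordid`, and
#'   attributes `centers` and `n_dropped`.
#' @export
build_frame <- function(fixations, corpus, features, preds = list(),
                        length_inverse = TRUE, min_length = 3L) {
  tok <- copy(corpus$tokens)
  n <- nrow(tok)
  stopifnot(nrow(features) == n)
  tk <- cbind(tok[, .(text_id, tok_text, sent_id, line_id, tok_sent,
                      tok_line)],
              features[, .(length, inv_length, log_freq, rps, rpl, rpt)])
  tk[, sent_len := .N, by = .(text_id, sent_id)]
  tk[, line_len := .N, by = .(text_id, line_id)]
  tk[, keep := length >= min_length &
       tok_sent > 0L & tok_sent < sent_len - 1L &
       tok_line > 0L & tok_line < line_len - 1L]
  for (nm in names(preds)) {
    v <- preds[[nm]]
    if (length(v) != n) {
      stop_param(sprintf("pred vector '%s' has length %d; expected %d",
                         nm, length(v), n))
    }
    tk[, (paste0(nm, "_n")) := v]
    v1 <- rep(NA_real_, n)
    nxt <- match(paste(tk$text_id, tk$tok_text + 1L),
                 paste(tk$text_id, tk$tok_text))
    v1[!is.na(nxt)] <- v[nxt[!is.na(nxt)]]
    tk[, (paste0(nm, "_n1")) := v1]
  }
  fx <- as.data.table(fixations)
  d <- merge(fx, tk, by.x = c("text_id", "token_idx"),
             by.y = c("text_id", "tok_text"))
  if (nrow(d) == 0L) stop_param("no fixations match the corpus tokens")
  n0 <- nrow(d)
  d <- d[keep == TRUE]
  d[, y := log(dur_ms)]
  d[, length_cov := if (length_inverse) inv_length else length]
  pred_cols <- as.vector(outer(names(preds), c("_n", "_n1"), paste0))
  covars <- c("launch_site", "length_cov", "log_freq", "rpl", "rpt", "rps",
              pred_cols)
  d <- d[complete.cases(d[, c("y", covars), with = FALSE])]
  if (nrow(d) == 0L) stop_param("no rows left after filtering")
  centers <- vapply(covars, function(cc) mean(d[[cc]]), numeric(1))
  for (cc in covars) set(d, j = cc, value = d[[cc]] - centers[[cc]])
  out <- data.frame(y = d$y,
                    launch_site = d$launch_site,
                    length = d$length_cov,
                    freq = d$log_freq,
                    rpl = d$rpl, rpt = d$rpt, rps = d$rps,
                    sujid = factor(d$subj_id),
                    textid = factor(d$text_id),
                    wordid = factor(paste(d$text_id, d$token_idx,
                                          sep = ":")))
  for (cc in pred_cols) out[[cc]] <- d[[cc]]
  structure(out, centers = centers, n_dropped = n0 - nrow(d),
            class = c("model_frame", "data.frame"))
}

#' Model specifications for the predictability roster
#'
#' `lmm_spec()` builds one specification: the baseline fixed effects
#' (launch site, length * frequency, relative positions in line, text
#' and sentence) plus any extra predictability terms, with crossed
#' random intercepts for subject, text and word. `build_roster()`
#' builds the full evaluation roster over three computational scores
#' and the cloze score: M0 baseline; M1 + cloze; M2-M4 each computer
#' score alone; M5-M8 their pairwise and triple combinations. With
#' `n1 = TRUE` every predictor enters for the fixated word N and the
#' next word N+1, and M9 combines the N-gram+cache score for word N
#' with the FastText-style embedding score for word N+1.
#'
#' @param name model label.
#' @param extra character vector of additional fixed-effect terms
#'   (column names in the frame, e.g. `"cloze_n"`).
#' @param scores named character vector mapping the three computer
#'   scores (ngram, lsa, ft) and cloze to frame column stems.
#' @param n1 build the word-N+1 roster.
#' @return `lmm_spec()` an `lmm_spec`; `build_roster()` a named list of
#'   them.
#' @export
lmm_spec <- function(name, extra = character(0)) {
  structure(list(name = name,
                 fixed = c(BASELINE_TERMS, extra),
                 extra = extra,
                 random = c("sujid", "textid", "wordid")),
            class = "lmm_spec")
}

#' @rdname lmm_spec
#' @export
build_roster <- function(scores = c(cloze = "cloze", ngram = "ngram",
                                    lsa = "lsa", ft = "ft"),
                         n1 = FALSE) {
  need <- c("cloze", "ngram", "lsa", "ft")
  if (!all(need %in% names(scores))) {
    stop_param("scores must name: ", paste(need, collapse = ", "))
  }
  term <- function(stem) if (n1) paste0(scores[[stem]], c("_n", "_n1"))
    else paste0(scores[[stem]], "_n")
  suffix <- if (n1) ".N+1" else ".N"
  specs <- list(
    lmm_spec(paste0("M0", suffix)),
    lmm_spec(paste0("M1", suffix), term("cloze")),
    lmm_spec(paste0("M2", suffix), term("ngram")),
    lmm_spec(paste0("M3", suffix), term("lsa")),
    lmm_spec(paste0("M4", suffix), term("ft")),
    lmm_spec(paste0("M5", suffix), c(term("ngram"), term("lsa"))),
    lmm_spec(paste0("M6", suffix), c(term("ngram"), term("ft"))),
    lmm_spec(paste0("M7", suffix), c(term("lsa"), term("ft"))),
    lmm_spec(paste0("M8", suffix), c(term("ngram"), term("lsa"),
                                     term("ft"))))
  if (n1) {
    specs <- c(specs, list(
      lmm_spec("M9.N+1", c(paste0(scores[["ngram"]], "_n"),
                           paste0(scores[["ft"]], "_n1")))))
  }
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

spec_formula <- function(spec) {
  fixed <- gsub("length:freq", "length:freq", spec$fixed, fixed = TRUE)
  rhs <- paste(c(fixed,
                 sprintf("(1 | %s)", spec$random)), collapse = " + ")
  stats::as.formula(paste("y ~", rhs))
}

#' Fit one roster model by maximum likelihood
#'
#' Gaussian linear mixed model with crossed random intercepts for
#' subject, text and word, fitted by maximum likelihood (not REML, so
#' that AIC and likelihood-ratio comparisons across fixed-effect
#' rosters are valid). The number of parameters counted in the AIC is
#' the number of fixed effects plus the three random-intercept
#' variances plus the residual variance.
#'
#' @param frame a `model_frame` from [build_frame()].
#' @param spec an `lmm_spec`.
#' @return an `lmm_fit`: fixed-effect table (`estimate`, `se`, `t`),
#'   random-intercept and residual SDs, `logLik`, `nparam`, `aic`,
#'   `n_obs`, `converged`, and the underlying `merMod` object.
#' @export
fit_lmm <- function(frame, spec) {
  missing_cols <- setdiff(setdiff(spec$fixed, "length:freq"), names(frame))
  if (length(missing_cols) > 0L) {
    stop_param("frame lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            check.conv.singular = "ignore")
  fit <- lme4::lmer(spec_formula(spec), data = frame, REML = FALSE,
                    control = ctrl)
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sds <- setNames(vc$sdcor, vc$grp)
  ll <- as.numeric(logLik(fit))
  npar <- length(cf) + 4L               # 3 random intercepts + residual
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L &&
    fit@optinfo$conv$opt == 0L
  structure(list(name = spec$name, spec = spec,
                 fixef = data.frame(term = names(cf), estimate = unname(cf),
                                    se = unname(se),
                                    t = unname(cf / se)),
                 sd_subj = unname(sds[["sujid"]]),
                 sd_text = unname(sds[["textid"]]),
                 sd_word = unname(sds[["wordid"]]),
                 sd_resid = unname(sds[["Residual"]]),
                 logLik = ll, nparam = npar,
                 aic = -2 * ll + 2 * npar,
                 n_obs = stats::nobs(fit),
                 converged = conv, model = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s: n=%d, logLik=%.2f, AIC=%.2f%s\n",
              x$name, x$n_obs, x$logLik, x$aic,
              if (x$converged) "" else " (NOT converged)"))
  print(x$fixef, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio comparison of two nested ML fits
#'
#' @param fit_full,fit_reduced `lmm_fit`s on the identical frame (equal
#'   `n_obs`); the reduced fixed terms must nest inside the full ones.
#' @return list `(chi2, df, p)` with `chi2 = 2 (logLik_full -
#'   logLik_reduced)` and a chi-squared tail p-value.
#' @export
compare_lmm <- function(fit_full, fit_reduced) {
  if (!fit_full$converged || !fit_reduced$converged) {
    stop_param("refusing to compare non-converged fits")
  }
  if (fit_full$n_obs != fit_reduced$n_obs) {
    stop_param("fits use different numbers of observations (",
               fit_full$n_obs, " vs ", fit_reduced$n_obs,
               "); refit both on one shared complete-case frame")
  }
  if (!all(fit_reduced$spec$fixed %in% fit_full$spec$fixed)) {
    stop_param("models are not nested")
  }
  chi2 <- max(0, 2 * (fit_full$logLik - fit_reduced$logLik))
  df <- fit_full$nparam - fit_reduced$nparam
  p <- if (df == 0L) 1 else pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Remove estimated fixed effects from the response
#'
#' Returns `y - X beta-hat`: the response with every fixed-effect
#' prediction (including the intercept) subtracted, while the random
#' effect structure stays in the data — the residuals are meant to be
#' refitted with the same random factors.
#'
#' @param fit an `lmm_fit`.
#' @param frame the frame it was fitted on.
#' @return numeric residual vector aligned with the frame rows.
#' @export
remef_residuals <- function(fit, frame) {
  X <- model.matrix(fit$model)
  beta <- lme4::fixef(fit$model)
  frame$y - as.vector(X %*% beta)
}

#' Refit cloze predictability on fixed-effect-removed residuals
#'
#' Fits `residual ~ cloze + (1|sujid) + (1|textid) + (1|wordid)`: the
#' cloze t-value of this refit measures how much cloze-shaped variance
#' the removed model left unexplained. A model whose predictors already
#' capture cloze predictability leaves residuals on which this t-value
#' collapses.
#'
#' @param residuals vector from [remef_residuals()].
#' @param frame the matching `model_frame`.
#' @param pred_col the cloze column (default `"cloze_n"`).
#' @return an `lmm_fit` for the single-predictor model.
#' @export
refit_cloze <- function(residuals, frame, pred_col = "cloze_n") {
  if (length(residuals) != nrow(frame)) {
    stop_param("residuals are not aligned with the frame")
  }
  if (!pred_col %in% names(frame)) stop_param("frame lacks ", pred_col)
  f2 <- frame
  f2$y <- residuals
  spec <- lmm_spec(paste0("refit:", pred_col))
  spec$fixed <- pred_col
  spec$extra <- pred_col
  fit_lmm(f2, spec)
}

#' Roster-wide results tables
#'
#' Assembles, across a list of fits on one shared frame: the
#' fixed-effect t-value matrix, the AIC difference of every model
#' against the baseline, likelihood-ratio p-values against the baseline
#' and against the cloze model (where nested), and optionally the
#' residual-refit cloze t-values.
#'
#' @param fits named list of `lmm_fit`s (same frame).
#' @param baseline,cloze names of the baseline and cloze models within
#'   `fits`.
#' @param refit_t optional named numeric vector of residual-refit
#'   t-values per model.
#' @return list of data.frames: `tvalues`, `delta_aic`, `lrt`,
#'   `refit` (if given).
#' @export
report_roster <- function(fits, baseline = names(fits)[1],
                          cloze = NULL, refit_t = NULL) {
  n_obs <- unique(vapply(fits, `[[`, numeric(1), "n_obs"))
  if (length(n_obs) != 1L) {
    stop_param("fits were made on different frames (n_obs differ)")
  }
  terms <- unique(unlist(lapply(fits, function(f) f$fixef$term)))
  tmat <- sapply(fits, function(f) {
    setNames(f$fixef$t, f$fixef$term)[terms]
  })
  rownames(tmat) <- terms
  delta_aic <- data.frame(
    model = names(fits),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    delta_aic = vapply(fits, `[[`, numeric(1), "aic") -
      fits[[baseline]]$aic,
    row.names = NULL)
  lrt <- do.call(rbind, lapply(names(fits), function(nm) {
    vs_base <- if (nm != baseline &&
                   all(fits[[baseline]]$spec$fixed %in%
                       fits[[nm]]$spec$fixed)) {
      compare_lmm(fits[[nm]], fits[[baseline]])$p
    } else NA_real_
    vs_cloze <- if (!is.null(cloze) && nm != cloze &&
                    all(fits[[cloze]]$spec$fixed %in%
                        fits[[nm]]$spec$fixed)) {
      compare_lmm(fits[[nm]], fits[[cloze]])$p
    } else NA_real_
    data.frame(model = nm, p_vs_baseline = vs_base, p_vs_cloze = vs_cloze)
  }))
  out <- list(tvalues = as.data.frame(tmat), delta_aic = delta_aic,
              lrt = lrt)
  if (!is.null(refit_t)) {
    out$refit <- data.frame(model = names(refit_t),
                            refit_cloze_t = unname(refit_t))
  }
  out
}
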