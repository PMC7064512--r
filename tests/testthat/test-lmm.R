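# shared fixture: one simulated reading study with known coefficients
lmm_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    study <- fixture_study(n_texts = 4, words = 300)
    tl <- true_logits(study$test)
    cfg <- gaze_config(n_subjects = 12, seed = 81)
    fx <- sample_gaze(study$test, study$features, tl$n, tl$n1, cfg)
    frame <- build_frame(fx, study$test, study$features,
                         preds = list(pred = tl$n))
    cache <<- list(study = study, tl = tl, fx = fx, frame = frame,
                   cfg = cfg)
    cache
  }
})

test_that("frame building applies the exclusion and complete-case rules", {
  co <- tokenize_corpus("ab uno dos tres cuatro. cinco seis siete ocho nueve diez fin.")
  f <- compute_features(co, build_frequency_table(co))
  fx <- data.table::data.table(subj_id = 1L, text_id = 1L,
                               token_idx = 0:(nrow(co$tokens) - 1L),
                               dur_ms = 200, launch_site = 2)
  fr <- build_frame(fx, co, f, min_length = 3)
  kept <- as.integer(sub("^1:", "", levels(fr$wordid)[fr$wordid]))
  expect_false(0L %in% kept)                 # 2-letter word dropped
  expect_true(1L %in% kept)                  # sentence- and line-interior
  # sentence boundaries: first and last tokens of each sentence are out
  expect_false(4L %in% kept)                 # "cuatro" sentence-final
  expect_false(5L %in% kept)                 # "cinco" sentence-initial
  expect_false(max(fx$token_idx) %in% kept)  # text-final token
  expect_equal(fr$y, rep(log(200), nrow(fr)))
  # centered covariates have mean zero
  for (cc in c("launch_site", "length", "freq", "rpl", "rpt", "rps")) {
    expect_lt(abs(mean(fr[[cc]])), 1e-10)
  }
})

test_that("rows missing any roster column become incomplete cases", {
  fix <- lmm_fixture()
  n_tok <- nrow(fix$study$test$tokens)
  # a predictor with a hole: every row for that token (and the token
  # before it, through the N+1 column) must fall out
  hole <- rep(0, n_tok)
  hole[50] <- NA
  fr <- build_frame(fix$fx, fix$study$test, fix$study$features,
                    preds = list(h = hole))
  tok50 <- fix$study$test$tokens[50]
  wid <- paste(tok50$text_id, tok50$tok_text, sep = ":")
  wid_prev <- paste(tok50$text_id, tok50$tok_text - 1L, sep = ":")
  expect_false(wid %in% as.character(fr$wordid))
  expect_false(wid_prev %in% as.character(fr$wordid))
  # pred columns are centered too
  expect_lt(abs(mean(fr$h_n)), 1e-10)
  expect_lt(abs(mean(fr$h_n1)), 1e-10)
})

test_that("ml fits match ols when the variance estimates collapse to zero", {
  # With no generative random effects the ML variance estimates sit at
  # the boundary: they collapse to exactly 0 for roughly half the
  # samples per component, and conditional on that collapse the mixed
  # model IS ordinary least squares. Scan seeds until a collapsed fit
  # appears and verify the equivalence there.
  study <- fixture_study(n_texts = 3, words = 250)
  tl <- true_logits(study$test)
  found <- FALSE
  for (s in 91:106) {
    cfg <- gaze_config(sigma_subj = 0, sigma_text = 0, sigma_word = 0,
                       sigma_resid = 0.3, n_subjects = 10, seed = s)
    fx <- sample_gaze(study$test, study$features, tl$n, tl$n1, cfg)
    fr <- build_frame(fx, study$test, study$features,
                      preds = list(pred = tl$n))
    fit <- fit_lmm(fr, lmm_spec("zv", c("pred_n", "pred_n1")))
    if (max(fit$sd_subj, fit$sd_text, fit$sd_word) > 1e-8) next
    found <- TRUE
    ols <- lm(y ~ launch_site + length * freq + rpl + rpt + rps +
                pred_n + pred_n1, data = fr)
    b_lmm <- setNames(fit$fixef$estimate, fit$fixef$term)
    b_ols <- coef(ols)[fit$fixef$term]
    expect_equal(b_lmm, b_ols, tolerance = 1e-4)
    # ML residual variance uses n, OLS uses n - p: SEs differ only by
    # that degrees-of-freedom factor
    se_ols <- sqrt(diag(vcov(ols)))[fit$fixef$term]
    dof <- sqrt(fit$n_obs / (fit$n_obs - length(b_ols)))
    expect_equal(setNames(fit$fixef$se, fit$fixef$term) * dof, se_ols,
                 tolerance = 1e-4)
    # remef residuals are orthogonal to every fixed-effect column here
    r <- remef_residuals(fit, fr)
    X <- model.matrix(ols)
    for (j in 2:ncol(X)) expect_lt(abs(cor(r, X[, j])), 1e-4)
    expect_lt(abs(mean(r)), 1e-6)
    break
  }
  expect_true(found)
})

test_that("fit summaries obey the AIC identity and the t definition", {
  fix <- lmm_fixture()
  fit <- fit_lmm(fix$frame, lmm_spec("M1", "pred_n"))
  expect_identical(fit$aic, -2 * fit$logLik + 2 * fit$nparam)
  expect_equal(fit$nparam, nrow(fit$fixef) + 4L)
  expect_equal(fit$aic, AIC(fit$model))          # lme4 agrees on nparam
  expect_equal(fit$fixef$t, fit$fixef$estimate / fit$fixef$se)
  expect_true(all(c(fit$sd_subj, fit$sd_text, fit$sd_word,
                    fit$sd_resid) >= 0))
  # the intercept of a centered frame estimates the mean log duration
  expect_equal(fit$fixef$estimate[fit$fixef$term == "(Intercept)"],
               mean(fix$frame$y), tolerance = 0.05)
})

test_that("likelihood-ratio comparison is exact on the fit roster", {
  fix <- lmm_fixture()
  f0 <- fit_lmm(fix$frame, lmm_spec("M0"))
  f1 <- fit_lmm(fix$frame, lmm_spec("M1", "pred_n"))
  f2 <- fit_lmm(fix$frame, lmm_spec("M2", c("pred_n", "pred_n1")))
  same <- compare_lmm(f1, f1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  c10 <- compare_lmm(f1, f0)
  expect_gte(c10$chi2, 0)
  expect_equal(c10$df, 1L)
  expect_equal(c10$chi2, 2 * (f1$logLik - f0$logLik))
  expect_equal(c10$p, pchisq(c10$chi2, 1, lower.tail = FALSE))
  # nesting: adding fixed effects never decreases the ML log-likelihood
  expect_gte(f1$logLik, f0$logLik - 1e-6)
  expect_gte(f2$logLik, f1$logLik - 1e-6)
  expect_error(compare_lmm(f0, f1), "nested")
  # refuse fits on different frames
  sub <- fix$frame[-seq_len(10), ]
  attr(sub, "class") <- class(fix$frame)
  f0b <- fit_lmm(sub, lmm_spec("M0"))
  expect_error(compare_lmm(f1, f0b), "observations")
})

test_that("the roster reproduces the published model structure", {
  ro <- build_roster()
  expect_named(ro, paste0("M", 0:8, ".N"))
  expect_equal(ro[["M0.N"]]$fixed,
               c("launch_site", "length", "freq", "length:freq",
                 "rpl", "rpt", "rps"))
  expect_equal(ro[["M1.N"]]$extra, "cloze_n")
  combs <- lapply(ro[paste0("M", 5:8, ".N")], `[[`, "extra")
  expect_equal(lengths(combs), c(M5.N = 2L, M6.N = 2L, M7.N = 2L,
                                 M8.N = 3L))
  ro1 <- build_roster(n1 = TRUE)
  expect_length(ro1, 10L)
  expect_equal(ro1[["M2.N+1"]]$extra, c("ngram_n", "ngram_n1"))
  expect_equal(ro1[["M9.N+1"]]$extra, c("ngram_n", "ft_n1"))
  expect_error(build_roster(scores = c(cloze = "a")), "scores")
})

test_that("removing fitted fixed effects absorbs the predictability signal", {
  fix <- lmm_fixture()
  f0 <- fit_lmm(fix$frame, lmm_spec("M0"))
  f1 <- fit_lmm(fix$frame, lmm_spec("M1", "pred_n"))
  r0 <- remef_residuals(f0, fix$frame)
  r1 <- remef_residuals(f1, fix$frame)
  t0 <- refit_cloze(r0, fix$frame, "pred_n")$fixef$t[2]
  t1 <- refit_cloze(r1, fix$frame, "pred_n")$fixef$t[2]
  # the generator used pred_n: baseline residuals keep its signal,
  # residuals of the model that includes it do not
  expect_gt(abs(t0), 2)
  expect_lt(abs(t1), abs(t0))
  expect_lt(abs(t1), 2)
  expect_error(refit_cloze(r0[-1], fix$frame, "pred_n"), "align")
})

test_that("report tables are internally consistent", {
  fix <- lmm_fixture()
  fits <- list(
    M0 = fit_lmm(fix$frame, lmm_spec("M0")),
    M1 = fit_lmm(fix$frame, lmm_spec("M1", "pred_n")))
  tabs <- report_roster(fits, baseline = "M0", cloze = "M1")
  expect_equal(tabs$delta_aic$delta_aic[1], 0)
  expect_equal(tabs$delta_aic$delta_aic[2],
               fits$M1$aic - fits$M0$aic)
  # recomputable from the stored logLik and nparam
  expect_equal(tabs$delta_aic$aic,
               vapply(fits, function(f) -2 * f$logLik + 2 * f$nparam,
                      numeric(1)),
               ignore_attr = TRUE)
  # the generator included the predictor: its model wins on AIC
  expect_lt(tabs$delta_aic$delta_aic[2], 0)
  expect_lt(tabs$lrt$p_vs_baseline[2], 0.05)
  expect_true(is.na(tabs$lrt$p_vs_baseline[1]))
})
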