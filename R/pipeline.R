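# Configuration-driven orchestration of the full chain:
# simulate -> features -> cloze -> LM / embedding scores -> LMM roster
# -> report, with a manifest and reproducible seeds. The default
# configuration runs entirely on synthetic data with known ground truth.

#' Default pipeline configuration
#'
#' A single nested list drives the whole run; it can be loaded from and
#' saved to YAML or JSON (`read_run_config()` / `write_run_config()`).
#' All randomness flows from `seed` (stage seeds are derived from it by
#' fixed offsets). The default sizes emulate a short-story reading
#' study at desk scale: a handful of texts of a few hundred words, a
#' larger independent training corpus for the language model and the
#' embeddings, a few dozen cloze responders per word, and a few dozen
#' readers.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master integer seed.
#' @return a `run_config` list.
#' @export
default_run_config <- function(out_dir = "gazepred_run", seed = 1L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    language = list(vocab_size = 60L, order = 2L, concentration = 0.12,
                    sent_mean = 12, sent_min = 3, sent_max = 30),
    corpus = list(n_texts = 6L, words_per_text = 300L,
                  train_texts = 40L, train_words_per_text = 2500L),
    tokenizer = list(lowercase = TRUE, strip_accents = FALSE,
                     wrap_width = 60L),
    cloze = list(responses_per_word = 30L, guess_noise = 0.1,
                 min_answers = 8L),
    ngram = list(n_order = 3L, gt_max_r = 5L, delta = 0.00015,
                 lambda = 0.15,
                 delta_grid = c(5e-05, 1.5e-04, 5e-04),
                 lambda_grid = c(0.05, 0.15, 0.3, 0.6)),
    embeddings = list(d = 30L, idf = "smooth",
                      windows = c(1L, 5L, 9L, 25L, 50L),
                      variant = "mean", stopword_policy = "with"),
    gaze = list(n_subjects = 20L, texts_per_subject = NULL,
                sigma_subj = 0.15, sigma_text = 0.05, sigma_word = 0.08,
                sigma_resid = 0.35),
    lmm = list(length_inverse = TRUE, min_length = 3L, n1 = TRUE)),
    class = "run_config")
}

#' @rdname default_run_config
#' @param path a YAML (`.yml`/`.yaml`) or JSON file.
#' @param config a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_run_config()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      for (sub in names(cfg[[nm]])) base[[nm]][[sub]] <- cfg[[nm]][[sub]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

#' @rdname default_run_config
#' @export
write_run_config <- function(config, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; returns findings rather than raising,
#' so a caller can distinguish warnings from errors.
#'
#' @param config a `run_config`.
#' @return data.frame `(level, field, message)`; zero rows when the
#'   configuration is clean.
#' @export
validate_run_config <- function(config) {
  f <- list()
  bad <- function(field, message, level = "error") {
    f[[length(f) + 1L]] <<- data.frame(level = level, field = field,
                                       message = message)
  }
  num_in <- function(x, lo, hi) is.numeric(x) && all(is.finite(x)) &&
    all(x >= lo) && all(x <= hi)
  if (!num_in(config$ngram$lambda, 0, 1)) {
    bad("ngram.lambda", "lambda must lie in [0, 1]")
  }
  if (!num_in(config$ngram$lambda_grid, 0, 1)) {
    bad("ngram.lambda_grid", "lambda grid values must lie in [0, 1]")
  }
  if (!num_in(config$ngram$delta, 0, Inf)) {
    bad("ngram.delta", "delta must be nonnegative")
  }
  if (!num_in(config$ngram$delta_grid, 0, Inf)) {
    bad("ngram.delta_grid", "delta grid values must be nonnegative")
  }
  if (!num_in(config$embeddings$windows, 1, Inf)) {
    bad("embeddings.windows", "context windows must be >= 1")
  }
  if (!num_in(config$language$vocab_size, 10, Inf)) {
    bad("language.vocab_size", "vocabulary must have at least 10 words")
  }
  if (!num_in(config$language$concentration, 1e-12, Inf)) {
    bad("language.concentration", "concentration must be positive")
  }
  if (!num_in(config$gaze$n_subjects, 2, Inf)) {
    bad("gaze.n_subjects", "need at least 2 subjects")
  }
  if (!num_in(config$cloze$min_answers, 1, Inf)) {
    bad("cloze.min_answers", "min_answers must be >= 1")
  }
  if (num_in(config$cloze$responses_per_word, 1, Inf) &&
      num_in(config$cloze$min_answers, 1, Inf) &&
      config$cloze$responses_per_word < config$cloze$min_answers) {
    bad("cloze.responses_per_word",
        "fewer responses per word than min_answers: every token excluded",
        level = "warning")
  }
  if (length(f) == 0L) {
    data.frame(level = character(0), field = character(0),
               message = character(0))
  } else {
    do.call(rbind, f)
  }
}

PIPELINE_STAGES <- c("simulate", "features", "cloze", "ngram",
                     "embeddings", "lmm", "report")

#' Run the pipeline
#'
#' Executes the requested stages in dependency order on the synthetic
#' study defined by `config`, writing every artifact (corpus files,
#' response/fixation/score tables, fit summaries, report tables) under
#' `config$out_dir` together with a JSON manifest recording the
#' configuration, the seeds and the MD5 of every output file.
#' Re-running with an identical configuration reproduces byte-identical
#' tables. Requesting a stage whose upstream artifacts are absent (and
#' not scheduled) raises a dependency error naming the stage.
#'
#' @param config a `run_config`.
#' @param stages subset of `c("simulate", "features", "cloze", "ngram",
#'   "embeddings", "lmm", "report")`.
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = PIPELINE_STAGES, quiet = FALSE) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  findings <- validate_run_config(config)
  if (any(findings$level == "error")) {
    stop_param("invalid configuration:\n",
               paste(sprintf("- %s: %s", findings$field, findings$message),
                     collapse = "\n"))
  }
  say <- function(...) if (!quiet) message(...)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  art <- function(...) file.path(out, ...)
  state <- new.env(parent = emptyenv())
  seed <- as.integer(config$seed)

  tokcfg <- tokenizer_config(config$tokenizer$lowercase,
                             config$tokenizer$strip_accents,
                             config$tokenizer$wrap_width)

  need <- function(stage, loader) {
    # an upstream product: take it from this run, else load the artifact,
    # else fail naming the missing stage
    if (!is.null(state[[stage]])) return(state[[stage]])
    val <- tryCatch(loader(), error = function(e) NULL)
    if (is.null(val)) {
      stop_param("stage dependency error: required artifacts of stage '",
                 stage, "' not found under ", out,
                 " (run it first or include it in `stages`)")
    }
    state[[stage]] <- val
    val
  }

  lang <- make_language(config$language$vocab_size, config$language$order,
                        config$language$concentration, seed = seed,
                        sent_mean = config$language$sent_mean,
                        sent_min = config$language$sent_min,
                        sent_max = config$language$sent_max)

  if ("simulate" %in% stages) {
    say("simulate: sampling corpora, cloze responses and fixations")
    test_corpus <- sample_corpus(lang, config$corpus$n_texts,
                                 config$corpus$words_per_text,
                                 seed = seed + 1L, config = tokcfg)
    train_corpus <- sample_corpus(lang, config$corpus$train_texts,
                                  config$corpus$train_words_per_text,
                                  seed = seed + 2L, config = tokcfg)
    responses <- sample_cloze_responses(lang, test_corpus,
                                        config$cloze$responses_per_word,
                                        config$cloze$guess_noise,
                                        seed = seed + 3L)
    freq <- build_frequency_table(train_corpus)
    feats <- compute_features(test_corpus, freq)
    true_logit <- logit(test_corpus$tokens$true_pred)
    gcfg <- gaze_config(n_subjects = config$gaze$n_subjects,
                        texts_per_subject = config$gaze$texts_per_subject,
                        sigma_subj = config$gaze$sigma_subj,
                        sigma_text = config$gaze$sigma_text,
                        sigma_word = config$gaze$sigma_word,
                        sigma_resid = config$gaze$sigma_resid,
                        seed = seed + 4L)
    pred_n1 <- c(true_logit[-1], NA)
    pred_n1[diff(c(test_corpus$tokens$text_id, Inf)) != 0] <- NA
    fixations <- sample_gaze(test_corpus, feats, true_logit, pred_n1, gcfg)
    write_corpus(test_corpus, art("corpus"))
    write_corpus(train_corpus, art("train_corpus"))
    write_tsv(test_corpus$tokens[, .(text_id, token_idx = tok_text,
                                     true_pred)],
              art("true_pred.tsv"))
    write_cloze_table(responses, art("cloze_responses.tsv"))
    write_fixation_table(fixations, art("fixations.tsv"))
    write_frequency_table(freq, art("frequency.tsv"))
    state$simulate <- list(test_corpus = test_corpus,
                           train_corpus = train_corpus,
                           responses = responses, fixations = fixations,
                           freq = freq)
  }

  load_simulate <- function() {
    test_corpus <- read_corpus(art("corpus"), tokcfg)
    tp <- read_tsv_checked(art("true_pred.tsv"),
                           c("text_id", "token_idx", "true_pred"),
                           c("text_id", "token_idx", "true_pred"))
    test_corpus$tokens[, true_pred := tp$true_pred]
    list(test_corpus = test_corpus,
         train_corpus = read_corpus(art("train_corpus"), tokcfg),
         responses = read_cloze_table(art("cloze_responses.tsv")),
         fixations = read_fixation_table(art("fixations.tsv")),
         freq = read_frequency_table(art("frequency.tsv")))
  }

  if ("features" %in% stages) {
    say("features: per-token covariates")
    sim <- need("simulate", load_simulate)
    feats <- compute_features(sim$test_corpus, sim$freq)
    write_tsv(feats, art("features.tsv"))
    state$features <- feats
  }
  load_features <- function() {
    f <- read_tsv_checked(art("features.tsv"),
                          c("text_id", "tok_text", "length", "inv_length",
                            "log_freq", "repetition", "rps", "rpl", "rpt"),
                          c("length", "inv_length", "log_freq",
                            "repetition", "rps", "rpl", "rpt"))
    f[, `:=`(text_id = as.integer(text_id), tok_text = as.integer(tok_text))]
    f
  }

  if ("cloze" %in% stages) {
    say("cloze: aggregating responses")
    sim <- need("simulate", load_simulate)
    cp <- aggregate_cloze(sim$responses, sim$test_corpus,
                          config$cloze$min_answers)
    write_cloze_pred(cp, art("cloze_pred.tsv"))
    state$cloze <- cp
  }
  load_cloze <- function() read_cloze_pred(art("cloze_pred.tsv"))

  if ("ngram" %in% stages) {
    say("ngram: training Katz model and scoring")
    sim <- need("simulate", load_simulate)
    model <- train_ngram(sim$train_corpus, config$ngram$n_order,
                         config$ngram$gt_max_r)
    write_arpa(model, art("model.arpa"))
    scores <- score_text(model, sim$test_corpus, config$ngram$delta,
                         config$ngram$lambda)
    write_tsv(scores, art("ngram_scores.tsv"))
    truth <- sim$test_corpus$tokens$true_pred
    gs <- grid_search(model, sim$test_corpus,
                      function(p, corpus) cor(logit(pmin(pmax(p, 1e-12),
                                                         1 - 1e-12)),
                                              logit(truth)),
                      config$ngram$delta_grid, config$ngram$lambda_grid)
    write_tsv(gs, art("ngram_grid.tsv"))
    state$ngram <- scores
  }
  load_ngram <- function() {
    s <- read_tsv_checked(art("ngram_scores.tsv"),
                          c("text_id", "token_idx", "p_ngram", "p_cache",
                            "p_combined"),
                          c("text_id", "token_idx", "p_ngram", "p_cache",
                            "p_combined"))
    s[, `:=`(text_id = as.integer(text_id), token_idx = as.integer(token_idx))]
    s
  }

  if ("embeddings" %in% stages) {
    say("embeddings: LSA training and CS scoring")
    sim <- need("simulate", load_simulate)
    space <- train_lsa(sim$train_corpus, config$embeddings$d,
                       idf = config$embeddings$idf)
    write_vectors(space, art("lsa_vectors.txt"))
    truth <- sim$test_corpus$tokens$true_pred
    sweep <- window_sweep(space, sim$test_corpus,
                          function(s, corpus)
                            cor(s, logit(truth), use = "complete.obs"),
                          windows = config$embeddings$windows,
                          variants = config$embeddings$variant,
                          stopword_policies = config$embeddings$stopword_policy,
                          stopwords = lang$stopwords)
    write_tsv(sweep, art("cs_sweep.tsv"))
    best <- attr(sweep, "best")
    cs_short <- cs_score(space, sim$test_corpus, best$window, best$variant,
                         best$stopword_policy, lang$stopwords)
    w_long <- max(config$embeddings$windows)
    cs_long <- cs_score(space, sim$test_corpus, w_long, best$variant,
                        best$stopword_policy, lang$stopwords)
    cs <- data.table(text_id = sim$test_corpus$tokens$text_id,
                     token_idx = sim$test_corpus$tokens$tok_text,
                     cs_short = cs_short, cs_long = cs_long)
    write_tsv(cs, art("cs_scores.tsv"))
    state$embeddings <- cs
  }
  load_embeddings <- function() {
    s <- read_tsv_checked(art("cs_scores.tsv"),
                          c("text_id", "token_idx", "cs_short", "cs_long"),
                          c("text_id", "token_idx", "cs_short", "cs_long"))
    s[, `:=`(text_id = as.integer(text_id), token_idx = as.integer(token_idx))]
    s
  }

  if (any(c("lmm", "report") %in% stages)) {
    say("lmm: fitting the model roster")
    sim <- need("simulate", load_simulate)
    feats <- need("features", load_features)
    cp <- need("cloze", load_cloze)
    ng <- need("ngram", load_ngram)
    cs <- need("embeddings", load_embeddings)
    tok <- sim$test_corpus$tokens
    key <- paste(tok$text_id, tok$tok_text)
    align <- function(tab, col) {
      v <- tab[[col]][match(key, paste(tab$text_id, tab$token_idx))]
      v
    }
    cloze_v <- align(as.data.table(cp)[included == TRUE], "logit_pred")
    preds <- list(
      cloze = cloze_v,
      ngram = logit(pmin(pmax(align(ng, "p_combined"), 1e-12), 1 - 1e-12)),
      lsa = align(cs, "cs_short"),
      ft = align(cs, "cs_long"))
    frame <- build_frame(sim$fixations, sim$test_corpus, feats, preds,
                         length_inverse = config$lmm$length_inverse,
                         min_length = config$lmm$min_length)
    roster <- build_roster(n1 = isTRUE(config$lmm$n1))
    fits <- lapply(roster, function(sp) fit_lmm(frame, sp))
    fit_tab <- rbindlist(lapply(fits, function(f)
      data.table(model = f$name, f$fixef, logLik = f$logLik,
                 nparam = f$nparam, aic = f$aic, n_obs = f$n_obs,
                 converged = f$converged)))
    write_tsv(fit_tab, art("lmm_fits.tsv"))
    state$lmm <- list(fits = fits, frame = frame)
  }

  if ("report" %in% stages) {
    say("report: model comparison tables")
    fits <- state$lmm$fits
    frame <- state$lmm$frame
    base_nm <- names(fits)[1]
    cloze_nm <- intersect(c("M1.N", "M1.N+1"), names(fits))[1]
    refit_t <- vapply(names(fits), function(nm) {
      r <- remef_residuals(fits[[nm]], frame)
      refit_cloze(r, frame)$fixef$t[2]
    }, numeric(1))
    tables <- report_roster(fits, baseline = base_nm, cloze = cloze_nm,
                            refit_t = refit_t)
    write_tsv(data.table(term = rownames(tables$tvalues), tables$tvalues),
              art("report_tvalues.tsv"))
    write_tsv(as.data.table(tables$delta_aic), art("report_delta_aic.tsv"))
    write_tsv(as.data.table(tables$lrt), art("report_lrt.tsv"))
    write_tsv(as.data.table(tables$refit), art("report_refit.tsv"))
    state$report <- tables
  }

  files <- sort(list.files(out, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    config = unclass(config),
    seed = seed,
    stages = stages,
    files = data.frame(path = sub(paste0("^", out, "/?"), "", files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
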