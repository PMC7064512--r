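---
title: "Estimating word predictability and evaluating it on gaze durations"
author: "gazepred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating word predictability and evaluating it on gaze durations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and the analysis it supports

Word *predictability* — the probability of guessing a word from its
preceding context — modulates how long readers fixate a word. The
package implements two computational families of predictability
estimates and a statistical harness that evaluates them exactly as a
reading study would: as fixed effects in linear mixed models (LMMs) of
log gaze duration with crossed random intercepts for subject, text and
word token,

```
log(duration) ~ LaunchSite + Length * Frequency + rpl + rpt + rps
                + <predictability terms>
                + (1 | sujid) + (1 | textid) + (1 | wordid)
```

where `rps`, `rpl` and `rpt` are the word's relative positions in its
sentence, display line and text, rescaled to [0, 1]. The roster
`M0`–`M9` grows this baseline with cloze predictability, the
N-gram+cache score, and two embedding cosine-similarity scores, singly
and in combination, for the fixated word N and the upcoming word N+1;
models are compared by AIC and likelihood-ratio tests, and a
fixed-effect-removal analysis (`remef_residuals()` + `refit_cloze()`)
asks how much *cloze-shaped* variance each computational score already
absorbed.

Because the human data such a study needs are expensive, the package
ships a synthetic-data generator with exact ground truth. Every
assumption below is therefore testable: the generator defines the true
next-word probabilities, the true cloze process, and the true gaze
model, and the test suite verifies that each stage recovers them.

# The N-gram + cache predictability score

`train_ngram()` builds a Katz back-off model of order N. k-gram counts
are taken over sentence-padded streams (each sentence prefixed by
N−1 `<s>` markers, so no k-gram crosses a sentence boundary and `<s>`
is never predicted). Counts r ≤ `gt_max_r` (default 5, the usual Katz
practice) are replaced by Good-Turing discounted counts
r\* = (r+1)·N~r+1~/N~r~ from the counts-of-counts; larger counts are
trusted as is. When a counts-of-counts cell is empty or the discount
would exceed the raw count, that count is left undiscounted. The
discounted mass of each context funnels into a back-off weight α chosen
so the conditional distribution sums to one exactly; a context whose
observed words already cover the entire lower-order mass keeps its
undiscounted MLE and gets α = 0. The unigram level is maximum
likelihood over the training vocabulary; out-of-vocabulary words can be
handled by mapping training singletons to an `<unk>` type
(`unk_singletons = TRUE`). Models round-trip through the standard ARPA
text format (`write_arpa()` / `read_arpa()`), including pseudo-entries
for `<s>`-prefixed contexts that carry a back-off weight without being
predictable events themselves, so external language-model toolkits can
cross-check the tables.

The cache is an additively smoothed unigram over the text read so far:
p = (c(w) + δ)/(δV + N). Two conventions the literature leaves open are
fixed here and tested: the cache is **reset at each text start**, and it
is updated with a word only **after** that word has been scored, so a
word never predicts itself. V counts the training vocabulary plus any
novel words already read in the current text, so in-text neologisms
receive cache mass. With an empty cache and δ > 0 the cache is uniform
(1/V); δ = 0 with an empty cache is undefined and raises an error.
`score_text()` combines the two sources as λ·p~cache~ + (1−λ)·p~ngram~,
and `grid_search()` sweeps (δ, λ) against any scalar criterion; the
default grids span δ ∈ [5·10⁻⁵, 5·10⁻⁴] and λ ∈ [0.05, 0.6], a range
whose interior contains the optimum typically reported for running-text
gaze analyses (δ = 1.5·10⁻⁴, λ = 0.15), and the search reports the
argmax by absolute criterion while persisting the full table.

# Embedding cosine-similarity scores

`train_lsa()` builds the word-by-document count matrix, applies tf-idf
(tf = raw count, idf = log(n_docs/df)) and truncates to rank d by SVD.
Word vectors are rows of U·S by default: scaling by the singular values
preserves the full-rank geometry exactly, which gives the package a
sharp correctness oracle (at full rank, cosine similarities equal those
of the tf-idf rows). The classic idf is the default, but on a small
closed-vocabulary corpus every word can occur in every document, making
the classic weighting identically zero; `idf = "smooth"`
(log(n_docs/df) + 1) keeps such corpora usable and is what the
synthetic pipeline configuration uses. Words whose weighted profile is
all-zero are dropped from the space rather than stored as zero vectors.

`cs_score()` scores token i as the cosine similarity between its vector
and its context: the `window` preceding tokens of the same text
(`stopword_policy = "without"` first removes stopwords and then gathers
`window` *content* words). The `mean` variant averages pairwise
cosines; the `resultant` variant takes the cosine to the summed context
vector; the two coincide at window 1. Out-of-vocabulary context words
are skipped so they neither dilute nor inflate the mean, and a token
with an empty usable context (e.g. the first token of a text) is marked
missing and later becomes an incomplete case. `window_sweep()` runs any
criterion over windows — by default a grid inside [1, 150] that
includes the window sizes usually selected for LSA-type (w ≈ 9) and
FastText-type (w ≈ 50) spaces.

Skipgram/FastText training is deliberately out of scope: those vectors
are consumed from the word2vec text format (`read_vectors()`), because
the package's contribution is the context scoring and the evaluation,
not neural embedding training.

# Cloze aggregation

`aggregate_cloze()` scores a response as correct when its
tokenizer-normalized form equals the token's normalized form — exact
match is the reproducible default and the matching rule is confined to
one function. Tokens with fewer than `min_answers = 8` answers are
flagged excluded rather than dropped, and a token with zero answers
carries `NA`, never a propagating NaN. Proportions are transformed by
the empirical logit, logit((k + 0.5)/(n + 1)), so 0 and 1 stay finite.
`covariation_summary()` bins the logit predictability by word
properties (repetition, log frequency, inverse length, sentence
position) with a per-bin standard error of the mean — the standard
sanity plot that frequent, short, repeated and late-in-sentence words
are more predictable.

# The synthetic study

`make_language()` draws an order-k Markov language: for every context
length 0..k and every context, the next-word distribution is an
independent Dirichlet draw. Two design choices matter:

* **Zipf-weighted base measure.** The Dirichlet parameter of the word
  with frequency rank r is proportional to `concentration / r^zipf_s`
  (`zipf_s = 1` by default). This makes word frequencies Zipfian and —
  because frequent words carry genuinely larger conditional
  probabilities across contexts — builds in the
  frequency-predictability covariation that real lexicons show.
  `zipf_s = 0` recovers the symmetric Dirichlet.
* **Log-space Dirichlet sampling.** Peaked languages need tiny Dirichlet
  shapes, where `rgamma()` underflows to zero. Draws therefore use the
  exact augmentation Gamma(a) = Gamma(a+1) · U^{1/a} in log space, so a
  concentration of 10⁻⁵ yields genuine near-one-hot conditionals
  instead of accidentally uniform ones.

Tokens near a text start use the shorter-context tables, so the exact
generative probability (`true_pred`) of *every* token is known. The
chain persists across sentence boundaries; sentences (lengths
truncated-normal between configurable bounds) and greedily wrapped
display lines only define the positional covariates. Word strings are
synthetic consonant-vowel syllables with lengths spread over 1–12
letters so length-based covariates vary and are independent of
frequency rank.

Simulated cloze responders sample from
(1−guess_noise)·P(w|context) + guess_noise·uniform. Simulated gaze
durations follow the analysis model exactly: a linear predictor over
centered covariates with configurable coefficients
(`default_gaze_beta()`: intercept 5.5 → ≈ 245 ms, inverse-length −0.3,
log-frequency −0.03, length:freq 0.02, positions −0.05/−0.1/+0.03,
launch site 0.01, logit-predictability of word N −0.03 and of word N+1
−0.01), Gaussian random intercepts (SDs 0.15 subject, 0.05 text, 0.08
word token, residual 0.35 — magnitudes typical of log gaze-duration
analyses), exponentiated to milliseconds. Skipping is an independent
Bernoulli per subject × token, more likely for short predictable words,
purely to create realistic missingness; the launch site is the previous
fixated word's length plus unit-Gaussian jitter, and the frame treats
it as an opaque covariate. There is no model of saccade programming,
refixations or regressions, and no parafoveal mechanism beyond the
optional N+1 coefficient — so passing tests certify the *estimation
machinery*, not the oculomotor realism of the generator.

# The evaluation frame and model roster

`build_frame()` joins fixations, covariates and predictability scores;
filters words shorter than three letters and the first and last word of
every sentence and of every display line; takes the natural log of gaze
duration (any fixed base would only rescale coefficients); attaches
each score for word N and for word N+1 (the next token of the same
text); keeps one shared complete-case set across every roster model so
all fits use the identical data; and centers every covariate afterwards
so the intercept estimates the mean log duration. Word length enters as
1/length by default (`length_inverse = FALSE` switches to raw letters).
The word-N+1 variants of the roster duplicate each predictor for the
upcoming word; `M9` combines the N-gram+cache score for word N with the
long-window embedding score for word N+1.

Fits use `lme4::lmer` under maximum likelihood — not REML — because the
roster varies fixed effects, and REML likelihoods are not comparable
across different fixed-effect sets. AIC is −2·logLik + 2·nparam with
nparam = fixed effects + 3 random-intercept variances + 1 residual
variance (the same accounting `lme4` uses, asserted in the tests).
Single coefficients are labelled significant by |t| = |b/SE| > 2; no
degrees-of-freedom approximation is attempted. `compare_lmm()` refuses
fits with different observation counts, so complete-case mismatches
surface as errors instead of silently invalid likelihood ratios.
`remef_residuals()` returns y − Xβ̂ — all fixed effects removed, random
structure retained in the data — and `refit_cloze()` refits cloze
predictability alone with the same random intercepts on those
residuals.

# Numerical and statistical choices worth knowing

* **Boundary variance estimates.** When a generative random-effect SD
  is zero, its ML estimate collapses to exactly zero for roughly half
  of the samples (the classic half-mass-at-the-boundary behaviour), and
  *conditional on that collapse* the mixed model is ordinary least
  squares to machine precision. The equivalence tests condition on a
  collapsed fit; an unconditional comparison would fail for a correct
  implementation about half the time.
* **Coverage as a pooled property, over slopes.** Parameter-recovery
  checks pool the 95%-interval coverage across the slope coefficients
  and 20 replications (≈180 Bernoulli(≈0.95) trials) before comparing
  against 0.90; at 20 replications a per-effect threshold would reject
  correct code with high probability. The intercept is excluded by
  design: with centered covariates it estimates the mean log duration
  of the *analyzed* rows, and once skipping (which favors predictable,
  short words) and the exclusion filters shift the covariate means,
  that estimand is no longer the generative intercept. Its own identity
  — intercept ≈ mean log duration of the frame — is asserted
  separately.
* **Statistical test sizes.** The cloze-consistency demonstration uses
  a strongly predictable language (concentration 0.005): with 500
  responses per word the binomial error E|p̂−p| ≈ 0.8·√(p(1−p)/500), so
  a mean-absolute-error target of 0.01 is attainable only when p(1−p)
  is small — this is a property of the binomial, not of the
  implementation.
* **Determinism.** All randomness flows through per-call seeds; the RNG
  state is saved and restored around every generator, so identical
  seeds give bit-identical corpora, responses, fixations, and pipeline
  artifacts (verified by MD5 in the manifest).
* **Problem sizes.** The shipped test and acceptance runs use a 20–60
  word vocabulary, 10⁶ training tokens for the language-model
  consistency check, 8 texts × 375 words with 30 readers (each reading
  3 texts) for parameter recovery, and 20 seeded replications for the
  coverage, power and remef properties — sizes at which every property
  above is statistically decidable on a single CPU.

# Limitations

The generator's language is Markovian and topic-free: document-level
LSA on such a language has no topical structure to learn, so its
cosine scores carry signal mainly through word frequency. The locality
property of the window sweep (small windows win when dependencies are
strictly local) is therefore demonstrated with an embedding space that
encodes the transition geometry directly, and conclusions about
real-corpus LSA behaviour should not be drawn from the synthetic
configuration. Cache persistence across a reading session, punctuation
in the cache count, and morphological tolerance in cloze matching are
all left at the documented defaults (reset per text; word tokens only;
exact normalized match) and are configurable where the package surface
allows.
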