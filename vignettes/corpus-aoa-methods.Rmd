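---
title: "Estimating word age of acquisition from longitudinal child corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating word age of acquisition from longitudinal child corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoacorpus)
```

## The problem

The age of acquisition (AoA) of a word — when in life it is learned — is a
central variable in psycholinguistics: early-acquired words are named and
recognized faster by adults, and AoA effects are routinely invoked to argue
about how the mental lexicon is organized. Yet AoA is nearly always
measured indirectly, most often by asking adults to *estimate* when they
learned each word. `aoacorpus` implements a direct, production-based
alternative: the age at which a word first appears in a dense longitudinal
corpus of a child's recorded speech, together with the full battery needed
to assess how trustworthy such an estimate is.

The package covers five stages:

1. **Extraction** — parse CHAT-format transcripts, collect the word types
   each child produced per session, and record per-child first-occurrence
   ages.
2. **Corpus AoA** — aggregate first occurrences into per-word estimates
   under a k-child attestation threshold.
3. **Reliability** — intraclass correlation ICC(2,k) with children as
   raters, and split-half correlation across random halves of the children.
4. **Norms** — parent-report AoA50 from CDI-style curves, adult rating and
   test-based norms, child and adult log-frequency, frequency-adjusted
   corpus AoA, all joined by word.
5. **Validation** — correlation matrices, standardized regressions on
   lexical decision times with VIF diagnostics, and repeated k-fold
   cross-validation.

A synthetic-world generator with known latent acquisition ages makes every
stage testable without any external data download.

## Corpus AoA

For child $c$ and word $w$, the first-occurrence age $t_{cw}$ is the age
(in months) of the earliest session in which $c$ produced $w$. The k-child
estimate for word $w$ retains words attested in at least $k$ children and
aggregates over *all* attesting children:

* the **1-child** estimate uses the *earliest* occurrence in any child
  (minimum), so that even idiosyncratic words receive a value;
* the **6-child** and **12-child** estimates use the *mean* of the
  attesting children's first ages.

Both aggregators are exposed (`kchild_aoa(..., aggregator=)`) because the
minimum and the mean answer different questions: the minimum estimates the
earliest observable onset, the mean a typical onset. Words first attested
in a child's very first session are flagged `censored`: recording began at
about 24 months, so such words may have been acquired earlier and the
recorded age is only an upper bound. They are retained by default (dropping
them would bias the early end of the scale); the flag supports sensitivity
analyses.

Ages use a single convention throughout: CHAT `Y;M.D` strings are converted
with a 30.44-day month and held at two-decimal precision.

Tokenization is deliberately conservative, since transcript conventions mix
speech with annotation: tokens are lowercased; unintelligible and
untranscribed markers (`xxx`, `yyy`, `www`), fillers and fragments
(`&`-prefixed), punctuation and bracketed codes are dropped; special-form
suffixes (`@c`, `@o`, ...) are stripped keeping the stem; compounds
(`choo+choo`, `night_night`) stay single types. Inflected forms count as
distinct types — no lemmatization is attempted, because none of the norm
sets the estimates are compared against is lemmatized either.

## Reliability

Treat words as subjects and children as raters of each word's acquisition
age. With $n$ words and $k$ raters, the two-way random-effects intraclass
correlation for the *average* of the raters is

$$\mathrm{ICC}(2,k) = \frac{BMS - EMS}{BMS + (JMS - EMS)/n},$$

where $BMS$, $JMS$ and $EMS$ are the between-word, between-rater and
residual mean squares of the two-way ANOVA decomposition. Both words and
children are random: a different sample of children should generalize.

The classical decomposition assumes a complete matrix, but different
children attest different words. The canonical path in `icc2k()` therefore
computes on the fully observed sub-matrix (all-rater rows). A consequence
worth knowing: under this rule a 6-child threshold and a 12-child threshold
yield the *same* complete sub-matrix (only words attested by every child
have complete rows), hence the same ICC. An alternative `method =
"available"` estimates variance components from all observed cells with a
crossed random-effects model (`lme4`) and is labeled non-canonical; it is
the route to a genuinely 6-child internal-consistency figure.

`split_half()` randomly partitions the children into two halves, computes
per-half per-word mean first ages, and correlates them over words present
in both halves. Because a single random split is noisy, the default
averages 100 seeded splits (`n_splits = 100`); the per-split values are
returned for inspection. No Spearman-Brown correction is applied by
default — the reported value is the raw half-correlation. Words attested by
fewer than two children can never appear in both halves, so the 1-child
variant is automatically restricted to words produced by two or more
children. Internal consistency (ICC) is undefined for the 1-child variant
for the same reason.

## Parent-report AoA50

CDI-style parent reports give, per word and age, the number of children
reported to say the word. `fit_aoa50()` fits the binomial GLM

$$\operatorname{logit} p(t) = \beta_0 + \beta_1 t$$

by maximum likelihood on the counts and returns the 50% crossing
$\mathrm{AoA50} = -\beta_0/\beta_1$, the age at which half of the children
say the word. Fits are excluded (value set missing, reason recorded) when
the model does not converge, when the slope is non-positive (a flat or
falling curve has no meaningful crossing), or when the crossing falls
outside an admissible range, 6–60 months by default: a crossing
extrapolated far beyond the sampled ages is an artifact of the linear
logit, not a measurement. The estimator is exactly equivariant under age
shifts, which the tests exploit.

## Frequency adjustment and the norm table

Corpus AoA is biased by word frequency: frequent words are more likely to
be *sampled* early, whatever their true acquisition age, because a
recording schedule observes only a thin slice of the child's speech.
`adjust_for_frequency()` removes the linear part of this bias by
regressing corpus AoA on child log-frequency — the natural log of the mean
of the preschool and primary-school per-million frequencies — over the
**full** set of words with both values, and taking residuals. The full-set
fit is a contract, not a convenience: residuals restricted to a word subset
are generally *not* orthogonal to frequency within that subset, and the
package intentionally reproduces that behavior by never refitting within
subsets.

`join_norms()` assembles the word-keyed table: case-folded exact string
matching, no lemmatization, duplicate words rejected loudly. Measures keep
their native units (ratings in years, test AoA in grade levels, corpus and
parent AoA in months) since every downstream statistic — correlations and
standardized regressions — is scale-free. Zero-frequency words are dropped
rather than smoothed; `epsilon` smoothing is available behind an argument
for users who prefer it.

## The validation battery

`correlation_matrix()` computes listwise complete-case Pearson (optionally
Spearman) correlations within each k-child word set, reproducing the
per-set n logic of norm-overlap studies.

`standardized_regression()` z-scores all variables on the analysis rows and
fits OLS, so coefficients are standardized betas; p-values are the usual
two-sided t-tests, unadjusted for multiplicity. The variance inflation
factor of predictor $j$ is $1/(1-R^2_j)$ from regressing $j$ on the other
predictors; exactly collinear designs are rejected before fitting, naming
the offending column. Corpus AoA enters the lexical-decision models
unadjusted by default — frequency is controlled by including log-frequency
as its own predictor, and residualized predictors would make the frequency
coefficient uninterpretable — with the frequency-adjusted variant available
as a configuration switch; both paths are exercised in the tests.

`cross_validate()` runs repeated k-fold cross-validation (5 folds, 4
repeats by default) with the z-scoring refit inside each training fold and
applied to the held-out fold, so no scaling information leaks. The outcome
is standardized too, which puts the RMSE on the standardized scale: a model
with no predictive value has expected RMSE 1, and values meaningfully below
1 indicate genuine out-of-sample signal. Reporting CV error on the
standardized scale is the canonical choice here because the regression
itself is standardized; the raw-RT scale can always be recovered by
multiplying by the outcome's standard deviation.

## The synthetic world

`world_params()` / `simulate_world()` generate a study-shaped world whose
truth is known:

| parameter | default | meaning |
|---|---|---|
| `n_children`, `n_sessions` | 12, 36 | children and sessions per child |
| `session_gap_days` | 10–14 | uniform gap between sessions |
| `age_start_months` | 24 | age at first session (corpus spans roughly 24–38 months) |
| `n_words` | 600 | vocabulary of the world |
| word mean AoA | lognormal, median 22 mo, 0.25 log-units | right-skewed early vocabulary |
| `child_sd_months` | 3 | Gaussian per-child deviation, truncated at a 10-month floor |
| `zipf_exponent`, `tokens_per_session` | 1, 300 | Zipfian usage rates; expected child tokens per session |
| `cdi_slope` | 0.5 / month | logistic slope of parent-report curves |
| rating model | affine in true AoA + noise (0.5 y) + 0.1 × (−log usage) | adult ratings with optional frequency contamination |
| RT model | 600 + 2 × AoA − 10 × log-freq + noise (30 ms) | positive AoA effect, negative frequency effect |

Session ages are snapped to the CHAT `Y;M.D` grid so that a written
transcript re-parses to bit-identical ages. Token emission is the simplest
mechanism that produces the sampling bias of interest: in each session a
word already acquired by the child contributes a Poisson token count at its
usage rate, and an unacquired word contributes nothing. Two consequences
are guaranteed by construction and verified exhaustively in the tests: no
word is ever attested before its latent acquisition age, and the mean lag
between acquisition and first observation shrinks as usage rates grow —
the frequency-bias mechanism that motivates the adjustment step.

The per-child deviation SD of 3 months and the rating model constants are
realism choices, made once: they give inter-child spreads and
rating-truth correlations in the range typically seen for early
vocabulary, and none of them is tuned to any particular test outcome.

What the generator does **not** emulate: real discourse (sessions are bags
of tokens), morphology and lemma structure, comprehension-production gaps
in parent reports, transcription error, or age-varying usage rates.
Passing tests on synthetic worlds therefore show that the *pipeline
machinery* is correct and calibrated — not that any particular real-corpus
number is right.

## Numerical choices and degenerate inputs

* ICC is computed from explicit sums of squares and cross-checked in the
  tests against an independent `aov()`-based decomposition at 1e-10;
  matrices with fewer than two complete rows or zero between-word variance
  return `NA` with a warning rather than a misleading number.
* `fit_aoa50` treats non-convergence and separation as exclusion reasons,
  never as errors; the pipeline carries the exclusion table along.
* OLS is delegated to `stats::lm`; collinearity is detected by QR rank
  before fitting.
* Split-half and cross-validation take mandatory seeds; every stochastic
  stage of the pipeline derives its own sub-seed from the run seed, so a
  run is reproducible end to end and two runs with the same configuration
  write byte-identical CSV artifacts.
* Ties in first occurrence (a word in two sessions at the same rounded
  age) are harmless: the minimum is taken over ages, not sessions.

## Problem sizes

The default test-suite worlds use 4–12 children, 12–36 sessions and
50–600 words; the calibration checks run 100 seeds per claim (AoA50
recovery within ±1 month in ≥95% of samples; sign recovery of the RT model
in ≥95% of default worlds; null cross-validation RMSE within [0.9, 1.1]).
These sizes keep each property readable as a statistical statement while
the whole suite runs in about a minute.

## Limitations

* Corpus AoA is right-censored by the recording window: words acquired
  after the last session are invisible, and words acquired before the
  first session are flagged, not corrected.
* The complete-row ICC path answers the 12-child question exactly but
  collapses 6-child and 12-child internal consistency onto the same
  sub-matrix; use the variance-component path for incomplete designs.
* The CHAT reader implements a minimal dialect (headers, main tiers,
  dependent tiers, continuations, bracketed codes); it is not a CLAN
  replacement and does not consult `%mor` tiers.
* Word matching across norm tables is exact string equality after case
  folding; homographs merge and spelling variants separate.
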