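---
title: "Auditing age stereotypes in LLM text: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing age stereotypes in LLM text: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmaudit)
```

## The problem and the model

Large language models answer open-ended prompts about social groups with
fluent, mostly positive prose. The question an audit must answer is whether
the *content* of that prose nonetheless differs systematically by group —
here, by the prompted age of the person being described. `scmaudit` frames
the question with the Stereotype Content Model (SCM), which locates social
perception on two axes:

* **warmth** — sociability (friendliness) and morality (trustworthiness);
* **competence** — ability (skill, intelligence) and assertiveness (agency,
  drive).

Each axis is measured on corpus sentences by a supervised semantic
projection: labelled template sentences ("These people are always
[ADJECTIVE]." and the two-adjective variant) are embedded, a partial least
squares (PLS) regression is fitted from embeddings to the pair of labels,
and the fitted linear map is applied to every corpus sentence. Scores are
interpreted on a −1 … +1 scale per axis. Between-age differences in the
score distributions are tested with Welch's heteroscedastic one-way ANOVA,
which does not assume equal variances across age groups — appropriate
because score dispersion varies visibly with age. A complementary
word-count analysis tallies lexicon words per (subdimension, valence) cell
and age, after removing each age's boilerplate vocabulary.

### Assumptions

* Sentences are the unit of meaning: scores and similarities are computed
  per sentence and then averaged per sample / per age.
* The embedding places sentences with similar stereotype content near one
  another, and template sentences are representative enough of corpus
  sentences for a linear map trained on the former to transfer to the
  latter.
* The lexicon's (word → subdimension, valence) assignments are trusted as
  given; no word-sense disambiguation or negation handling is attempted.

## Pipeline stages and their parameters

### Corpus filtering

Three rules, applied per response in this order: (1) drop the first and the
last sentence (LLM responses open and close with variability disclaimers
that do not describe the prompted age); (2) drop sentences of three words
or fewer (very short sentences embed poorly); (3) drop colon-ended
sentences (list headers). "Word" means a whitespace token after stripping
surrounding punctuation; hyphenated forms count once. The splitter is
rule-based: terminal `.`/`!`/`?` followed by whitespace ends a sentence
(with a small abbreviation guard), and newlines always end one, which
handles list-style LLM output.

### Embedding backends

All analysis code sees only the backend contract (`embed(texts)` → matrix).
The **synthetic backend** is the package's test instrument: each SCM
subdimension owns one dedicated coordinate (4 axes in a 64-dimensional
space); a lexicon word adds `valence × signal_weight` on its subdimension's
axis, so opposite valences cancel; optional `token_hash_weight` places
every non-lexicon token on a deterministic hashed coordinate, giving
sentences a vocabulary-driven geometry; isotropic Gaussian noise
(`noise_sd`) is seeded per sentence so identical inputs embed identically.
Real encoders (a sentence transformer exposing 1,024-dimensional vectors,
say) are wrapped with `function_backend()`, which records the checkpoint
identifier in the output metadata rather than assuming one.

### Similarity

PCA is fitted on the sentence embeddings of the whole corpus jointly
(mean-centred, unscaled), *before* any averaging, and retains the smallest
number of components explaining 90% of variance by default. Sample vectors
are unweighted means of their sentences' reduced vectors; age vectors are
unweighted means of sample vectors; the report matrix holds pairwise
cosines. Because the component space is mean-centred, strongly negative
cosines between dissimilar age groups are expected and are part of the
signal, not an artefact.

### Scoring

* `pair_budget` (default 200): number of two-adjective templates sampled,
  seeded, from unordered pairs sharing dimension *and* valence — mixed
  pairs would have ambiguous labels. Each adjective contributes its valence
  on its own dimension and 0 on the other; sentence labels are the mean
  contribution.
* `pls_components`: `fit_scm_model()` defaults to
  `min(25, rank of the training matrix)`, a sensible cap for
  high-dimensional transformer embeddings. The *pipeline* default for the
  synthetic backend is the backend's known signal rank (the number of
  distinct stereotype axes, 4). This matters: with far more components than
  signal directions, PLS fits the isotropic noise on non-signal coordinates
  and the fitted map acquires large pseudo-random loadings there, which
  injects variance — and, for hashed vocabulary coordinates, systematic
  offsets — into corpus scores. Matching the component count to the latent
  rank removes that failure mode.
* Clipping: a linear map cannot guarantee the −1 … +1 scale, so predictions
  are clipped post hoc and the clipping rate is reported (`clipping_rate`
  attribute; about 3–4% on the default synthetic corpus). Clipping
  compresses extreme scores but preserves the ordering of age means.
* Welch's ANOVA is computed by `stats::oneway.test(var.equal = FALSE)`;
  the package reports F, df1 = k−1, the Welch–Satterthwaite df2, and the
  upper-tail p. Only two tests are run (one per dimension); p-values are
  reported unadjusted. A numerical note: with equal group sizes and equal
  sample variances, Welch's F equals the classical one-way F *exactly* only
  for two groups; for k > 2 the two statistics differ by the small-sample
  correction factor `1 + (2(k−2)/(k²−1)) Σ (1−w_i/W)²/(n_i−1)`, which tends
  to 1 as group sizes grow. The test suite asserts this exact algebraic
  relationship rather than a false equality.

### Word counts

* `extract_content_words()` uses a self-contained rule-based
  tagger/lemmatizer: function words are removed via a closed-class list,
  `-ly` adverbs and `-ing` gerunds are dropped (with allow-lists for
  adjectives such as *friendly* and *caring*), and regular plurals are
  reduced to singular lemmas with guards for `-ss/-us/-is/-ous` endings.
  It is deliberately conservative; gerund/participle tagging is the main
  tagger-dependent ambiguity, and counts may shift slightly versus a
  statistical tagger.
* `top_fraction` (default 0.8): each age's "common terms" are the shortest
  frequency-ranked prefix of its lemma distribution reaching this
  cumulative share of tokens, extended across ties at the cut. This is a
  deterministic formalization of common-term extraction by rank-frequency
  (Zipf) structure.
* `max_ages` (default 6): a word common in strictly more than this many
  ages is treated as model boilerplate and removed from **all** ages'
  vocabularies before counting. Membership is evaluated on the common-term
  sets; removal applies to the full vocabulary, so rare stereotype-bearing
  words are kept for counting.
* Totals: the `total_word_count` column is the raw token count of the
  age's sentence-filtered text — all tokens, not just nouns/adjectives, and
  before any vocabulary filtering — so category cells are small fractions
  of it, as in published count tables. A lemma with several lexicon entries
  increments every matching cell (polysemous words can legitimately count
  as, e.g., positive sociability and negative morality at once).

## What the synthetic generator emulates — and what it does not

`generate_corpus()` produces, per response: one opener from a pool of
variability disclaimers, an optional colon-ended list header, 5–9 body
sentences, and one closer — so the three sentence filters are exercised
exactly as on real LLM output. Each body sentence carries 8–12 content-word
slots filled from the lexicon according to the age profile's
(subdimension, valence) rates, from regime marker vocabulary, or from a
60-word neutral filler list disjoint from all of the above.

The default profiles plant the structure a real audit of age-conditioned
LLM text is reported to exhibit: warmth rising to a mid-life peak (age 40)
then declining gently; competence peaking at age 30 and declining through
the older ages; positive assertiveness falling strictly with age; and three
vocabulary regimes (young 10–20, middle 30–50, older 60–90) that give the
similarity matrix its block structure. Planted `warmth_level` /
`competence_level` values are the per-slot net signed rates on a 0.06
full-scale; adjacent ranks are separated by 0.006 net words per slot.

Two variance-control choices make the planted structure recoverable at the
study size (9 ages × 100 responses) rather than a coin flip:

* **Stratified planting.** Within a response, each cell receives
  `floor(rate × slots)` words plus a Bernoulli remainder, shuffled over
  slots — the expected rate is exactly the profile's, but the per-age
  realized counts have far less variance than iid per-slot draws. With iid
  draws the realization noise of the rates themselves (~0.03 net words per
  sentence) is the same order as the planted adjacent-rank gaps.
* **Rank-matched scoring** (see `pls_components` above).

What the generator does **not** emulate: grammar and fluency (body
sentences are scaffolded word lists), discourse structure, negation and
sarcasm, polysemy (the built-in seed lexicon is unambiguous by
construction, so counting oracles are exact), and any real encoder's
geometry. Passing tests therefore demonstrate that the pipeline recovers
planted statistical structure through its own stages — filtering,
embedding, projection, testing, counting — not that a particular LLM is or
is not biased.

## Numerical and degenerate-input choices

* PCA on an all-identical embedding matrix aborts with a zero-total-variance
  error; a zero-norm age-group vector aborts naming the age.
* PLS training requires variance and both signs on each label dimension,
  and at least `n_components + 1` sentences; a training matrix of rank
  lower than the requested components aborts suggesting fewer components.
* Welch's ANOVA requires ≥ 2 groups, each with n ≥ 2 and positive variance;
  violations abort naming the offending group. In per-age summaries these
  degenerate cases are caught and recorded as messages instead of results.
* Zipf ties at the cumulative cut are broken lexicographically and the
  whole tie group is included, making the common sets order-independent.
* Cosines are clipped to [−1, 1] against floating-point overshoot and the
  similarity matrix is symmetrized exactly; the diagonal is set to 1.
* All randomness (generation, pair sampling, per-sentence noise) flows from
  explicit integer seeds; per-response seeds are derived arithmetically so
  corpus generation is order-independent and bit-reproducible, and the
  provider route (`collect_corpus()` + `synthetic_provider()`) reproduces
  the direct `generate_corpus()` output exactly.

## Problem sizes used by the test suite

Unit tests run on corpora of 2–8 responses per age; the end-to-end
recovery checks run the full 9 × 100 design once (about 20 s with the
synthetic backend); the Welch oracle checks use 200 simulated datasets of
2–9 groups with 5–50 observations each; sign calibration uses 500
leave-one-adjective-out refits. These sizes were chosen to match the study
design where the property under test depends on it, and to stay small
where it does not.

## Known limitations

* The rule-based tagger/lemmatizer trades recall for reproducibility; a
  statistical tagger would classify gerunds and rare inflections better.
* The seed lexicon is a compact demonstration set; substantive audits
  should supply a full stereotype content dictionary via
  `read_scm_lexicon()`.
* Scores are clipped rather than calibrated to [−1, 1]; the clipping rate
  is reported so users can judge whether a rescaling is warranted.
* The similarity stage reports the matrix and leaves cluster labels to the
  analyst; no formal clustering is performed.
* Live collection is a thin synchronous provider contract; retry/backoff,
  billing and credentials are the caller's concern by design.
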