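# scmaudit

Audit age-related stereotypes in text generated by large language models,
using the Stereotype Content Model (SCM).

When an LLM is asked a neutral, open-ended question such as *"Describe the
personality of a 40-year-old person."*, the text it produces can carry subtle
social stereotypes even when every sentence is positively phrased. `scmaudit`
implements a complete, reproducible audit pipeline for age-conditioned
corpora of such responses, for researchers in computational social science,
gerontology and AI fairness:

1. **Corpus construction and filtering** — collect (or synthesize) ~100
   responses per prompted age over ages 10–90 in 10-year steps, split them
   into sentences, and drop boilerplate: the first and last sentence of each
   response, sentences of three words or fewer, and colon-ended list headers.
2. **Text similarity by age** — embed every sentence, reduce the corpus
   jointly by PCA, average to per-sample and per-age vectors, and compute the
   age-by-age cosine similarity matrix. In the mean-centred component space,
   negative similarities are meaningful (groups on opposite sides of the
   corpus centroid).
3. **Warmth/competence scoring** — build labelled template sentences
   ("These people are always [ADJECTIVE].", "… [ADJ 1] and [ADJ 2].") from a
   stereotype content lexicon, fit a partial least squares (PLS) regression
   from sentence embeddings to the two SCM axes

   *score(s) = B′·embed(s) + b, clipped to [−1, 1]*

   with warmth covering sociability + morality and competence covering
   ability + assertiveness, then score every corpus sentence and test
   between-age differences with **Welch's heteroscedastic one-way ANOVA**
   (F with Welch–Satterthwaite denominator df).
4. **Subdimension word counts** — extract noun/adjective lemmas, identify
   each age's common terms by a Zipf cumulative-frequency rule, exclude
   words common in more than six ages (model boilerplate), and tally
   positive/negative occurrences for the four subdimensions per age.

Because no public corpus of this kind exists, the package ships a seeded
**synthetic corpus generator** with planted stereotype structure (warmth
peaking in mid-life, competence peaking at 30 and declining in older ages,
positive assertiveness declining strictly with age, and three vocabulary
regimes: young / middle / older). Every pipeline stage is testable against
the generator's ground truth, offline and deterministically. A matching
**synthetic embedding backend** maps lexicon words onto dedicated stereotype
axes; real encoders (e.g. a 1,024-dimensional sentence transformer) plug in
through `function_backend()`.

## Worked example

```r
library(scmaudit)
report <- run_pipeline(pipeline_config(seed = 1))
print(report)
#> <scm_report>
#>   samples: 900  sentences kept: 6306
#>   ages: 10, 20, 30, 40, 50, 60, 70, 80, 90
#>   warmth: Welch F(8, 2612.1) = 70.90, p = 7.46e-106
#>   competence: Welch F(8, 2615.8) = 54.20, p = 8.19e-82
#>   clipping rate: 0.036
```

The per-age warmth summary shows the planted mid-life peak recovered from
the text alone (mean warmth rises from 0.03 at age 10 to 0.27 at age 40,
then declines to 0.14 at age 90):

```r
subset(report$score_summary, dimension == "warmth")[, c("age", "n", "mean", "sd")]
#>   age   n   mean    sd
#>    10 699 0.0291 0.177
#>    20 711 0.0725 0.221
#>    30 680 0.0993 0.251
#>    40 691 0.2717 0.347
#>    50 722 0.2521 0.338
#>    ...
#>    90 701 0.1354 0.266
```

The similarity matrix reproduces the three-cluster structure typical of
age-conditioned LLM text — the young pair is internally similar
(`similarity(10, 20) = 0.80`) and the oldest ages are the most homogeneous
(pairwise 0.54–0.87 among ages 70–90) while being dissimilar to the young
group. `report$count_table` holds the per-age positive/negative counts for
all four subdimensions plus total word counts, and
`write_report(report, "out/")` exports everything as CSV/JSON together with
a run manifest.

Both Welch tests reject equality of means across ages (p < .001 with
df1 = 8), flagging the planted age differences on each SCM dimension.

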