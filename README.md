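# hsq5d — five-dimension service-quality assessment from online patient reviews

`hsq5d` turns free-text patient reviews from online health-care platforms
into structured weekly service-quality scores for doctors, and validates
those scores econometrically. It is aimed at researchers in health-services
text mining and platform analytics who need the full chain — text
processing, topic discovery, aspect classification, sentiment scoring,
panel regression — reproducible in one place, with a synthetic-data
generator so every stage can be exercised and tested without access to any
proprietary review corpus.

## What it computes

1. **Clause segmentation** — reviews split into punctuation-delimited
   clauses (configurable Chinese/ASCII delimiter set), tokenized, with
   stopword removal.
2. **Topic discovery** — collapsed-Gibbs LDA with 3-fold cross-validated
   selection of the topic count by held-out perplexity, greedy merging of
   near-duplicate topics (cosine ≥ 0.75 on word distributions), top-word
   reports, and an annotator label-agreement measure.
3. **Aspect classification** — a fastText-style averaged n-gram embedding
   classifier assigning each clause to one of five quality dimensions
   (expertise, service delivery process, communication attitude, empathy,
   outcome) or "other", with stratified train/test evaluation and Cohen's
   κ for annotation reliability.
4. **Sentiment scoring** — a rule-based lexicon algorithm: polarity words,
   multiplicative degree adverbs, odd/even negation in scope; clause
   scores aggregate to doctor-week dimension scores normalized by token
   counts.
5. **Panel validation** — the demand regression

   *Y*<sub>i,t</sub> = α + Γ·*X*<sub>i,t−1</sub> + Ctrl<sub>i,t</sub> + θ<sub>t</sub> + μ<sub>i</sub> + ε<sub>i,t</sub>

   estimated by two-way fixed effects (doctor + week) with CR1
   doctor-clustered standard errors, plus one-SD marginal effects
   (e<sup>γσ</sup> − 1), a stepwise variance-explained table, and a
   tail-censoring robustness check.
6. **Synthetic data** — a generator producing review corpora, lexicons,
   labels, and demand panels with known ground truth, whose defaults
   encode the documented study conditions (aspect prevalences, quality
   means, true coefficients Γ = 1.12 / 5.60 / 0.82 / 2.65 / 0.26).

## Worked example

```r
library(hsq5d)

s <- scenario("paper-defaults", seed = 1)      # corpus + lexicons + demand panel
out <- run_pipeline(s, classifier = "trained", seed = 1)
print(out$fit)
```

```
Fixed-effects demand regression (twoway_fe), N = 219, doctors = 60, weeks = 12
Overall R-squared (fixed effects included): 0.9447

      term estimate     se statistic   p_value
 expertise  1.14644 0.3930    2.9171 3.533e-03
   process  5.51412 0.3568   15.4531 7.189e-54
  attitude  1.27004 0.4795    2.6489 8.075e-03
   empathy  2.63244 0.2019   13.0394 7.307e-39
   outcome  0.09183 0.2188    0.4197 6.747e-01
```

Reviews were generated with true coefficients (1.12, 5.60, 0.82, 2.65,
0.26); after classification and sentiment scoring the two-way FE fit
recovers them within sampling error at this small scale (219 doctor-week
rows survive the one-week lag). Coefficients convert to demand terms via
one-SD marginal effects:

```r
marginal_effect(gamma = 1.1189, sigma = 0.0252)
#> # A tibble: 1 × 5
#>   dimension gamma  sigma log_effect pct_effect
#>   <chr>     <dbl>  <dbl>      <dbl>      <dbl>
#> 1 <NA>       1.12 0.0252     0.0282       2.86
```

— a one-SD improvement in perceived expertise raises log demand by ≈ 0.03,
i.e. about 2.9% more patients. The stepwise table shows each dimension's
incremental information:

```
 step           added r_squared
    0 (controls only)    0.7709
    1       expertise    0.7750
    2         process    0.8578
    3        attitude    0.8630
    4         empathy    0.9447
    5         outcome    0.9447
```

The `analysis/` directory holds the full narrative workflow as numbered
scripts (simulate → segment → topics → classify → score → regress), each
writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_segment_tokenize.R
...
Rscript analysis/06_demand_regression.R
```

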