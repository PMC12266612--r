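---
title: "Assessing health-care service quality from online reviews: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing health-care service quality from online reviews: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Online health-care platforms accumulate large volumes of free-text patient
reviews, but platform-scale quality assessment needs structure: which
aspects of a doctor's service does a review speak to, and how favourably?
This package implements a five-dimension service-quality pipeline for such
review corpora. Reviews are segmented into punctuation-delimited clauses;
clauses are classified into five quality dimensions — a doctor's
**expertise**, the **service delivery process**, **communication
attitude**, **empathy**, and treatment **outcome** — plus a residual
**other** class; clause sentiment is scored with a rule-based lexicon
algorithm; sentiments are aggregated into weekly per-doctor dimension
scores; and the dimensions are validated econometrically by asking whether
they predict subsequent patient demand in a doctor-week panel.

The five dimensions extend two classical service-quality traditions: the
structure–process–outcome view of care delivery, and SERVQUAL's
consumer-perception dimensions (notably empathy and responsiveness),
adapted to a setting where digital interaction replaces physical
infrastructure.

Because real platform review corpora are not redistributable, the package
ships a synthetic-data generator that produces clause-structured corpora,
lexicons, and demand panels with known ground truth. Every stage is tested
against that truth.

## Pipeline stages and their models

### Clause segmentation and tokenization

A clause is a maximal run of non-delimiter characters with non-whitespace
content. The default delimiter set covers Chinese and ASCII sentence and
clause punctuation (，。！？；、,.!?;:…) and is configurable, since
platforms differ and no single inventory is canonical. Whitespace-only
runs are dropped; clause text is otherwise untouched. Tokenization splits
on whitespace by default — sufficient for pre-segmented or schematic text —
and accepts a user-supplied segmentation function for unsegmented Chinese;
the core deliberately carries no segmenter dependency. Stopwords are
removed after splitting, preserving token order.

### Topic discovery

Topics are discovered with latent Dirichlet allocation fit by collapsed
Gibbs sampling: each token's topic is resampled from
$p(z = k) \propto (n_{dk} + \alpha)\,(n_{kw} + \beta)/(n_k + V\beta)$
with the token removed from all counts. Documents are whole reviews
(tokenized, stopword-filtered), not clauses — topics describe complete
after-service comments. Defaults are the common symmetric priors
$\alpha = 50/K$, $\beta = 0.01$; both are exposed because the fit is
sensitive to them on short documents (see *Numerical choices*).

The number of topics is chosen by 3-fold cross-validation: for each
candidate K the model is trained on two folds and scored on the third by
held-out perplexity, $\exp(-\sum_{d,w} \log p(w \mid d)/N)$ with
$p(w\mid d)=\sum_k \hat\theta_{dk}\hat\phi_{kw}$. Held-out
document–topic weights are estimated by fold-in Gibbs sampling (20 sweeps,
point estimate) with the topic–word distribution frozen; fold-in is
simpler than left-to-right evaluation and adequate for ranking candidate
K. The K minimizing mean perplexity wins; ties go to the larger mean
log-likelihood, then the smaller K. The log-likelihood reported is the
same held-out sum used by perplexity — two views of one quantity.

Near-duplicate topics are merged greedily: while the most similar pair of
topics exceeds a cosine threshold (default 0.75, computed on smoothed
topic–word probability rows), their count rows are summed and topics are
renumbered. Greedy best-pair-first is a choice; no ordering is canonical,
and the merge log records every step. Topic labeling — and the exclusion
of disease- or hospital-specific topics — is inherently human-in-the-loop;
the package supplies top-word reports and an annotator-agreement measure
(mean bag-of-words cosine between two coders' label strings per topic)
rather than automating the judgment.

### Aspect classification

Clause classification is a shallow averaged-embedding model in the
fastText tradition: a clause is the mean of its feature embeddings (words,
optionally word bigrams — off by default), mapped through a six-way
softmax. Training is plain SGD on the negative log-likelihood, one example
at a time, learning rate decaying linearly to zero. Defaults (learning
rate 0.8, 25 epochs, 20 dimensions) are the grid-search optimum reported
for this task family. Plain softmax replaces hierarchical softmax: with
six classes the hierarchy is purely an efficiency device. Embeddings
initialize uniform on $(-1/d, 1/d)$, output weights at zero, and a seed is
required, so training is reproducible. A clause whose features are all
out-of-vocabulary is assigned **other** with a uniform probability vector,
so downstream sentiment never scores unclassifiable text under a quality
dimension. Ties in the argmax resolve by the fixed class order (expertise,
process, attitude, empathy, outcome, other).

Annotation quality is assessed with Cohen's $\kappa$ from marginal label
frequencies; the degenerate case of two identical constant annotators
returns 1 by convention, with a notice.

### Sentiment scoring

The lexicon algorithm follows the standard four steps: find each sentiment
word and its polarity; collect degree adverbs in its scope and multiply
their weights; count negation words in the scope and flip the sign if the
count is odd; sum contributions over the clause. The **scope** of a
sentiment word runs from just after the previous sentiment word (or the
clause start) to the token before it — the conventional reading of
"preceding", which also prevents a modifier from being counted twice.
Several degree adverbs in one scope compose multiplicatively. The clause
score is normalized by the clause token count; doctor-week dimension
scores divide the summed raw scores by the summed token counts of the
contributing clauses ("averaging by corpus length"); the two readings of
the normalization coincide for single-clause groups. Clauses labeled
**other** never contribute. Scores are not capped or rescaled.

Lexicons are three TSV tables (polarity word → signed value, degree adverb
→ positive multiplier, negation word list) with disjoint word sets.
Commercial lexicons are not redistributable, so the package ships a small
synthetic lexicon (`inst/extdata/synthetic_*.tsv`) with polarities ±1 and
degree weights 0.5/1.5/2; real deployments substitute their own tables.

### Econometric validation

The validating regression is a doctor-week panel model of demand:

$$Y_{i,t} = \alpha + \Gamma X_{i,t-1} + \mathrm{Ctrl}_{i,t} + \theta_t + \mu_i + \varepsilon_{i,t}$$

with $Y$ log demand, $X_{i,t-1}$ the five dimension sentiments one week
earlier, week effects $\theta_t$, doctor effects $\mu_i$, and controls.
Count-valued controls enter as $\log(1+x)$, which also handles zero weeks.
A panel row exists only where demand and all five lagged scores are
defined; the missing-score policy is drop-row by default, with an optional
carry-forward-last alternative, since sparse weeks are a real-data fact the
demand model itself is silent about.

Two estimation modes are exposed. `twoway_fe` is the within estimator —
doctor and week intercepts absorbed by alternating demeaning — and is
numerically identical to least squares on full dummy sets (the test suite
verifies the equivalence to 1e-8). It necessarily drops doctor-invariant
controls. `pooled_weekfe` keeps week dummies only, so time-invariant
coefficients (chronic status, rank, gender) remain identifiable; published
tables that print such coefficients alongside individual effects are of
this shape, and exposing both modes avoids guessing which identification
was intended. Standard errors are the CR1 cluster-robust sandwich by
doctor with the $G/(G-1)\cdot(N-1)/(N-K)$ correction, $K$ counting
absorbed intercepts; p-values use a normal reference, appropriate for the
large cluster counts the design targets. The reported $R^2$ is overall
(fixed effects included), matching the convention in which adding the five
dimensions moves explained variance from roughly 79% to 85%.

Marginal effects translate a coefficient into demand terms: a one-SD
increase in a dimension raises log demand by $\gamma\sigma$ and demand by
$e^{\gamma\sigma}-1$. The stepwise information-load table refits the model
adding one dimension at a time (controls-only baseline first); nesting
makes the sequence non-decreasing, and a step whose regressor is perfectly
collinear with the existing design repeats the previous $R^2$ rather than
erroring — redundancy adds nothing, which is exactly what the table should
show. The censoring robustness check removes the $\lfloor fN\rfloor$
smallest and largest demand observations (default 10% per tail, ties by
row order) and refits.

## The synthetic-data generator

The generator is the package's study design, not a tuning knob. Its
defaults encode the documented conditions:

* **Aspect prevalence** per clause: proportional to the reported clause
  counts by dimension — process 0.159, attitude 0.145, expertise 0.103,
  outcome 0.055, empathy 0.025, other 0.513. About half of clause text is
  non-cue content, and roughly 84% of multi-clause reviews contain some.
* **Latent doctor quality** per dimension, normal with means 0.04
  (expertise), 0.06 (attitude), 0.03 (outcome) — the reported perceived-
  quality score means — and 0.05/0.04 for process/empathy, interpolated
  since only three means are printed. A clause's polarity is positive with
  probability $\mathrm{logit}^{-1}(1.5\,q)$; the link is logistic because
  the substantive claim is only that better doctors receive more positive
  text, and slope 1.5 gives doctors one SD apart in quality a noticeably
  different positive share without saturating.
* **True demand coefficients** $\Gamma = (1.12, 5.60, 0.82, 2.65, 0.26)$,
  the reported regression estimates, with intercept −2.52 and the reported
  control coefficients available for confounded designs.
* **Regressor SDs** for directly simulated sentiment panels:
  (0.03, 0.02, 0.04, 0.03, 0.10). The first three are the printed SDs of
  the expertise/process/attitude scores; empathy and outcome are
  back-solved from the reported one-SD marginal effects (7.3% and 2.5%).
* **Demand noise**: doctor and week effects N(0, 1), idiosyncratic noise
  N(0, 0.5); demand is the latent log value by default, or Poisson with
  mean $e^{\text{latent}}$ in count mode.
* **Review volume**: Poisson reviews per doctor-week (preset rates 10–30,
  bracketing the ~10 reviews per doctor-week of the motivating platform),
  1–4 clauses per review.

Clause text is schematic — aspect-tagged identifier tokens, one sentiment
word per clause, optional degree/negation decoration, neutral filler —
rather than natural language: the pipeline is language-agnostic, and
schematic tokens make ground truth exact. When a negation word is
inserted, the sentiment word's sign is chosen so the *net* contribution
matches the drawn polarity, keeping the clause's effective sentiment tied
to latent quality. Reviews are clause texts joined by random delimiters,
so segmentation must recover the generated boundaries exactly — a
round-trip identity the tests assert.

What the generator does **not** emulate: natural-language variation
(synonymy, sarcasm, misspellings), multi-aspect clauses, correlated clause
sentiment within a review, review-length/quality dependence, and strategic
reviewing. Consequently, passing tests demonstrate that the machinery is
correct under the stated statistical structure — vocabulary-separable
aspects, one sentiment word per clause, demand generated by the linear
model — not that classification accuracy or sentiment fidelity would reach
the same levels on real reviews. Published accuracy on a real labeled set
(0.93) is not reproducible without that data; the synthetic analog
(≥ 0.95 on separable clauses) checks the implementation, not the claim.

## Numerical choices

* **LDA priors.** The $\alpha = 50/K$, $\beta = 0.01$ defaults are common
  practice, but on short documents a large $\alpha$ flattens document–
  topic posteriors and can defeat topic recovery; the recovery and
  model-selection demonstrations therefore use a sparse $\alpha = 0.1$,
  and selection examples use $\beta = 0.5$, which penalizes needlessly
  split topics on small vocabularies. Both are stated per-analysis.
* **Determinism.** Every stochastic routine takes a seed; the Gibbs
  samplers draw through R's RNG, so `set.seed` governs C++ sampling too.
  Identical seed and input reproduce identical topic assignments, splits,
  classifier weights, and simulated data.
* **Demeaning.** The two-way within transformation iterates doctor/week
  demeaning to a 1e-11 max-change tolerance (one pass suffices on balanced
  panels). Rank deficiency among the requested regressors is an error
  naming the collinear columns.
* **Rounding.** Printed shares use half-up rounding to two decimals
  (`percentage()`), matching how such tables are conventionally printed;
  R's own `round()` is banker's rounding and would differ at exact .005.
* **Fallbacks.** All-out-of-vocabulary clauses go to **other** with a
  uniform distribution (logged); degenerate $\kappa$ (two identical
  constant annotators) returns 1 with a notice; an empty degree lexicon
  means all degree weights are implicitly 1.

## Problem sizes used in the shipped analyses

The `analysis/` scripts run the full pipeline on the `paper-defaults`
preset: 60 doctors × 12 weeks at ~10 reviews per doctor-week (≈ 7,000
reviews, ≈ 18,000 clauses), a scale at which every stage completes in
seconds while the panel still has hundreds of doctor-week rows after the
one-week lag. The coefficient-recovery study simulates 500 doctors × 20
weeks (9,500 panel rows per replicate) and averages 100 replicates; at
that size the two-way FE estimator's Monte-Carlo standard errors are
0.005–0.025 per coefficient, tight enough to detect estimator bias well
below the 2% level.

## Known limitations

* The clause segmenter is purely punctuation-driven; clause boundaries
  marked only semantically (no punctuation) are not found.
* Single-label clauses: a clause mentioning two dimensions contributes
  only to its argmax class.
* The within estimator assumes strict exogeneity of lagged sentiment given
  the fixed effects; the generator satisfies this by construction, real
  platforms need not.
* Degree-adverb weights in any shipped lexicon are synthetic; real
  lexicon weights are not public and must be supplied by the user.
* Count-mode demand breaks the linear model's exact identity (the latent
  mean enters through a Poisson); the recovery guarantees are stated for
  latent-log mode.
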