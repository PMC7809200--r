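---
title: "Modelling lifespan trajectories of executive function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lifespan trajectories of executive function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifespanEF)
```

`lifespanEF` implements a complete cross-sectional analysis of four
executive functions — inhibitory control (Stroop colour-word), working
memory (operation span), cognitive flexibility (alternating-runs task
switching) and planning (Tower of Hanoi) — from trial-level records to
age-trajectory inference. This vignette documents the scientific choices
behind each stage: the scoring rules, the regression machinery, the
model-selection vote, the synthetic-cohort generator, and the numerical
conventions.

## Trial scoring

### Response-time trimming

All response-time analyses use accurate, non-timed-out responses made more
than 200 ms after stimulus onset and lying within 2.5 SDs of the
participant's overall trial mean. Three choices deserve comment, because a
trimming rule stated in one sentence leaves them open:

* **Reference set.** The mean and SD are computed per participant and task
  over all eligible trials *pooled across conditions*. A per-condition
  reference would shrink the very differences (incongruent vs congruent)
  the scores are built from.
* **Single pass.** The band is computed once, before any exclusion, and
  applied once. Iterative re-trimming converges to tighter sets but makes
  the retained fraction depend on the iteration count; nothing in the
  scoring rationale requires it.
* **Scale.** The band is computed on raw milliseconds by default; an
  `on_log` flag switches to log RTs for sensitivity analyses. On the raw
  scale a 2.5 SD band excludes roughly 1–2% of a log-normal RT
  distribution, almost all in the slow tail.

Participants with fewer than two eligible trials have no defined SD; their
eligible trials are kept untrimmed and a warning is emitted, so the
downstream score is computable but flagged.

### Score definitions

The Stroop congruency effect, switch cost and mixing cost are differences
of condition means of log-transformed trial RTs, each negated so that
higher scores mean better performance across all five measures. The
natural logarithm is used; on this scale typical adult RTs of 600–1400 ms
map to 6.4–7.2 log-ms units, and a cost of −0.35 corresponds to a ~42% RT
penalty. Log-transforming each *trial* before averaging (rather than
transforming the condition means) makes the score the log of a geometric
mean ratio, which is the quantity that is approximately normal for
log-normal RTs.

Block-initial trials in mixed switching blocks have no preceding task, so
the alternating-runs transition that defines switch vs non-switch does not
exist for them; they are excluded from both condition means. The generator
marks them with a missing condition label, and the scorer additionally
drops the first trial of each mixed block when block structure is present,
so externally supplied tables behave identically whether or not they
pre-label these trials.

Operation-span recall is matched position by position against the
presented sequence; a blank marker occupies a position and never matches,
and recalled entries beyond the presented span contribute nothing. The
absolute score sums the spans of perfectly recalled sets; the partial
score counts all correctly placed letters, so `partial >= absolute` holds
structurally. The Tower of Hanoi absolute score credits the full step
count of each trial solved in exactly its minimum number of moves.

### Reliability

`reliability()` computes raw (covariance-form) and standardized
(correlation-form) Cronbach's alpha with listwise deletion. For the
response-time tasks there is no single canonical definition of an "item"
(candidates include single trials, trial pairs, or condition-difference
mini-scores); any item matrix can be supplied, and reports should state
the convention used. The standardized identity
`alpha = k * rbar / (1 + (k - 1) * rbar)` is exposed directly as
`standardized_alpha()` because design-level statements ("16 items with
mean inter-item correlation 0.20 give alpha 0.80") are statements about
that identity, not about any particular dataset.

## Age-trajectory models

Each measure is regressed on orthonormal polynomial age terms of degree 1,
2 or 3 plus full-scale IQ and the SES index (sum of education 1–6, income
1–7 and occupation 1–7 codes, range 3–20). The basis is built on the
analysis sample's ages with `stats::poly()`, whose recurrence constants
are stored so fitted curves can be evaluated on a fine age grid. Columns
are zero-sum, pairwise orthogonal and unit-norm to 1e-10, which makes the
degree-j coefficient the marginal contribution of the degree-j shape.

Model-wise complete cases (outcome, age, IQ, SES all present) define the
sample for all three degrees of a measure, so that nested comparisons are
computed on identical rows; per-measure sample sizes therefore differ
across measures, and every output records the `n` actually used.

Conventions, chosen once and validated by identity tests:

* Gaussian log-likelihood `-n/2 (log 2π + log(rss/n) + 1)`; `k` counts the
  intercept, all slope coefficients, and the residual variance. With these
  definitions `aic = 2k - 2LL`, `bic = k ln(n) - 2LL`, and
  `bic - aic = k (ln n - 2)` exactly — e.g. 19.14 for a linear model with
  two covariates (`k = 5`) on `n = 340` rows.
* Standardized betas rescale each coefficient by `sd(x_j)/sd(y)`, which is
  identical to refitting with every column z-scored (the intercept-free
  part of the z-scored fit).
* The overall F uses `(k_coef - 1, n - k_coef)` degrees of freedom — a
  quadratic model with two covariates on 340 rows reports `F(4, 335)`.

### Model selection

Four indices are computed for each nested comparison: the change-F
p-value, the likelihood-ratio p-value (both favouring the complex model
when below 0.05), and the AIC and BIC differences. Selection is a
hierarchical majority vote: degree 1 vs 2, then the winner vs degree 3,
with 2–2 ties resolved toward the simpler model. The residual sum of
squares is reported but never votes, since it always favours the complex
model. Two consequences are worth knowing. First, because a change-F
p-value below 0.05 almost always drags the likelihood-ratio vote and the
AIC vote with it, the effective probability of spuriously stepping up one
degree under a true simpler model is close to the nominal 5% test size —
this is a property of the published selection rule, not of this
implementation. Second, the winner-vs-degree-3 comparison can be a
two-degree jump (linear vs cubic), so the nested-comparison machinery
accepts any nesting, with `Δk` equal to the coefficient-count difference.

Covariate-free refits use exactly the same machinery with an empty
covariate matrix. Fig-2-style adjusted trajectories are produced by
`residualize()` (residuals on IQ and SES) and `predict_curve()`
(covariates held at sample means).

### Comparing trajectories across measures

Two measures selected with the same polynomial degree are compared by
z-scoring each within its own sample, stacking the observations,
rebuilding the age basis on the stacked ages, and testing model 1
(`z ~ age terms`) against model 2 (model 1 + group indicator + group ×
each age term) with a nested ANOVA. The group main effect is retained for
orthodoxy even though z-scoring makes it essentially zero, and freeing
*all* age terms in the interaction is required for the test to address
"same shape" rather than "same average". With a quadratic shared degree
this adds three parameters. Measures whose selected degrees differ are
refused with a classed error — a different selected degree is already a
qualitative statement that the trajectories differ.

Participants contributing both measures appear in both halves of the
stack, and the test treats the observations as independent. This is the
standard stacked-ANOVA construction, and its type-I calibration under the
null is verified by simulation in the test suite (rejection rate within
0.05 ± 0.025 over 500 replicate cohorts at n = 350 per measure), but it is
a documented limitation: a seemingly-unrelated-regression treatment of the
within-person covariance is out of scope.

### Correlations

Raw correlations are pairwise-complete Pearson correlations (per-task
attrition differs, and listwise deletion would discard ~6% more rows).
Age-adjusted partial correlations correlate the residuals of each measure
on its *own* best-fitting age polynomial; with a single linear age term
this reduces exactly to the textbook first-order partial correlation,
which the tests assert to 1e-10. P-values for partial correlations use
`df = n - 2 - q` with `q` the number of age terms partialled; when the two
measures were adjusted with different degrees the larger `q` is used
(conservative).

## The synthetic cohort

The generator is a first-class module, not a test fixture: it emulates the
task designs exactly (pseudo-randomised 50/50/50 Stroop sequences under
the no-repeated-word/colour constraints, quadrant-rotation switching
blocks of 2 × 32 single + 4 × 32 mixed trials, three span trials at each
length 2–7 from the 12-letter pool, and Tower of Hanoi problem sets with
two problems at each minimum distance 3–10, verified by breadth-first
search over the 81-state move graph).

The statistical structure is: five age bands (10–17, 18–29, 30–49, 50–64,
65–86) with sizes 62/60/76/74/78; per-band IQ distributions; SES component
codes drawn from plausible population distributions summing to a mean
index near 13.7; and per-measure latent abilities

  ability = trajectory(u) + iq_load · zIQ + N(0, person_sd),

with `u = (age − 10)/76` so trajectory coefficients are portable across
age ranges. Response times are log-normal around an age-increasing
baseline (general slowing, calibrated so single-task band means fall in
the observed 6.27–6.59 log-ms range) with condition shifts equal to the
latent interference/switch/mixing abilities; span recall is per-letter
Bernoulli with a logistic in working memory and span length; Tower of
Hanoi success is per-trial Bernoulli with a logistic in planning ability
and required steps.

Default trajectory shapes are quadratic inhibition (peak ≈ age 35),
quadratic working memory (peak ≈ age 30), linear improvement of switch
cost, linear worsening of mixing cost, and a cubic planning curve (rise to
≈30, decline to ≈70, slight late recovery). Effect sizes were set once to
the magnitude of the reported standardized betas (quadratic ≈ −0.3, linear
≈ ±0.2, cubic ≈ 0.2), which places model R² in the 0.04–0.28 range; with
those conditions the full pipeline recovers each generating degree in well
over 80% of replicate cohorts at n = 350. Missingness removes whole
participants per task at rates 3/350, 16/350, 17/350 and 2/350.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: sequential trial-level dependencies
(fatigue, post-error slowing), non-stationary trial noise, correlated
attrition (missingness is independent of ability), floor/ceiling
compression in extreme ages, and within-person correlation between
abilities beyond their shared IQ loading. The accuracy model is a constant
high per-trial rate with a small condition penalty, since accuracy only
feeds the trimming filter. Maths-problem performance in the span task is
generated as a per-trial summary at or above the 85% criterion, not
analysed.

Two generation paths exist. `simulate_cohort()` emits full trial tables;
`simulate_scores()` draws the same person-level variables and emits scores
directly (binomial task outcomes exactly as the trial path; RT scores with
the Gaussian sampling error implied by the trial counts), and is used for
replicate-heavy experiments. `fresh_design = FALSE` shares one generated
design across a cohort's participants — condition-mean scoring is
invariant to the specific pseudo-random orderings, so replicate studies
use this faster path. All randomness descends from one master seed via
fixed substream derivation; a cohort is byte-identical across runs of the
same seed.

### Tower of Hanoi state space

A state assigns each of the four disks to one of three pegs; stacking
order is implied by size, so all 3⁴ = 81 assignments are legal states. A
move takes the smallest disk of a peg onto a peg whose smallest disk is
larger (or which is empty). Distances come from breadth-first search with
a cached all-pairs table; the graph is connected and the classic full
transfer takes 2⁴ − 1 = 15 moves, so the required 3–10-step problems
always exist. Problem sets sample uniformly among state pairs at the
required distance (excluding pairs whose target duplicates a practice
target) — how the original problems were chosen is not documented, so
uniform sampling is a declared choice, and the early-termination rule
after five consecutive errors is recorded as data but not modelled.

## Problem sizes and numerical notes

The replicate experiments in the test suite use the cohort size of the
study design (n = 350): 500 replicates for null-calibration checks, 150
for degree-recovery per scenario, and 100 full trial-level cohorts for the
end-to-end recovery experiment; these sizes give binomial standard errors
comfortably below the margins being asserted. Orthonormality is asserted
at 1e-10; least-squares results are compared to explicit normal-equations
and hat-matrix oracles at 1e-8; rank deficiency is detected via QR with
the offending columns named; zero-variance outcomes yield undefined
(missing) reliability rather than errors. Degenerate inputs — empty trial
tables, single-condition participants, spans recalled longer than
presented — produce missing scores, never silent numbers.

## Pipeline and artifacts

`run_pipeline()` composes the stages and writes `scores.csv`, five-band
descriptives (`table3.csv`), the per-measure fit-index table with the
selection flag (`table4.csv`), the correlation matrix with partial
correlations in parentheses (`table5.csv`), all pairwise trajectory
comparisons (`trajectory_comparisons.csv`), full fit details with and
without covariates (`fits.json`), and a `run.log` echoing seed and
configuration. Every statistic in the tables is recomputable from
`scores.csv` through the exported functions alone. The descriptive bands
are fixed to the five study groups; all inferential modelling uses
continuous age.
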