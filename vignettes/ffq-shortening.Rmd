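---
title: "Shortening food frequency questionnaires: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shortening food frequency questionnaires: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffqreduce)
```

## The problem

A non-quantitative food frequency questionnaire (FFQ) asks how often a
respondent consumes each of a list of food items — "rarely or never" up
to "5+ a day" — without asking for portions. Nutrient intake amounts are
computed deterministically from the answers, and mapped through
per-target cutoffs to a three-class diet-quality score (1 bad, 2 medium,
3 good). Even a carefully drafted instrument can feel long to someone
answering it every couple of weeks, so the practical question is: which
questions can be dropped while preserving the ability to estimate
amounts and scores?

`ffqreduce` treats that as a model-selection experiment. Correlated
question pairs are pruned at a ladder of thresholds to obtain nested
question subsets; predictors (machine-learning models and two
imputation baselines) are benchmarked per subset under a shared
cross-validation; and the PROMETHEE outranking scheme turns the
resulting multi-measure performance tables into rankings of methods and
subsets.

## Scoring model

For target $T$ with amount table $A$ (items $\times$ frequency codes,
grams/day) the intake of a respondent with answers $x$ is

$$\mathrm{amount}(x) = \sum_{i \in \mathrm{items}(T)} A_{i,\,x_i},$$

and the score is the cutoff band of the amount. Structural constraints
on $A$: the code-0 column ("rarely or never") is zero, rows are
non-decreasing in frequency and non-negative. Those constraints are what
make zero imputation (treating an unanswered item as "rarely or never")
a guaranteed *under*estimate of the true amount — one of the properties
the test suite asserts.

Two conventions are deliberate and documented so tests can be exact:

* **Cutoff boundaries belong to the middle class.** The recommendation
  phrasing for the vegetable target is "80 g to 240 g" for medium,
  which reads as inclusive at both ends; an amount of exactly 80 or
  240 g scores 2.
* **Score direction is a per-target field**, never hard-coded. For
  vegetable, fiber or protein a larger amount is better; for fat, sugar
  or salt the published material does not state the direction, so the
  definition file carries it (`direction: lower_better` reverses the
  class order).

The bundled ESFFFQ definition carries the published vegetable amount
table and cutoffs. The instrument's other amount tables are not public,
so the fixture defines no fat/sugar/fiber/protein/salt targets; users
supply their own or generate synthetic ones. Of the 27 item tags, 19
come from the published subset ladder; the remaining 8 are
reconstructed stand-ins (marked as such in the fixture file) — they
carry no published data and only complete the item count.

## Standardization

Answer codes are centred and scaled to unit variance per column before
they reach learners or correlations, using the population convention
(variance divided by $n$), the standard behaviour of machine-learning
scalers. Zero-variance columns — questions every respondent answered
identically — become all-zero columns with a warning rather than NaNs,
so no downstream model ever sees a non-finite value. Inside
cross-validation the scaler is fitted on the training folds only and
applied frozen to the test fold.

## Nested subsets by correlation thresholding

Pearson correlations between all item pairs are computed once
(correlations are affine-invariant, so raw codes and standardized
features agree). For a strictly decreasing threshold ladder
$TH_1 > TH_2 > \dots > TH_n$, subset $F_i$ is built **from**
$F_{i-1}$ by removing one member of every remaining pair with
$|r| > TH_i$; building each subset from the previous one makes the
nesting $F_0 \supseteq F_1 \supseteq \dots \supseteq F_n$ structural
rather than something to verify. Within a pass, offending pairs are
processed in decreasing $|r|$, skipping pairs that already lost a
member.

Open choices, and what this package does with them:

* **Which member to drop.** There is no canonical criterion. The
  default rule drops the item *later in questionnaire order* — fully
  deterministic and auditable; an alternative rule (drop the member
  with the higher mean $|r|$ against the remaining items) is selectable.
  Every removal is recorded as an audit triple (kept, removed, r).
* **Absolute value.** Thresholding uses $|r|$ by default: a strongly
  negatively correlated pair is just as redundant as a positive one. A
  signed-only mode is available (`use_abs = FALSE`).
* **Choosing the ladder.** Thresholds are config inputs; the package
  does not choose them automatically. (In the motivating study they
  were picked so subset sizes fell roughly linearly.)
* **Zero-variance columns** correlate 0 with everything, so they are
  never removed by thresholding; exclude them upstream if undesired.

## Baselines: zero imputation and chained equations

When only a subset of questions is answered, the two statistical
baselines complete the answers and then run the deterministic scoring
pipeline:

* **Zero imputation** sets every dropped question to code 0.
* **Chained-equations imputation** (`mice_impute()`) fills missing
  cells by iterated conditional modelling: each incomplete column is
  regressed by ordinary least squares on all other columns over the
  rows where it is observed, missing entries are replaced by the
  prediction plus Gaussian noise at the residual scale, and the cycle
  repeats (default cap 10 cycles, stopping early when the mean absolute
  change drops below `1e-3`). Predictions are rounded and clipped to
  valid codes, because the amount lookup needs legal frequencies.
  Defaults: $m = 5$ completed matrices; pooled amount = mean of
  per-imputation amounts; pooled score = cutoff of the pooled amount
  (Rubin-style pooling of a deterministic function of the data reduces
  to that average for point prediction). Columns are visited in order
  of increasing missingness, ties broken by questionnaire order. All
  noise comes from the recorded seed, so imputation is bit-reproducible.

The $m$, iteration count and pooling rule are this package's defaults —
the motivating study does not state its imputation engine or
parameters. In the benchmark the chained equations are conditioned on
the training folds' complete answers (the test fold's dropped columns
are stacked as missing below them), avoiding test-fold leakage.

## The benchmark

Eight learner families — logistic/linear regression, k-nearest
neighbours, decision tree, SVM, bagged trees, gradient boosting, random
forest, and a voting ensemble of the other seven — are run at library
default settings, deliberately untuned so no family gets a tuning
advantage. Classification predicts the score class from the kept
standardized columns; regression predicts the amount. Targets are
always the ground truth computed from the *full* questionnaire.

One fold plan (default $k = 5$, balanced, seeded) is drawn per run and
reused across every model, subset and target. Per-fold metrics are
precision, recall, F1 (support-weighted by default; macro selectable —
the study regime has imbalanced score classes, which is why weighted is
the default) and MAE, MSE, RMSE, R2. The fold mean is the $q_j$ that
enters ranking. Degenerate cells — a training fold with a single class —
fall back to a constant predictor with a warning; absent classes
contribute zero precision/recall; a benchmark run never aborts
mid-grid. Baselines enter the metric table like any other method; on
$F_0$ they reproduce the ground truth exactly (classification metrics
1.0, regression errors 0), which the acceptance suite asserts.

## PROMETHEE ranking

For each context (a subset, when ranking methods; a method, when
ranking subsets) a decision matrix $D$ holds the fold-mean $q_j$ per
alternative, each measure flagged maximizing or minimizing. For every
ordered pair and measure, the difference (negated for minimizing
measures) passes through the V-shaped preference function

$$p(x) = \begin{cases}0 & x \le 0\\ x/Q & 0 < x \le Q\\ 1 & x > Q,\end{cases}$$

and the preference index is
$\pi(A,B) = \tfrac{1}{N}\sum_j \omega_j P_j(A,B)$. Positive, negative
and net flows are the row/column means of $\pi$ (excluding self), and
alternatives are ranked by decreasing net flow with **fractional
(average) ranks** for ties — the only tie convention that produces the
familiar "1.5 / 1.5" pattern when the two baselines tie on the full
question set. Ranks are averaged across contexts and the averages
re-ranked for the "avg." line; across targets, tables are aggregated
cell-wise the same way.

Parameter defaults, both open choices documented here:

* **Indifference threshold $Q_j$**: the largest observed pairwise
  difference on measure $j$ in the current decision matrix, so the
  linear branch spans exactly the observed range (a degenerate measure
  with zero spread falls back to $Q = 1$, where all preferences are 0
  anyway). $Q$ is configurable per measure.
* **Weights $\omega_j = 1$**, making $\pi$ the plain mean of
  per-measure preferences. Weights are injectable but no weighting
  scheme is derived here.
* Only the V-shaped preference function is implemented; the interface
  (a difference, a threshold) admits alternatives.

Ties in net flow are only ever broken by fractional ranking, never by
alternative order.

## The synthetic cohort generator

Real FFQ answer sets are rarely shareable, so `generate_cohort()`
produces cohorts with *known* structure: a latent multivariate normal
row per respondent with a planted correlation matrix (pairs you
specify, plus a background level), thresholded per item into the 8
ordinal codes at cut-points implied by each item's marginal level
frequencies (a Gaussian copula). Amount tables follow the shape of the
published vegetable row (zero, then convex growth to a per-item
maximum), and cutoffs sit at the 1/3 and 2/3 quantiles of the induced
amount distribution so all three score classes are populated. Ground
truth is computed through the same scoring code the rest of the package
uses, so it is bit-recomputable.

Choices and caveats:

* The default cohort size is 289, the pooled size of the two cohorts
  the generator emulates; unit tests use smaller sizes.
* The default marginal is mildly right-skewed (most answers at low
  frequencies), which is realistic for consumption data but otherwise
  arbitrary — the real answer marginals are unpublished.
* A non-positive-semi-definite planted correlation spec is repaired by
  eigenvalue clipping with a warning rather than rejected, so specs can
  be sketched loosely.
* Thresholding a latent Gaussian *attenuates* correlations: a planted
  latent $r = 0.9$ appears as roughly $0.75$–$0.85$ on the ordinal
  codes. Plant correlations on the latent scale accordingly.
* What passing tests on these cohorts do **not** show: real dietary
  patterns (co-consumption structure beyond pairwise correlation),
  demographic covariates, or informative non-response. The generator's
  missingness is by-design subset missingness only.

## Problem sizes in the test suite

The stochastic properties are checked at sizes chosen to give the
claimed margins comfortably while keeping the default suite fast:
planted-pair recovery uses 20 replicates of $n = 2000$ cohorts with
three planted pairs at latent $r = 0.9$ and thresholds $0.4/0.3$; the
learners-vs-baseline property uses 20 replicates of $n = 200$ cohorts
over a 12-item instrument in which ten items carry intake and four of
them are droppable via planted $r \ge 0.8$ pairs — a deliberately
redundant instrument, which is the regime where shortening is
meaningful in the first place.

## Reproducibility

A single seed in `run_config()` fans out deterministically: the fold
plan uses it directly, learner fits use
`seed * 1000 + 20 * fold + learner index`, the imputation baseline
`seed * 100 + fold`, and the synthetic generator its own config seed.
Identical config and seed give byte-identical persisted bundles (the
test suite diffs the files). Learners with internal randomness (random
forest, bagging, boosting) are seeded through the same rule; gradient
boosting additionally runs single-threaded for bit-stability.

## Known limitations

* Chained equations use linear per-column models on codes; ordinal
  logistic columns would be more faithful at the extremes of the scale.
* The benchmark standardizes per training fold (no leakage); a
  single global standardization pass — closer to how a one-shot study
  might have preprocessed — is not currently a switch.
* PROMETHEE rankings depend on $Q$; with the span default, adding or
  removing one extreme alternative can change other alternatives'
  pairwise preferences. That is inherent to relative $Q$ choices.
* `recommend_questions()` assumes the answered set is a union of ladder
  subsets; budgets that fall strictly between two subsets are served
  with the largest fully covered subset's best model.
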