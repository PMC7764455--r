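# ffqreduce

Tools for shortening non-quantitative food frequency questionnaires
(FFQs) without losing the ability to estimate nutrient intake and
diet-quality scores.

An FFQ asks how often each food item is consumed ("rarely or never" …
"5+ a day"), and intake amounts follow deterministically: for target
*T* with per-item, per-frequency gram contributions *A*,

    amount(x) = Σ_i A[i, x_i],     score(x) = cutoff band of amount(x)

with three score classes (1 bad / 2 medium / 3 good). `ffqreduce`
answers the question *which questions can be dropped* by:

1. **Nested subsets** — Pearson correlations between items are
   thresholded at a decreasing ladder TH₁ > TH₂ > …; at each level one
   member of every over-correlated pair is removed, each subset built
   from the previous one so F₀ ⊇ F₁ ⊇ … ⊇ Fₙ holds structurally.
2. **Benchmark** — eight untuned learners (logistic/linear regression,
   kNN, decision tree, SVM, bagging, gradient boosting, random forest,
   voting ensemble) predict scores (classification) and amounts
   (regression) from each subset, against two statistical baselines:
   zero imputation (dropped answers = "rarely or never") and
   chained-equations multiple imputation. One shared, seeded 5-fold
   split for everything; metrics are precision/recall/F1 and
   MAE/MSE/RMSE/R².
3. **PROMETHEE ranking** — per context, pairwise performance
   differences pass through the V-shaped preference function
   p(x) = min(max(x/Q, 0), 1), are averaged into preference indices
   π(A,B) = (1/N) Σⱼ ωⱼ Pⱼ(A,B), and aggregated into net preference
   flows φ = φ⁺ − φ⁻; alternatives are ranked by decreasing φ with
   fractional ranks for ties. Rankings are produced both ways (methods
   per subset, subsets per method) and aggregated across targets.

A Gaussian-copula generator (`generate_cohort()`) produces synthetic
cohorts with planted correlations and exact ground truth, so the whole
pipeline is testable without access to any real answer set.

## Worked example

Scoring the bundled instrument — a respondent eating salad "1–2 times a
day" (120 g) and vegetables "4–6 times a week" (56.8 g):

```r
library(ffqreduce)
q   <- esfffq()                       # bundled 27-item definition
row <- setNames(resolve_codes(q$scale, c("1-2 times a day", "4-6 times a week")),
                c("salad", "vegetables"))
compute_amount(row, q$targets$vegetable)
#> [1] 176.8
amount_to_score(176.8, q$targets$vegetable$cutoffs)
#> [1] 2
```

176.8 g/day falls in the 80–240 g band, so the vegetable diet-quality
score is 2 (medium).

A small end-to-end experiment on a synthetic cohort with two strongly
redundant question pairs and one mildly redundant pair:

```r
cfg <- run_config(
  synthetic = synthetic_config(
    n_respondents = 120, items = paste0("q", 1:8),
    pairs = list(list("q1","q2",0.85), list("q3","q4",0.8), list("q5","q6",0.45)),
    targets = list(intake = list(items = paste0("q", 1:6))),
    seed = 42),
  thresholds = c(0.5, 0.3), k = 5, seed = 42,
  models = c("linear_model", "grad_boost", "random_forest",
             "zero_imputation", "multiple_imputation"),
  mice_m = 3)
bundle <- run_experiment(cfg, quiet = TRUE)
bundle$subsets
#> F0          8 items: q1, q2, q3, q4, q5, q6, q7, q8
#> F1      0.5 6 items: q1, q3, q5, q6, q7, q8
#> F2      0.3 5 items: q1, q3, q5, q7, q8
bundle$rankings$intake$methods_per_subset$classification
#> <ffq_ranktable> methods_per_subset | target: intake | task: classification
#>                      F0  F1  F2 avg.
#> linear_model        5.0 5.0 2.0  4.5
#> grad_boost          3.0 4.0 5.0  4.5
#> random_forest       4.0 3.0 4.0  3.0
#> zero_imputation     1.5 2.0 3.0  2.0
#> multiple_imputation 1.5 1.0 1.0  1.0
```

Reading the table: each column ranks the five methods on one question
subset (fractional ranks, 1 = best). On the full set F₀ the two
baselines tie at 1.5 — with nothing missing they *are* the ground
truth — while on the reduced subsets the thresholding removed exactly
the planted redundant items (q2, q4, then q6) and the methods reorder.
The "avg." column ranks the methods by their mean rank across subsets.

Given a question budget, the recommended asking order follows the
subset nesting (innermost first):

```r
recommend_questions(bundle$subsets, budget = 6,
                    ranking = bundle$overall$methods_per_subset$classification)
#> $questions: "q1" "q3" "q5" "q7" "q8" "q6"   $covered_subset: "F1" ...
```

A thin CLI over the same functions ships in `inst/cli/ffq.R` (verbs
`validate`, `simulate`, `run`, `recommend`).

## Package layout

| Area | Functions |
| --- | --- |
| Questionnaire I/O | `load_questionnaire()`, `write_questionnaire()`, `load_answers()`, `ffq_standardize()`, `esfffq()` |
| Scoring + baselines | `compute_amount()`, `amount_to_score()`, `compute_ground_truth()`, `zero_impute()`, `mice_impute()`, `pool_imputations()` |
| Subset reduction | `pearson_matrix()`, `build_subsets()`, `esfffq_subsets()` |
| Benchmark | `make_folds()`, `model_roster()`, `run_benchmark()`, `classification_metrics()`, `regression_metrics()` |
| PROMETHEE | `decision_matrix()`, `preference_value()`, `pairwise_preferences()`, `flows()`, `rank_alternatives()`, `aggregate_ranks()` |
| Synthetic cohorts | `synthetic_config()`, `generate_cohort()`, `generate_amount_tables()`, `make_missing()` |
| Pipeline | `run_config()`, `run_experiment()`, `recommend_questions()` |

See the vignette (`vignettes/ffq-shortening.Rmd`) for the model
details, parameter defaults and the design decisions behind them.
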