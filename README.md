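# fitid3

Physical-fitness evaluation and sports-mode recommendation for college
cohorts, built on two flavours of ID3 decision-tree induction.

College fitness batteries (BMI, vital capacity, sitting forward flexion,
standing long jump, 50 m sprint, endurance run, pull-ups / sit-ups) produce
per-indicator scores that must be turned into interpretable grade decisions
and, from those, concrete exercise recommendations.  `fitid3` implements
that whole pipeline for analysts and PE departments, with a seeded
synthetic-cohort generator so every stage can be validated without access to
student records.

## The algorithms

**Classic ID3.**  At a node holding class counts `s_1, ..., s_n` out of `s`
rows, the expected information is

    I(s_1, ..., s_n) = - sum_i  p_i log2 p_i,        p_i = s_i / s

and splitting on attribute `A` with value-subsets `S_d` leaves the
conditional entropy `E(A) = sum_d (|S_d|/s) I(S_d)`.  The attribute
maximizing the gain `G(A) = I - E(A)` is chosen, one branch per value,
recursively.  A Quinlan-style *windowed* trainer (grow a random window with
the rows the current tree misclassifies) is included.

**Improved binary ID3.**  For a two-class node with `p` positive and `n`
negative rows, expanding the node entropy with the second-order Maclaurin
series `ln(1+x) ≈ x - x²/2` (valid as the minority share `x -> 0`) collapses
the weighted post-split entropy — up to the constant `2/ln 2` — to

    G'(F) = sum_j  p_j n_j / (p_j + n_j)

which needs no logarithms.  Candidate splits are one-vs-rest tests
"attribute F = value f", the test *minimizing* `G'` wins, and the resulting
tree is strictly binary.  A Gini-style generalization
`sum_j |S_j| (1 - sum_i q_ij²)/2` — exactly equal to `G'` for two classes —
handles four-grade labels.  `approximation_error()` quantifies the
entropy-vs-surrogate gap, which vanishes as branches become pure.

**AHP weighting.**  Indicator weights come from pairwise judgment matrices
(`m_ij > 0`, `m_ij m_ji = 1`): column-normalize, row-sum, normalize
(`ahp_weights`), then test consistency via
`CI = (λ_max - n)/(n - 1)`, `CR = CI/RI`, accepting when `CR < 0.1`
(`ahp_consistency`, Saaty RI table).

**Evaluation pipeline.**  Raw measurements are scored through sex-specific
piecewise-linear tables into [0, 100], discretized at 85/75/60 into
excellent/good/medium/poor (left-closed: 85 is excellent), combined with
the AHP weights into primary and overall decisions by trained trees, and
mapped to sports-mode recommendations by a total, first-match rule table.
Comparison metrics: the node-walk information-entropy ratio of two trees
and the mutual-information loss rate `100 (1 - I(Y;Ŷ)/H(Y))`.

## Worked example

```r
library(fitid3)

path   <- system.file("extdata", "synthetic_cohort_example.csv", package = "fitid3")
cohort <- impute_missing(read_cohort(path), "attribute-mean")
scores <- score_cohort(cohort)
scores$composite <- composite_score(scores[, indicator_names()])
round(scores[1:3, c("vital_capacity", "sprint_50m", "composite")], 1)
#>   vital_capacity sprint_50m composite
#> 1           77.3       69.4      77.8
#> 2           76.9       74.1      76.8
#> 3          100.0       74.1      90.9
```

Subject 1's 2862.8 mL vital capacity scores 77.3/100 on the female table;
the AHP-weighted composite 77.8 discretizes to "good".  Fit the improved
binary tree on the grade data and decide hierarchically:

```r
grades <- grade_cohort(scores)[, indicator_names()]
d <- grades; d$.label <- planted_rule(grades)$overall
summary(id3(.label ~ ., d, method = "binary"))
#> ID3 (binary): 11 nodes (6 leaves), depth 4
#> Training rows: 20, training accuracy: 100.0%

trees   <- train_hierarchy_trees(grades)
profile <- evaluate_hierarchy(grades[1, ], trees)
profile
#>   body_composition cardiorespiratory flexibility  speed strength overall
#> 1        excellent            medium        good medium     good  medium
recommend(profile)
#> [1] "aerobic running program" "swimming"  "cycling"
```

The weakest primary dimension (cardiorespiratory, "medium") selects the
aerobic rule, so endurance-building modes are recommended first.  AHP
consistency of a 3-indicator judgment matrix:

```r
ahp_consistency(judgment_matrix(rbind(c(1, 3, 5), c(1/3, 1, 2), c(1/5, 1/2, 1))))
#> AHP consistency (order 3): lambda_max = 3.0037, CI = 0.0018, RI = 0.58
#> CR = 0.0032 -> pass (CR < 0.1)
```

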