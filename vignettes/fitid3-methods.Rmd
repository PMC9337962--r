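---
title: "Methods: ID3 variants, AHP weighting and the synthetic cohort"
author: "fitid3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ID3 variants, AHP weighting and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitid3)
```

This vignette records the models, the numerical choices and the open design
decisions behind `fitid3`, in the spirit of a lab notebook: what is computed,
why these defaults, and what the validation suite does and does not show.

## 1. The two induction algorithms

### Classic multiway ID3

Training data are categorical attribute vectors with a class label
(`labeled_dataset()`).  At a node with per-class counts $s_1,\dots,s_n$,
$s = \sum_i s_i$, the expected information is

$$I(s_1,\dots,s_n) = -\sum_{i=1}^{n} p_i \log_2 p_i, \qquad p_i = s_i/s,$$

and an attribute $A$ partitioning the rows into subsets $S_d$ leaves

$$E(A) = \sum_{d=1}^{r} \frac{|S_d|}{s}\, I(S_d), \qquad G(A) = I - E(A).$$

`build_id3()` selects the gain-maximizing attribute, one branch per domain
value, and recurses.  Stop rules: pure subset (class leaf); exhausted or
uniform candidates (majority leaf); empty branch (leaf with the *parent's*
majority).  All logarithms are base 2, including places where a natural or
unspecified base would be equivalent up to a constant — one base keeps every
reported bit-quantity comparable.

Ties in gain break by candidate-list order, and majority ties break by
preferring the better grade (for ordered grade labels) and otherwise the
lexicographically first label.  Both rules are arbitrary but fixed; they make
every tree, and therefore every downstream metric, reproducible.

`train_windowed()` implements the windowed main loop: draw a seeded random
window guaranteed to contain two classes (one anchor row from each of two
classes, then uniform fill), build a tree on it, classify the rows outside
the window, and add every misclassified row.  Defaults: window = half the
training set, at most 10 rounds.  This is the classic Quinlan windowing
scheme; on consistent data it converges in a handful of rounds (asserted by
the tests on separable planted data).

### Improved strictly binary ID3

For a two-class node with $p$ positives and $n$ negatives, write the node
entropy and expand $\ln(1+x)$ to second order ($x$ = minority share).  Up to
the constant $2/\ln 2$ the weighted post-split entropy collapses to

$$G'(F) = \sum_j \frac{p_j n_j}{p_j + n_j},$$

which costs no logarithm evaluations.  Two consequences drive the
implementation:

* **$G'$ is minimized, not maximized.**  $G'$ approximates the *remaining*
  impurity after the split (the quantity gain subtracts), so the
  gain-maximizing split is the $G'$-minimizing one.  The quantity is
  conventionally *named* a simplified gain — `simplified_gain()` keeps that
  convention — but the optimizer treats it as an impurity.
* **Candidate splits are one-vs-rest value tests.**  Testing "$F = f_j$?"
  yields yes/no branches whatever the domain size, which is what makes the
  tree strictly binary.  The alternative reading — one multiway candidate
  per attribute scored by the same criterion — is exposed as
  `select_attribute_simplified()` for comparison, but the binary tree is the
  shipped default.

Four-grade labels do not fit the $p/n$ form directly.  Two routes are
provided: dichotomize grades (`positive = c("excellent", "good")`) and run
the criterion in its native two-class form, or use the multiclass
generalization

$$\sum_j |S_j|\,\frac{1 - \sum_i q_{ij}^2}{2},$$

a Gini-style impurity that reduces *algebraically* to $G'$ for two classes
(identity $pn/(p+n) = |S|(1 - q_+^2 - q_-^2)/2$; verified exhaustively in
the tests for all two-class counts with totals $\le 30$, to $10^{-12}$).

`approximation_error()` reports $|$entropy $- (2/\ln 2)\,pn/(p+n)^2|$: zero
at purity, maximal ($\approx 0.279$ bits) at $p = n$.  The surrogate is
therefore trustworthy exactly where split decisions matter most — near-pure
branches — and the tests confirm that whenever both the gain-optimal and the
$G'$-optimal split have child minority shares below 0.15, the two criteria
choose the same split (overall agreement on random two-class data is
~90%).

`build_binary_tree()` stops on purity, on the no-valid-split signal (every
test leaves one side empty), or at `max_depth` (default 25 — a guard that
guarantees termination on label-inconsistent data; on consistent data the
tree never reaches it because every split strictly shrinks the yes-subset).

## 2. AHP weighting of the evaluation hierarchy

Judgment matrices are validated as positive reciprocal matrices
($m_{ii}=1$, $m_{ij}m_{ji}=1$ within $10^{-9}$).  Reciprocity — not the
symmetry $m_{ij} = m_{ji}$ sometimes stated — is what the consistency
machinery requires; a symmetric non-reciprocal matrix like
$(m_{12}, m_{21}) = (3, 3)$ is rejected with the offending indices.

Weights use the column-normalization / row-sum approximation:
$t_{ij} = m_{ij} / \sum_i m_{ij}$, $v_i = \sum_j t_{ij}$,
$w_i = v_i / \sum v_i$.  This is exact for consistent matrices (tests
assert recovery of generators $m_{ij} = w_i/w_j$ to $10^{-9}$) and is the
standard hand-calculation; a full eigen-decomposition exists only as a test
oracle (power iteration), against which $\lambda_{\max} = \frac{1}{n}\sum_i
(AW)_i / w_i$ agrees to $10^{-3}$ on perturbed matrices.

Consistency: $CI = (\lambda_{\max} - n)/(n-1)$, $CR = CI/RI$ with Saaty's
canonical RI table $(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)$ for
orders 1–9, pass iff $CR < 0.1$; orders 1–2 are always consistent and
report $CR = 0$.  The RI table ships as data inside `saaty_ri()` and orders
above 9 error rather than extrapolate.

The default hierarchy groups the seven scored indicators into five primary
dimensions (body composition, cardiorespiratory, flexibility, speed,
strength).  Its primary judgment matrix encodes the package's own expert
ordering — cardiorespiratory first, strength and speed next — and has
$CR = 0.0030$, computed, not assumed, at construction time; any edited
configuration re-runs the consistency test and refuses inconsistent
matrices.

```{r}
default_hierarchy()
```

## 3. Scoring, grades and the recommendation table

Raw measurements map to scores through sex-specific piecewise-linear tables
(`default_scoring_tables()`): linear interpolation between breakpoints,
clamped beyond the ends, monotone in each indicator's better direction.
The breakpoints are *illustrative defaults shaped like the national
college fitness-test standards* (e.g. male 1000 m: 100 points at 197 s,
pass at 272 s); they are configuration, not a transcription of any official
table,
and deployments should substitute their own via the JSON config.  BMI is
simplified to a monotone lower-is-better table; real standards score an
optimal band, which a piecewise-linear monotone table cannot express — a
known limitation.

Grades use left-closed intervals at 85/75/60, so the boundary scores 85, 75
and 60 take the better grade; the four bands abut at those cut points, so a
boundary convention had to be picked, and left-closed keeps everything
below 60 poor while giving boundary scores the benefit of the doubt.
`discretize()` is total and monotone on $[0, 100]$ and errors outside it.

Recommendations are a total first-match rule table keyed on the *weakest*
primary dimension (ties by the fixed primary order): one rule per dimension
mapping to an ordered mode list, plus an unconditional maintenance rule.
Totality is enforced by exhaustive enumeration of all $4^6$ grade profiles
at validation time, so `recommend()` can never return empty.

## 4. The synthetic cohort generator

The generator exists so that every pipeline stage — scoring, grading,
AHP-weighted decisions, both tree algorithms, the comparison metrics — can
be validated against a known ground truth.  Per subject: sex by
`sex_ratio` (default 0.5), a latent fitness factor $z \sim N(0,1)$, and
each raw indicator

$$x = \mu_{s} + \sigma_{s}\left(\ell z + \sqrt{1-\ell^2}\,\varepsilon\right),
\qquad \varepsilon \sim N(0,1),$$

truncated (clamped) to a plausible range and rounded for counts.  Loadings
$\ell$ are 0.6–0.8 for performance indicators (negative for times, where
faster is better) and $-0.3$ for BMI: fit students do well across the
battery, weakly so for body composition.  Means and SDs per sex were chosen
once so that each indicator's score distribution centres near 70 with all
four grades populated (e.g. male vital capacity 3800 ± 650 mL, female 50 m
9.1 ± 0.7 s) — a realistic college mix of roughly 15% poor / 50% medium /
25% good / 10% excellent per indicator.  Truncation bounds sit $\ge 2$ SD
from the means, so the clamping bias is far below the 3-standard-error
band the mean-convergence test allows at $n = 10{,}000$.

**Planted rule.**  Ground-truth labels must be a deterministic function of
the *discretized grades* (otherwise no tree over grades could be
consistent).  Each grade is mapped to the midpoint of its score interval
(poor 30, medium 67.5, good 80, excellent 92.5), combined with the AHP
weights child→primary→overall, and re-discretized.  The midpoint mapping —
rather than grade ranks — keeps the planted rule on the same 0–100 scale as
the composite score, so the AHP weights mean the same thing in both places.
`label_noise` flips overall grades to a different uniform grade;
`missing_rate` blanks measurement cells in the delivered records only
(ground truth is computed before blanking).

Two cohort designs are first-class because the study setting this
generator emulates uses both a single split cohort and small independent
groups: `cohort_spec(n = 300)` with a 150/150 `train_test_split()`, and
`generate_grouped_cohort(5, 30)`.  Neither is asserted to reproduce any
external figure.

**What passing tests do and do not show.**  The generator draws
conditionally independent indicators around one latent factor, with no
measurement error model, no item non-response structure beyond
uniform missingness, and no real scoring tables.  Consistency results
(100% training accuracy, exact planted-rule recovery by the hierarchical
trees) validate the *implementations*; they say nothing about how well ID3
variants grade real students.

## 5. Comparison metrics and their behaviour

* `information_loss_rate(tree, data)` $= 100\,(1 - I(Y;\hat Y)/H(Y))$ from
  the prediction contingency table: 0% iff predictions carry all label
  information, 100% for constant predictions; undefined (error) on
  single-class data.  Output is clipped to $[0, 100]$ against
  floating-point spill.
* `entropy_ratio(improved, classic, data)` routes the data through both
  trees and compares the sums of subset-weighted class entropies over *all*
  nodes, as a percentage.  Self-comparison gives exactly 100%.  Note a
  structural bias worth knowing: a strictly binary tree expands a $k$-way
  split into a chain of internal nodes, each contributing its residual
  entropy, so on realistic cohorts the improved tree's sum often *exceeds*
  the classic tree's (ratios above 100%).  The package reports the metric
  as defined and asserts only its boundary laws.
* `compare_algorithms()` runs the grouped design (default matching 5×30):
  per group a seeded 50/50 split, both algorithms trained, entropy ratio on
  the training half, loss rate and accuracy on the held-out half, and
  wall-clock training time rescaled by the fastest fit.  Timings are
  reported but never asserted — they are hardware noise at these sizes.
  Everything else is reproducible field-for-field under a fixed seed.
  Field deployments sometimes judge recommendation quality by student
  satisfaction scoring; that protocol is subjective and has no ground truth
  to simulate, so accuracy here always means agreement with ground-truth
  labels.

## 6. Validation scope and known limitations

Problem sizes in the test-suite were chosen to exercise every code path at
desk scale: 1000 random datasets (≤ 50 rows, ≤ 4 attributes) for the
entropy/gain oracle equivalence, 1000 two-class instances (≤ 60 rows,
≤ 5 attributes) for split-choice agreement, 100 + 100 matrices (orders 3–9)
for AHP recovery and Saaty's bound, cohorts of 150–300 for tree
consistency, and 5 × 30 groups for end-to-end reproducibility.

One validation target is knowingly not met: with 150 training subjects the
planted rule over $4^7$ possible grade profiles is only ~27% covered by the
training sample, and both ID3 variants resolve unseen profiles by majority
fallback, which caps held-out accuracy at roughly 80–85% (the same
experiment with ~2000 training rows exceeds 97%).  Reaching 95% held-out
accuracy at these sample sizes would require near-perfect inter-indicator
correlation, which would no longer resemble a fitness battery.  The
generator's defaults were fixed on realism grounds and the shortfall is
reported as-is rather than engineered away.

Other limitations: no pruning or continuous-attribute thresholding (out of
scope by design); the BMI monotonicity simplification above; recommendation
rules are a starting template, not exercise science; and the windowed
trainer commits to the classic Quinlan loop among the several windowing
variants in the literature.
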