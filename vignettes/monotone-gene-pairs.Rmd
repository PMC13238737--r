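---
title: "Monotone gene-pair classifiers for ordinal outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monotone gene-pair classifiers for ordinal outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordpair)
```

## The model

`ordpair` predicts an ordinal outcome with classes $0, \dots, p-1$ —
internally, **0 is always the worst clinical outcome** and label files must
declare the worst-to-best class order — from the expression of exactly two
genes. A classifier $f(x_1, x_2)$ is admissible when it is monotone: after
multiplying each coordinate by a per-gene sign ($s_1, s_2 \in \{-1,+1\}$,
the *orientation*), $f$ is nondecreasing in both oriented coordinates. Such
an $f$ is equivalent to $p-1$ nested upper sets $U_1 \supseteq \dots
\supseteq U_{p-1}$ (regions closed under coordinate-wise increase), with
$f(x) = \max\{t : x \in U_t\}$ and $f(x)=0$ when $x$ is in none. The fit
minimizes the weighted L1 error $\sum_i w_i\,|f(x_i) - y_i|$, which treats
consecutive classes as equally spaced (distance 1) — the standard working
assumption for ordinal endpoints without a calibrated utility scale.

Monotonicity is deliberately **non-strict**: tied expression values may
share a label, and a point dominated componentwise can never receive a
larger label than its dominator, but flat regions are allowed.

## Exact fitting

The L1 error decomposes over class thresholds: $|f(x)-y| = \sum_{t=1}^{p-1}
\big|\,\mathbf 1[f(x) \ge t] - \mathbf 1[y \ge t]\,\big|$, so the
multi-class problem is a sequence of binary problems — find the monotone
upper set minimizing weighted misclassification of the labels collapsed at
$t$ — coupled only by the nestedness constraint. The solver follows the
divide-and-conquer schedule: the class range is split at its midpoint
($k = \lfloor p/2 \rfloor$ at the top level, fixed rather than heuristic
for determinism), the binary problem at threshold $k$ is solved, and the
recursion descends into the point subsets on each side, the parent boundary
acting as the region constraint. A lattice argument (the minimal optimal
upper sets of the per-threshold problems are automatically ordered by
inclusion) shows the constraint never costs optimality; the test suite
verifies global optimality against an exhaustive enumeration oracle on
hundreds of random instances.

Each binary problem is solved exactly in compiled code by a dynamic program
over the distinct $x_1$ values ("columns"): a monotone upper set restricted
to the data is a nonincreasing per-column $x_2$-threshold, thresholds drawn
from the observed values plus $+\infty$. The DP is $O(m \cdot r)$ in the
distinct coordinate counts — comfortably subquadratic-capable in practice
(a 500-point fit takes ~20 ms) even though it does not implement the
asymptotically faster $O(n \log n)$ divide-and-conquer known for this
regression problem.

### Canonical solution and boundary geometry

Ties between optimal upper sets are broken by returning the **smallest**
one (fewest points assigned high); the DP's reconstruction picks the
largest optimal threshold per column, which realizes that canonical form
deterministically. Boundary **corners are placed at the coordinates of the
fit points assigned to the upper class** (the minimal elements of that
region) and membership is closed ($\ge$ in both coordinates), so a query
exactly on a corner belongs to the higher class. Two degenerate
conventions: if no point is assigned low, the boundary is the whole plane
— encoded as the single corner $(-\infty, -\infty)$ — or a copy of the
parent boundary inside the recursion; if no point is assigned high, the
boundary is empty (no corners).

A consequence worth knowing: because corners sit *at* upper-class training
points, out-of-sample predictions are biased downward — a held-out sample
just beyond the training staircase fails the domination test and falls to
the lower class. This is why even a noise-free planted pair shows a small
positive cross-validated MAE (~0.2 at $n=120$) despite a training MAE of
exactly 0. We kept this geometry rather than, say, midpoint boundaries
because it is deterministic, representation-independent, and conservative
(uncertain samples are pushed toward the worse prognosis).

### Orientation

When no orientation is supplied, all four sign combinations are fitted and
the smallest training error wins, ties broken in the fixed order
$(+,+), (+,-), (-,+), (-,-)$. Inside cross-validation the orientation is
re-selected within each training fold — inheriting it from the full-data
fit would leak information.

## Pair screening

With $G$ genes there are $\binom{G}{2}$ candidate pairs and a $k$-fold CV
of each is the expensive part. The screen exploits that the per-sample MAE
of the optimal fit on *all* samples (`mae_full`) is in practice a lower
bound on the cross-validated MAE (`mae_cv`): training on less data and
scoring out-of-sample cannot beat the optimal in-sample fit. The procedure:

1. compute `mae_full` (one exact fit, no CV) for every pair — it is the
   sort key;
2. visit pairs in ascending `mae_full` (ties by lexicographic pair key),
   computing `mae_cv`;
3. maintain the greedy gene-disjoint set by ascending `mae_cv`; once it
   holds $N$ pairs (`min_disjoint`, the scenario parameter — typically 5,
   10 or 20), its $N$-th member's `mae_cv` is the threshold $\theta$;
4. stop when the next pair's `mae_full` exceeds $\theta$: under the bound,
   no unvisited pair can reach `mae_cv` $\le \theta$. The top set is every
   visited pair with `mae_cv` $\le \theta$ (a superset of the $N$ disjoint
   pairs, matching how top-pair counts exceed $N$ in practice).

The bound is not a theorem of this implementation: each screen counts and
*warns about* observed violations (`mae_full > mae_cv`), and the pruning
guarantee is only claimed for violation-free runs — the test suite checks
exact agreement with a brute-force all-pairs CV in that case and audits the
violation count. Fold assignment is stratified by class, seeded, and
attached to sample identifiers, so results are invariant to the column
order of the matrix; each class must have at least `n_folds` members.

## Ensembles

`build_ensemble()` takes the $m$ best gene-disjoint pairs (greedy by
`mae_cv`; disjointness keeps the members' evidence non-redundant and the
gene signature compact) and refits each on the full training data. At
prediction time each member votes a class and the majority wins; **ties go
to the smallest label**, i.e. the worst outcome — the conservative clinical
choice. With more than two tied labels the smallest tied label wins, the
strict generalization of the two-way rule.

One subtlety: member-wise monotonicity does *not* make the ensemble
monotone under this tie rule. Votes $(1,1,0)$ elect 1, yet the weakly
upward move to $(1,2,0)$ creates a three-way tie and 0 wins. The tie rule
is the documented, deliberate behavior; the guaranteed invariants are that
each member's vote is monotone and that the elected label is always one of
the cast votes. `choose_ensemble_size()` picks $m$ from odd candidates
(default 1, 3, 5, 7, 9 — odd sizes reduce two-way ties; even sizes are
allowed) by minimizing the voted CV MAE under the same stratified folds,
ties toward the smallest $m$.

## Metrics

All metrics are computed from the $p \times p$ confusion matrix (rows =
true, columns = predicted): MAE with unit spacing, accuracy, balanced
accuracy (mean per-class recall), macro-F1 (unweighted mean of per-class
F1, with 0 substituted for a class whose F1 is undefined — the convention
is ambiguous in the field, so it is fixed and documented here), Cohen's
$\kappa$, and the covariance-form multiclass Matthews correlation.
Degenerate denominators — e.g. the MCC of a constant predictor — return 0
with a warning (and a `degenerate` flag) instead of an error, since
collapsed models are a real phenomenon worth reporting rather than
crashing on. Reports round percentages to whole percent and metrics to two
decimals; raw values are always retained.

## Resampling validation

* **Training bootstrap, fixed test set**: `n_boot` (default 1000)
  resamples of the training samples with replacement; the full pipeline —
  including pair re-selection, if the supplied pipeline performs it — is
  rerun per resample and scored on the untouched test set; each metric is
  summarized by its median and central 95% percentile interval
  (`stats::quantile`, type 7). Resamples that lose an entire class are
  redrawn (up to 100 attempts, counted); pipeline failures are recorded
  and skipped, never silently imputed. A pipeline that ignores its
  training data yields exactly zero-width intervals — a useful signature
  of a collapsed model.
* **Permutation test per pair**: the null recomputes `mae_cv` under
  `n_perm` (default $10^4$) label permutations, leaving the pair's joint
  expression intact; $p = (1 + \#\{\text{null} \le \text{obs}\}) /
  (n_{perm}+1)$, which can never be 0.
* **Overlap randomization**: the null redraws both gene sets (or one, by
  flag) from the shared universe and counts overlaps at least as large;
  same add-one estimator.

All resampling is reproducible from the seed in its config object.

## Data handling

Expression is genes × samples, assumed normalized upstream (normalization
and deconvolution are out of scope). MAD filtering uses the raw median
absolute deviation, $\mathrm{median}_s |x_{gs} - \mathrm{median}_s x_{gs}|$
without a consistency constant, and keeps either the top-$k$ genes or
those above a threshold; constant genes have MAD 0 and drop under any
positive threshold. The stratified split draws, per class, the nearest
integer to `train_frac` $\times$ the class size (halves away from zero) —
the rounding rule that reproduces standard published cohort splits exactly,
including 80% of 32 being 26, not 25 — with seeded within-class shuffles.
`train_frac` must be strictly inside $(0,1)$.

## The synthetic generator

`synth_generate()` emulates a MAD-filtered cohort: a small number of
planted gene pairs whose joint expression is monotonically tied to the
label, embedded among independent standard-normal noise genes. For a
planted pair with orientation $(s_1, s_2)$, a latent score $z$ is drawn
from the class's band of the standard normal (bands cut at the cumulative
class-weight quantiles), and the expression values are $x_1 = s_1(z/2+e)$,
$x_2 = s_2(z/2-e)$ with jitter $e \sim N(0, 0.5^2)$. The jitter displaces
points along the anti-diagonal only, so the oriented score $s_1x_1 +
s_2x_2 = z$ is exact and the noiseless planted relation is *exactly*
monotone-realizable: full-data MAE 0 by construction. Label noise enters
only through `flip_rate` (probability a label is replaced by a uniform
class; in the rare event flips empty a class in a tiny dataset, the
pre-flip labels are kept so the container invariant holds). Defaults —
150 samples, 3 balanced classes, 50 genes, one planted pair, 10% flips —
are the calibration scenario used by the recovery tests. Each random
component draws from its own deterministic sub-stream, so adding noise
genes never perturbs planted columns.

What the generator does **not** emulate: RNA-seq count distributions and
mean–variance coupling, library-size effects, batch structure, correlated
co-expression among noise genes, or censoring. A green recovery test
therefore establishes that the pipeline finds an exactly-monotone signal
under label noise among independent Gaussian distractors — not that it
would do so under realistic technical covariation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_folds` | 5 | CV folds; every class needs ≥ `n_folds` samples |
| `min_disjoint` (N) | 5 | disjoint pairs the screen certifies; larger N widens the top set (5/10/20 are the usual scenarios) |
| `sizes` | 1,3,5,7,9 | candidate ensemble sizes (odd) |
| `n_boot` | 1000 | bootstrap resamples |
| `n_perm` | 10⁴ | permutation draws; p-value floor 1/(n_perm+1) |
| `ci_level` | 0.95 | central percentile mass |
| `train_frac` | 0.8 | stratified split fraction, in (0,1) |
| `flip_rate` | 0.1 | synthetic label noise |
| `jitter` | 0.5 | synthetic anti-diagonal expression noise (units of z, the N(0,1) latent score) |

## Numerical choices and degenerate inputs

Comparisons against boundary corners are closed and exact (corners are
stored at data coordinates; JSON serialization uses 17 significant digits
precisely so round-tripped models predict identically). Visit order,
greedy selection and orientation search all carry fixed lexicographic
tie-breaks, making every result deterministic given seeds. Empty inputs,
labels outside $0..p-1$, negative weights, non-finite expression, classes
smaller than the fold count, and sets outside their universe all raise
immediate errors with the offending item named.

## Known limitations

Classifiers use exactly two genes — more features raise both computational
cost and the risk of spurious monotone fits, and are out of scope.
Censored outcomes cannot be used: every sample needs an observed class.
The screening bound is enforced empirically, not proven here; violation
warnings should be taken seriously on small cohorts. The boundary geometry
biases out-of-sample predictions toward worse outcomes by construction;
users wanting symmetric generalization should calibrate on held-out data.
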