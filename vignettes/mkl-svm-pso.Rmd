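---
title: "Swarm-tuned multiple-kernel SVMs for nodule classification"
author: "mklpso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm-tuned multiple-kernel SVMs for nodule classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mklpso)
```

## The problem

In a lung computer-aided-detection pipeline, candidate regions of
interest (ROIs) extracted from CT slices must be classified into true
pulmonary nodules (+1) and false-positive findings (−1). The candidate
sets are strongly imbalanced — false positives typically outnumber true
nodules by a factor of two or more — and the feature vectors computed
from the ROIs are not linearly separable. `mklpso` implements the
classification stage of such a pipeline: a soft-margin SVM with a
two-kernel mixture, tuned by particle swarm optimization (PSO), with a
grid-search baseline and convergence diagnostics for comparing
inertia-weight regimes. ROI extraction and feature computation are out
of scope; the package starts from a labeled numeric feature table.

## The model

The classifier is the standard dual soft-margin SVM. For training pairs
$(x_i, y_i)$, $y_i \in \{-1, +1\}$, the multipliers $\alpha$ solve

$$\min_\alpha \tfrac12 \sum_{i,j} y_i y_j K(x_i, x_j)\,\alpha_i \alpha_j
  - \sum_j \alpha_j, \qquad
  \sum_i y_i \alpha_i = 0, \quad 0 \le \alpha_i \le C,$$

and new points are labeled by
$f(x) = \mathrm{sgn}\big(\sum_i \alpha_i y_i K(x_i, x) + b\big)$.
The kernel is a convex mixture of the two workhorse kernels,

$$K(x, x') = m\,(x \cdot x' + 1)^d + (1 - m)\,
  \exp\!\big(-\|x - x'\|^2 / 2g^2\big),$$

combining the polynomial kernel's generalization behavior with the RBF
kernel's local flexibility. A convex combination of Mercer kernels is
again a Mercer kernel (the Gram matrix is a nonnegative mixture of PSD
matrices); `check_psd()` provides the executable form of that fact and
the test suite exercises it on random Gram matrices.

Three continuous hyperparameters are tuned — the regularization
coefficient $C$, the RBF width $g$ and the mixture weight $m$ — while
the polynomial order is enumerated over $d \in \{2, 3\}$: orders beyond
3 degrade generalization, and a discrete dimension sits awkwardly in a
continuous swarm, so `tune_mkl_svm_pso()` runs one swarm per order and
keeps the better result, ties resolving to $d = 2$.

### RBF parameter conventions

The width convention $\exp(-\|x-x'\|^2/2g^2)$ is canonical here, but
several SVM toolboxes name $\gamma$ in $\exp(-\gamma\|x-x'\|^2)$ by the
same letter. `kernel_params(..., g_as = "gamma")` selects the second
reading, and `gamma_from_width()` / `width_from_gamma()` convert
($\gamma = 1/2g^2$). Reported optima from other software can therefore
be reproduced under either interpretation without guessing which one
was meant.

## The fitness

A hyperparameter point is scored by `cv_fitness()`: stratified k-fold
cross-validation (default $k = 5$) on the training table, pooling the
out-of-fold confusion counts into a single accuracy percentage,

$$\mathrm{ACC} = 100\,\frac{TP + TN}{TP + TN + FP + FN}, \qquad
  \mathrm{SEN} = 100\,\frac{TP}{TP + FN}.$$

Three choices deserve note:

* **Stratification.** With an 80/190 class imbalance, unstratified
  folds have high variance in their class ratios; folds are therefore
  stratified by class, sizes differing by at most one both overall and
  per class, with a seeded shuffle for reproducibility.
* **Pooled counts, not mean of fold accuracies.** Pooling keeps the
  fitness a rational number with denominator $l$ (e.g. $160/170 =
  94.1176$), identical to per-sample counting, and equals the
  sample-weighted mean of fold accuracies exactly (unit-tested
  identity).
* **Scaling inside the fold.** Features are z-scored with training-fold
  statistics only, applied unchanged to the validation fold, so no
  information leaks across the fold boundary.

Prediction ties ($g(x) = 0$ exactly) map to +1, the nodule class — the
recall-favoring choice for a screening task, and a documented, tested
contract rather than an accident of floating point.

## The optimizer

`pso_optimize()` is a global-best PSO over the box
$C \in [0.1, 100]$, $g \in [0.01, 50]$, $m \in [0.01, 0.99]$
(`default_mkl_bounds()`; wide enough to bracket typical optima with
headroom, and keeping $m$ strictly inside $(0,1)$ so the mixture never
collapses). Velocities and positions follow

$$V \leftarrow \omega V + c_1 r_1 (P_i - X) + c_2 r_2 (P_g - X), \qquad
  X \leftarrow X + V,$$

with $r_1, r_2$ fresh uniforms per particle *and* per dimension (the
more common variant; a scalar-per-particle variant changes little but
is not what is implemented). Velocities are capped at 20% of each
dimension's range; positions are clamped to the box, and a clamped
component's velocity is zeroed so particles do not press against the
boundary. Personal/global bests update only on strict improvement, so
ties resolve to the first achiever. The acceleration factors default to
$c_1 = c_2 = 1.49445$, the constriction-derived standard; both are
configurable.

Six inertia-weight regimes are provided (`inertia_weight()`), with
endpoints $\omega_{start} = 0.9$, $\omega_{end} = 0.4$:

| id | form | character |
|----|------|-----------|
| `constant` | $\omega \equiv 1$ | undamped |
| `lin_a`, `lin_b` | linear $\omega_s \to \omega_e$ | two conventional writings of the same line |
| `quad_late` | $\omega_s - (\omega_s-\omega_e)(k/T)^2$ | slow early decay, strong early exploration |
| `quad_early` | $\omega_s - (\omega_s-\omega_e)(2k/T - (k/T)^2)$ | fast early decay |
| `exp_ratio` | $\omega_e (\omega_s/\omega_e)^{1/(1+ck/T)}$ | asymptotic; never reaches $\omega_e$ |

`lin_a` and `lin_b` are algebraically identical and kept as distinct
ids only so comparison reports can carry both rows. The constant $c$ of
`exp_ratio` is not standardized anywhere; the default $c = 10$ puts the
final weight near 0.43 over 200 generations and is configurable. For
$0 < k < T$ the quadratics bracket the line strictly
(`quad_late` > linear > `quad_early`), which the suite checks
analytically.

The per-generation trace records `v_best`, the running maximum of **all**
fitness evaluations so far (hence monotone), and `v_ave`, the mean
fitness of the current particles — the two curves the diagnostics
consume. With the undamped constant weight the swarm keeps oscillating
and will generally not localize an optimum to fine precision; that
behavior is asserted in the tests, since it is the motivation for the
dynamic schedules.

## Diagnostics

`curve_summary()` condenses a trace into the quantities used to compare
regimes: max of `v_best`, mean and median of `v_ave`, the Euclidean
norm of the full best-minus-average gap vector, the convergence
generation $t$, and the normalized post-convergence error

$$F_{gy} = \sqrt{\frac{\sum_{k=t}^{T}\big(V_{best}(k) -
  V_{ave}(k)\big)^2}{T - t + 1}}.$$

$F_{gy}$ is deliberately an RMS — dividing by the window length inside
the root — so that runs converging at different generations, and hence
producing error vectors of different lengths, remain comparable; a
plain norm would grow with the window and conflate lateness with
looseness.

The convergence generation is the first $t$ from which `v_ave` stays
within a band of its final value; the band is 1% of the curve's total
range by default (`epsilon = 0.01`). No standard detection rule exists,
so this one is declared rather than inferred; if only the last
generation qualifies, the curve has not settled and `NA` is returned —
which genuinely happens for well-performing swarms whose mean curve
keeps dipping when single particles wander.

`boxplot_stats()` implements the Tukey convention (type-7 quartiles,
fences at $1.5 \cdot IQR$, adjacents the extreme data points inside the
fences) for summarizing repeated runs.

## Synthetic data

No clinical feature table ships with the package, so two seeded
generators emulate the relevant structure, with the study's class
imbalance (80 positives / 190 negatives) and split (170 train / 100
test) as defaults:

* `generate_gaussian_classes()` — two spherical unit-variance Gaussians
  shifted along the first axis; `separation` (in pooled-sd units) dials
  linear separability from chance (0) to near-perfect (10). The default
  3 gives a Bayes error near 7%, a realistic difficulty for a nodule
  task. Dimension defaults to 10, a typical size for a post-selection
  radiomic feature set.
* `generate_ring_classes()` — a unit disc (+1) inside an annulus of
  radius 2 (−1) with radial Gaussian noise, linearly inseparable by
  construction; the default `noise_sd = 0.2` leaves a narrow but
  nonempty margin. This fixture is what the end-to-end benchmark runs
  on, because it requires the nonlinear part of the mixture to do real
  work.

These generators emulate imbalance, nonlinear class geometry and
controllable overlap. They do **not** emulate correlated or
heterogeneous feature scales, label noise, or the heavy-tailed feature
distributions of real radiomic data — so green end-to-end tests
demonstrate that the machinery optimizes and generalizes on data with
the right shape, not that any particular clinical accuracy is
attainable.

## Numerical choices

* **Solver.** The dual is solved by an SMO working-set method
  (C++ core) with second-order pair selection; default stopping
  tolerance `kkt_tol = 1e-3` on the maximal KKT violation — a standard
  operating tolerance for CV-scored training — and `max_iter = 10 l²`
  pair updates. Tests tighten the tolerance to `1e-8` when comparing
  against an independent interior-point QP solution, where agreement is
  at the `1e-9` level. Non-convergence raises a condition object
  carrying the best iterate.
* **Offset.** $b$ is averaged over all unbounded support vectors
  ($0 < \alpha_i < C$) rather than taken from a single one; with none
  present, the midpoint of the feasible interval implied by the bounded
  points is used.
* **Support threshold.** $\alpha_i > 10^{-8} C$ counts as support.
* **PSD tolerance.** Eigenvalues down to $-10^{-8}\max_i K_{ii}$ pass,
  since exact Gram matrices routinely show round-off-negative
  eigenvalues at this scale.
* **Degenerate inputs.** Single-class training sets, dimension
  mismatches, empty confusion tables and undefined sensitivity (no
  positives) are errors, not silent zeros; a constant feature in a fold
  is centered but left unscaled.

## Problem sizes in the shipped tests

The suite validates the solver against a QP oracle on duals of up to 12
points, kernel PSD on 100 random draws, swarm convergence on a 3-D
quadratic (n = 20, 200 generations, 100 seeds per schedule), and the
end-to-end ring benchmark on the full 270-sample, 170/100 protocol with
the swarm's evaluation budget matched to the 1458-point default grid —
sizes chosen so each property is measured at the scale it is claimed,
while a complete run stays comfortably on one workstation core.

## Limitations

* The fitness is ACC alone; on imbalanced data, configurations with
  mediocre sensitivity can score well. SEN is reported but not
  optimized (a multi-objective fitness is a natural extension).
* Global-best PSO with 20 particles over 3 dimensions has no
  convergence guarantee; the grid baseline is the honest fallback.
* d is enumerated, not searched; orders above 3 are rejected by
  design.
* `cv_fitness` retrains k SVMs per evaluation; the cost of a full
  protocol run is dominated by the swarm budget
  ($n \times T \times |d|$ evaluations).
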