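---
title: "Continuous chromatin state features: model, constraints and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous chromatin state features: model, constraints and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the state space
model behind the annotation, how the non-negativity constraints are
enforced, the numerical and design choices that were genuinely open, what
the synthetic data generator does and does not emulate, and the known
limitations.

## The model and its assumptions

Each epigenomic assay is summarized as mean fold enrichment per 200 bp
bin and variance-stabilized with `asinh(x) = log(x + sqrt(x^2 + 1))`,
which is linear near zero and logarithmic for large enrichment, so large
peaks do not dominate the Gaussian likelihood. For a contiguous chain of
bins the model is linear-Gaussian:

$$y_g = Z\alpha_g + \epsilon_g,\quad \epsilon_g \sim N(0, I_E)$$
$$\alpha_{g+1} = T\alpha_g + v_g,\quad v_g \sim N(0, I_K),\quad
  \alpha_1 \sim N(0, I_K)$$

Assumptions worth making explicit:

* **Unit noise covariances, never re-estimated.** The model equations fix
  both noise terms at the identity; the M-step only updates `Z` and `T`.
  Per-track scale heterogeneity must therefore be absorbed by the arcsinh
  transform. A practical consequence: a track whose (transformed)
  genome-wide variance is well below 1 is largely explained as
  observation noise, and its emission weights shrink toward zero. Sparse,
  narrow marks are the ones affected; broad marks (gene-body or domain
  scale) are comfortably above this floor in real data.
* **The initial state prior is `N(0, I)`.** The model statement leaves it
  open; the unit-variance prior matches the unit-noise convention and
  makes chains exchangeable.
* **Chains are independent.** Chromosome ends, training-region boundaries
  and blacklist gaps split the genome into chains; the filter restarts
  from the prior at each chain start and sufficient statistics add across
  chains.
* **No missing-data marginalization.** Bins with non-finite track values
  are removed and the chain is split at the gap (like blacklisted bins),
  since the Gaussian message passing has no mechanism for partial
  observations.

## EM, regularization, and one notational decision

The E-step runs a Kalman filter and Rauch–Tung–Striebel smoother per
chain (compiled, `src/ssm_kalman.cpp`), accumulating
$\sum_g E[\alpha_g\alpha_g^\top]$, the lag-one cross moments (using the
exact smoothed cross-covariance
$\mathrm{Cov}(\alpha_g, \alpha_{g-1}\mid Y) = P^s_g J_{g-1}^\top$) and
$\sum_g y_g E[\alpha_g]^\top$. The M-step solves ridge-regularized normal
equations.

The penalized objective is stated in the literature in a form that mixes
a *minimize* with a log-posterior plus additive norms. We use the
internally consistent reading: **maximize**
$\log P(Y\mid Z,T) - \lambda_1\lVert Z\rVert_F^2 -
\lambda_2\lVert T\rVert_F^2$ (squared Frobenius, i.e. standard ridge).
The exact derivative of the squared penalty gives the update
$Z = S_{y\alpha}(S_{\alpha\alpha} + 2\lambda_1 I)^{-1}$ and likewise for
`T` with $2\lambda_2$. Defaults are $\lambda_1 = \lambda_2 = 0.01$ —
small relative to any genome-scale likelihood, present to keep the
normal equations well conditioned; with $\lambda = 0$ a singular system
raises an error advising a positive value.

EM stops at `max_iter` or when the relative objective change drops below
`tol` (default `1e-6`). For the unconstrained variant the objective is
provably non-decreasing (asserted in the tests); see below for why this
is not guaranteed under constraints.

## Non-negativity

**States.** After every filter update the mean is projected onto the
constraint set. For non-negativity the projection solves
$\min_\alpha \lVert\alpha - \hat\alpha\rVert^2$ subject to $A\alpha = 0$,
where `A` selects the violated coordinates; because the rows of `A` are
distinct basis vectors the closed form
$\hat\alpha - A^\top(AA^\top)^{-1}A\hat\alpha$ reduces to zeroing the
negative coordinates, and the projection is idempotent (both verified in
tests against the literal formula). Smoothed means are re-projected.

**Emission matrix.** With states fixed, the expected complete-data
log-likelihood separates across tracks: each row of `Z` solves a K-dim
quadratic program $\min_z \tfrac12 z^\top A z - b^\top z$, $z \ge 0$ with
shared Gram matrix $A = S_{\alpha\alpha} + 2\lambda_1 I$. We solve it by
an active-set method of Lagrange multipliers: step from the current point
toward the unconstrained optimum of the free coordinates by the largest
feasible step $\tau_{max}$, pin every coordinate that reaches zero
(simultaneous hits are all pinned), then recompute the multipliers of the
pinned set (the gradient components $A z - b$ at the pinned coordinates)
and release the entry with the most negative multiplier. At exit,
complementary slackness $\Lambda_{e,k} Z_{e,k} = 0$ holds by construction
and all multipliers are non-negative. The published update equations for
this step are typographically fragmentary (index partitions `a`/`−a` with
truncated matrix inverses), so the implementation follows the standard
partitioned-normal-equation reading and is validated against a
brute-force oracle that enumerates all $2^{K}$ pinned subsets per row.
The iteration is capped at 100 cycles per row per M-step.

Whether the line search applies per column of the published layout or to
the whole matrix is unstated; since the subproblems are independent we
solve them independently (per track row in this package's E×K
orientation), which is equivalent to per-column for the transposed
convention.

**Sum-to-one variant.** The extra constraint is implemented as
$\{\alpha \ge 0, \sum_k \alpha_k \le 1\}$ — non-negativity plus a unit
cap, not an exact simplex equality: clamping negatives and then, only if
the sum still exceeds 1, projecting onto the probability simplex by the
sort-and-threshold rule. A brute-force grid oracle checks this is the
Euclidean projection.

**Likelihood under projection.** Projection makes the model
non-Gaussian. The reported objective uses the pre-projection innovations
(a pseudo-likelihood), so EM ascent is only asserted for the
unconstrained variant; constrained runs are stopped by the same relative
change rule but their histories may wiggle. Whether the E-step moments
should use projected or raw means is equally unspecified; both are
implemented (`projected_stats`, default `TRUE`, matching the stated
filter behaviour).

**Numerical choices.** Covariances are symmetrized
($(P + P^\top)/2$) at every step; symmetric-PD inversions fall back to a
`1e-9` diagonal jitter and then to a pseudo-inverse. Feature output is the
*smoothed* posterior mean — the annotation should use all evidence — with
a filter-only flag (`annotate_features(..., smoother = FALSE)`, CLI
`--filter-only`) preserving the causal alternative.

## Genome bookkeeping

* Bins are 0-based half-open; the terminal bin of a chromosome may be
  short and is retained, its mean computed over its actual length.
* Membership of a bin in keep/drop regions uses the **bin midpoint**
  (with closed-interval boundary handling, so a midpoint on a region
  edge counts as inside). This is unambiguous and never double-counts a
  bin into disjoint regions on both sides.
* Uncovered bases read as signal 0, the fold-enrichment convention.
* The per-bin aggregation statistic is the mean, switchable to max
  (`load_signal(..., stat = "max")`); the mean matches the transform's
  variance-stabilizing intent.

## Evaluation protocols

* Gene layout: 5 flank bins over each 5 kb flank (equal fifths — the
  source only says "evenly spaced"), 10 equal body bins, strand-oriented
  so bin 1 is 5'-most. Genes with a body shorter than the bin count are
  skipped with a warning. The whole-gene regression uses the 10
  concatenated body bins by default (a K=3 model gives a 30-slot
  design); a `single_average` flag collapses the body to one K-vector,
  the alternative reading of the protocol.
* Reported adjusted R² is in-sample; the adjustment
  $1-(1-r^2)(n-1)/(n-p-1)$ is the complexity control, matching how the
  protocol is used for model comparison. Collinear design columns are
  dropped (with a warning) and do not count toward `p`.
* Discrete annotations are one-hot encoded per sub-bin (fraction of the
  bin under each label), so the same regressions apply to label-based
  annotations.
* ROC: a genome bin is a positive for an element type if it overlaps any
  element by ≥ 1 bp; thresholds sweep the unique score values and tied
  scores count one half (Mann–Whitney convention), equivalently the
  trapezoid area. The best feature per element type is reported per
  model.

## The synthetic generator

`simulate_ssm()` draws from the generative equations themselves
(optionally clamping states at zero for non-negative ground truth) and is
used for the smoother-oracle, EM-ascent and parameter-recovery tests.

`make_toy_genome()` builds a small genome whose tracks are driven by
three latent activity types — transcription over gene bodies, promoter
activity over the 400 bp upstream of each TSS (written out as the
ROC-positive mask), regulatory activity at promoters and enhancers —
through a fixed response matrix of six tracks (two per type, like paired
histone marks). Design choices made for realism, fixed once:

* response gains put element peaks at fold enrichments of roughly 5–40,
  so the transformed tracks carry genuine contrast against the model's
  unit observation noise;
* peaks decay geometrically into ±3 flanking bins and each painted bin
  carries lognormal jitter (sd 0.3), emulating ChIP peak shoulders and
  bin-to-bin fluctuation — perfectly flat elements would let the
  smoother trade all locality away;
* promoter strength is drawn independently of expression, so flank bins
  carry no hidden shortcut to the expression response;
* expression and eRNA activity are linear in the element's latent
  activity on the arcsinh scale plus Gaussian noise (sd 0.2), stored raw
  so the evaluation exercises the response transform;
* defaults (5 chromosomes × 1 Mb = 25 000 bins, 100 genes, 80
  enhancers) keep every regression well-posed (n comfortably above the
  30-column whole-gene design) while a full train→annotate→evaluate
  cycle runs in about two minutes.

What the toy genome does **not** emulate: read-level noise and peak
caller artifacts, unmappable regions, overlapping or nested elements,
distal enhancer–gene wiring, replicate structure, and the broad
repressive domains of real chromatin. Passing the planted-signal tests
shows the pipeline recovers structure it is built to see, not that the
model resolves everything real epigenomes contain.

## Problem sizes in the checks

The test-suite experiments use: 50 random chains with G ≤ 5, K ≤ 3,
E ≤ 3 for the exact-conditioning oracle; G = 5000 (K = 2, E = 4) for EM
ascent; 100 random instances with E·K ≤ 6 for the constrained-update
oracle; G = 20 000 (K = 3, E = 6) for emission recovery; and the default
toy genome for the end-to-end evaluation. These sizes were chosen as the
smallest at which each property is meaningfully exercised.

## Known limitations

* Gaussian observation model only — no negative-binomial/Bernoulli
  variants, so raw counts or binarized data need external preprocessing.
* No duration modelling: feature persistence is a single AR step `T`.
* Single cell type per fit; joint or stacked annotation across cell
  types is out of scope.
* The constrained objective is a pseudo-likelihood; constrained EM has no
  ascent guarantee (in practice it converges by the relative-change
  rule).
* Features are identified only up to permutation and, weakly, scale;
  interpretation should use the emission heatmap (`autoplot(fit)`), and
  recovery is scored after greedy column matching.
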