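---
title: "Scoring biological-process deregulation with local principal curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring biological-process deregulation with local principal curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Bulk expression cohorts mix samples at very different stages of a disease
process. For a chosen gene set ("biological process"), `lpcscore` asks: *how
far along* the process's deregulation axis does each individual sample sit?
The answer is a Biological Process Score (BPS) in [0, 1] per sample and per
gene set, with 0 anchored at the reference (normal) state.

The method assumes the samples of one process occupy, after normalization, a
noisy one-dimensional manifold in the space of the process's genes: a
progression curve. The curve need not be straight — feedback and saturation
bend expression trajectories — which is why a *local* principal curve (LPC)
replaces the first principal component. The LPC is grown "bottom-up": from a
starting point \(x_0\), the algorithm alternates

1. a kernel-weighted local center of mass
   \(\mu^x = \sum_i w_i X_i\), \(w_i = K_H(X_i - x) / \sum_j K_H(X_j - x)\),
   with Gaussian \(K\) and diagonal bandwidth matrix
   \(H = \mathrm{diag}(h_1^2, \dots, h_p^2)\);
2. the first eigenvector \(\gamma^x\) of the local weighted covariance
   \(\sigma^x_{jk} = \sum_i w_i (X_{ij} - \mu^x_j)(X_{ik} - \mu^x_k)\);
3. a step \(x \leftarrow \mu^x + t_0 \gamma^x\),

until the data cloud's boundary is reached or the centers stop moving. The
ordered centers are interpolated per coordinate by natural cubic splines over
the cumulative chord length \(s\), reparameterized by arc length
\(t(s) = \int_0^s \sqrt{\sum_j \mu_j'(u)^2}\,du\), and anchored so that
\(t = 0\) at the projection of the starting point. Each sample's projection
index — the arc-length coordinate of its nearest curve point — is min-max
normalized into the BPS.

Upstream of the curve, each gene set gets its own *mapping space*: expression
is normalized against the reference samples (each gene centered by the
reference mean and divided by the reference **variance**; the conventional
SD denominator is available via `scale = "sd"`, and a per-gene z-score is the
fallback without references), the lowest-variance quartile of genes is
removed, and a PCA of the set's genes supplies the leading components in
which the curve is fitted. Downstream, the survival harness regresses
clinical outcome on the BPS matrix with an L1-penalized Cox model, computes
the prognostic index \(PI = \beta^\top X\), dichotomizes it so the high-risk
fraction matches the training event fraction, and evaluates by log-rank
tests, ROC/AUC, leave-one-out cross-validation, and cluster–factor
chi-square associations.

## Tunable parameters

All curve-level quantities are in mapping-space score units; defaults are
expressed relative to the data so they are scale-free.

| parameter | default | meaning and rationale |
|---|---|---|
| `scale` | `"variance"` | reference-normalization denominator; the literal convention, `"sd"` available |
| `variance_filter_quantile` | 0.25 | genes below this variance quantile are noise-dominated and removed |
| `pc_excess_fraction` | 0.10 | tumor-over-normal variance excess a component must show |
| `component_rule` | `"normal_total"` | see "Choosing k" below |
| `bandwidth_fraction` | 0.10 | kernel bandwidth per dimension as a fraction of that dimension's range |
| `step_size` | adaptive | one kernel bandwidth along the travel direction, \(t_0 = \lVert(\gamma_j h_j)\rVert\) |
| `tol` | \(10^{-3}\,\bar h\) | center-of-mass movement below this ends a traversal |
| `max_iter` | 150 | per-direction cap; ~15 data diameters at bandwidth-length steps |
| `boundary_frac` | 0.001 | kernel-mass fraction of the cloud's density peak that defines "outside" |
| `angle_penalty` | 1 (off) | optional blending of successive directions |
| `grid_per_interval` | 50 | arc-table density per spline knot interval |
| `normalize` | `"minmax"` | BPS normalization; `"clamp_minmax"` zeroes indices behind the reference origin first |

## Design choices in the curve fitter

**Adaptive step length.** A direction-independent step (e.g. the mean of the
per-dimension bandwidths) can be much smaller than the bandwidth along the
travel direction in anisotropic mapping spaces. The iteration then admits
literal fixed points — the same nearest neighbour dominates the weights, the
center of mass maps onto itself, and the walk "converges" in the middle of
the cloud. The default step is therefore one kernel bandwidth *in the travel
direction*, which reduces to the scalar bandwidth in an isotropic space (the
convention of the LPC literature, which works on range-scaled data).

**Boundary correction.** Centers of mass are convex combinations of the
data, so a fixed-bandwidth walk stalls roughly one bandwidth short of the
data extremes. As the kernel mass decays toward the cloud's edge the
bandwidth is shrunk by the square root of the mass ratio (floored at 25%),
letting the recorded centers follow the data to its extremes. The reference
mass is the cloud's global density peak, so the correction also applies at
the starting end of an anchored traversal.

**Loop stop.** At the far end of a strongly curved cloud the walker can
U-turn and re-trace the curve, which makes projections bimodal. A traversal
therefore stops when its new center returns within half a bandwidth (in the
kernel metric) of a center laid down more than five steps earlier. Angle
penalization, the classical remedy for oversteering, is exposed
(`angle_penalty < 1`) but did not prevent U-turns in our experiments and
stays off by default.

**Initial direction.** The leading local eigenvector's sign is arbitrary.
For a one-sided traversal anchored at the reference centroid the initial
direction is oriented toward the data centroid, so the curve grows from the
normals *into* the tumor cloud. Thereafter signs follow the previous
direction (dot product ≥ 0).

**Projection beyond the ends.** The extreme samples always lie past the last
center (see above), so projecting strictly onto the spline support would tie
all of them at the endpoint indices. Samples beyond the ends are instead
projected onto the linear tangent extensions of the end segments — standard
principal-curve practice — keeping boundary samples distinguishable.
Consequently reported indices may slightly exceed the fitted arc length.

**Orientation of the scores.** With reference samples the origin anchors the
low end and scores grow away from the normals. Without references the sign
of the projection index is not identifiable from the data (reversing the
latent direction is a symmetry of any generative model), so the index is
oriented to correlate positively with the per-sample mean normalized
expression of the set's genes: "higher score, larger overall deviation".

## Choosing k (the mapping-space dimension)

The selection rule keeps leading components along which tumor variation
exceeds what reference samples show, with a floor of one component. The
subtlety is estimation: the PCA is fitted on the pooled, tumor-dominated
sample, so on *pure-noise* components the tumor score variance is inflated
by 1.2–2× relative to the normals' — at any noise level — purely because the
axes chase the majority class's noise. A per-component comparison
(`component_rule = "contiguous"` or `"count"`) therefore tends to run past
the true dimension. The default `"normal_total"` compares each component's
tumor variance against 1.1× the *total* normal score variance; because
reference-based normalization makes genuine tumor signal variance orders of
magnitude larger than reference noise, this recovers the generator's true
dimensionality (k = 1 for linear processes, k = 2 for arcs) across seeds
while remaining conservative about noise components. Without reference
samples the rule degenerates and the smallest number of components reaching
80% cumulative variance is used.

## What the synthetic generator emulates

`simulate_cohort()` generates the structure the method assumes: per process,
tumor samples carry a latent progression \(u \sim U(0,1)\) and each gene
responds smoothly to it — affinely (`line`), along a half-circle
(`arc`: \(a_g\cos\pi u + b_g\sin\pi u\), a curved manifold no single linear
component can parameterize), or sigmoidally (`s-curve`) — plus Gaussian
noise (default SD 0.05, i.e. 5% of the unit response amplitude). Normal
samples sit at \(u = 0\) with the same noise, so "deviation from normals"
holds exactly. Linear and sigmoidal response slopes are drawn from
N(1, 0.5²): predominantly coherent co-regulation, as in progression
signatures, which also makes the no-reference orientation convention
meaningful.

Survival is exponential with log-hazard `hazard_coef` (default 2) times the
mean latent of the driver processes, baseline rate 0.1 per time unit (median
survival around 7 time units at mid-progression — a years-scale cancer
cohort). Censoring defaults to an administrative follow-up window: a fixed
horizon \(\tau\), calibrated by root finding so the expected censored
fraction equals `censor_rate` (default 0.3). Two alternatives are available:
independent exponential censor times, and pure random thinning. Thinning
makes event status independent of risk — any status-based AUC is then
exactly 0.5 — so it is only useful for time-based (log-rank) checks. Even
under the administrative default the status signal is modest: with the
default effect size, the *ideal* prognostic index (the true latent risk)
attains a status AUC of only about 0.66 in the infinite-data limit, which is
the honest ceiling for any estimator evaluated this way on these cohorts.

Features of real data the generator does *not* emulate: batch and platform
effects, heavy-tailed noise, subtype mixtures, correlated gene sets,
branched or disconnected latent topologies, and probe-level artifacts.
Passing tests therefore demonstrate correctness of the machinery under the
stated assumptions, not performance on any real cohort.

## Survival-harness choices

The L1 penalty is selected by 5-fold cross-validation with a deterministic
fold assignment; the cross-validation score is Harrell's concordance,
matching the discrimination objective the prognostic index is evaluated on
(deviance is available and is noticeably more conservative — with weak
signals it often selects the empty model). The risk cutoff is the
\((1-d)\)-quantile (linear interpolation) of the training prognostic
indices, \(d\) the training event fraction, so the labeled high-risk
fraction matches \(d\) within \(1/n\). "Wilcoxon log-rank" is read as the
Peto–Prentice-weighted family; the plain log-rank is the default with
`weighted = TRUE` as the option. LOOCV pools the held-out prognostic indices
into a single AUC rather than averaging per-fold AUCs (undefined for
singleton folds), and transfers each fold's training cutoff to its test
sample. Hierarchical clustering uses Euclidean distance with average
linkage, cut at two groups; chi-square tests switch to a Monte-Carlo
p-value (fixed internal seed) when an expected cell count is zero.

## Numerical details

Natural (second-derivative-zero) spline boundary conditions; with fewer than
4 centers the interpolation is linear, in which case \(t(s) = s\) exactly.
Arc length is tabulated by composite Simpson quadrature on 50 subdivisions
per knot interval (a quarter circle sampled at 9 knots reproduces
\(r\pi/2\) to well under 1%). Projection combines a dense-grid search with
bounded scalar minimization in the best grid cell; ties break toward smaller
\(t\). Duplicate consecutive centers are dropped before chord
parameterization. Degenerate inputs (zero reference variance, constant
genes, sets with fewer than 2 present genes, zero local covariance) are
dropped or skipped with explicit conditions rather than imputed, because the
method is variance-sensitive. Gene symbols match exactly and
case-sensitively by default (`case_insensitive` relaxes this); how upstream
probe sets were collapsed to symbols is the user's responsibility.

## Validation scales

The test suite and the acceptance script exercise the pipeline at the scales
the generator encodes: 200 tumor + 20 normal samples, 20 processes of 15
genes with 3 hazard drivers for survival recovery (20 seeds for the
selection-recall estimate); 300-point semicircles at 5% noise for curved
recovery; zero-noise 200-sample cohorts for the exact linear oracle; and a
100,000-point brute-force grid as the projection oracle. These sizes were
chosen so that each property is measured with comfortable margins at
interactive run times.

## Known limitations

Single connected curves only: branched or disconnected trajectories would
need multiple starting points. One bandwidth per dimension for the whole
traversal (the boundary correction is the only local adaptation); strongly
uneven sample density along the trajectory can still distort the
parameterization. Scores are relative within a cohort — min-max
normalization makes BPS values comparable across samples of one run, not
across cohorts. And a BPS orders samples along deregulation; it does not say
which genes moved up or down.

## A worked example

```{r}
library(lpcscore)

coh <- simulate_cohort(n_tumor = 120, n_normal = 15, n_processes = 5,
                       n_drivers = 2, curve_shape = "arc", seed = 42)
fit <- bps_score(coh$expression, coh$genesets)
summary(fit)

## agreement with the generator's hidden progression
diag(cor(t(fit$values[, colnames(coh$latent)]), t(coh$latent),
         method = "spearman"))

## survival stage
cl <- coh$clinical
model <- fit_cox_lasso(t(fit$values[, cl$sample]), cl$time, cl$status)
model
pi <- prognostic_index(model, t(fit$values[, cl$sample]))
grp <- risk_groups(pi, pi_cutoff(pi, cl$status))
logrank_test(cl$time, cl$status, grp)$p_value
```
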