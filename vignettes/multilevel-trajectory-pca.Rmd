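---
title: "Multilevel PCA of landmark trajectories: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel PCA of landmark trajectories: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynshape)
```

## The problem

A subject performs an action — a blink, a smile — and a fixed set of $M$
landmarks in $\mathrm{Dim}$ dimensions is tracked over the frames of the
capture. Subjects fall into groups (trajectory classes, sexes, scanners).
Two questions drive the analysis: what are the dominant modes of variation
of the *trajectories* (not of single shapes), and how much of that
variation separates groups rather than subjects within a group?

`dynshape` answers both with a functional-flavoured PCA pipeline: each
subject's trajectory is interpolated onto a common regular time grid,
flattened into one feature vector, and the sample of feature vectors is
decomposed either by ordinary PCA or by a two-level multilevel PCA
(mPCA; with two levels this is exactly between-group PCA, bgPCA).

## From frames to feature vectors

Each coordinate channel (landmark $\times$ spatial coordinate) is fitted
with an interpolating cubic spline against time, separately per subject,
and evaluated at $T$ regular times. Choices behind that sentence:

* **Time normalization.** Every subject's time axis is affinely mapped so
  the first frame sits at 0 and the last at 1, and the grid lives on
  $[0,1]$. Captures of different durations and frame counts (the
  smile-like generator draws 100–250 frames per subject) are thereby
  aligned endpoint-to-endpoint. No nonlinear time warping is attempted;
  if actions need phase alignment, that must happen upstream.
* **Spline type.** The interpolant is the classic cubic with
  Forsythe–Malcolm–Moler end conditions (`stats::splinefun`,
  `method = "fmm"`): it passes through every observation and reproduces
  polynomials up to degree 3 exactly, which the test suite asserts to
  $10^{-10}$. A natural spline would not have that reproduction property.
  Subjects with only 2 or 3 frames degrade gracefully to linear or
  quadratic interpolation instead of erroring. The grid never extends
  beyond the observed time range, so there is no extrapolation.
* **No smoothing.** Interpolation, not penalized smoothing: smoothing
  parameters would add a tuning dimension the downstream decompositions
  do not need on capture rates of 100+ frames. Frame-level noise is
  instead attenuated by the grid evaluation and, mainly, averaged out by
  the covariance estimation.
* **Centering.** `center_frames()` subtracts each frame's landmark
  centroid, removing rigid translation at every time point (per frame,
  not per subject, because drift during the capture is also translation).
  No Procrustes rotation or scaling is applied anywhere.
* **Flattening.** Time-major layout: element $t(\mathrm{Dim}\,M) + m\,\mathrm{Dim} + d$
  (0-based) is coordinate $d$ of landmark $m$ at grid time $t$, so
  $L = \mathrm{Dim}\times M\times T$ ($L = T$ for a scalar outcome).
  Every covariance in the package inherits this one convention.

## The two-level model

With subjects $X^{i,j}$ ($i$-th subject of group $j$, $p$ groups of size
$n_j$, all flattened to length $L$):

* group means $\eta^j = \frac{1}{n_j}\sum_i X^{i,j}$, and the **grand
  mean** $\eta = \frac{1}{p}\sum_j \eta^j$ — the unweighted average of
  group means, *not* the pooled subject mean;
* level 2 (within-group): per-group covariances
  $K^{2,j} = \frac{1}{n_j-1}\sum_i (X^{i,j}-\eta^j)(X^{i,j}-\eta^j)^{\!\top}$
  pooled with equal weight, $K^2 = \frac{1}{p}\sum_j K^{2,j}$;
* level 1 (between-group):
  $K^1 = \frac{1}{p-1}\sum_j (\eta^j-\eta)(\eta^j-\eta)^{\!\top}$, whose
  rank — and hence the number of nonzero level-1 eigenvalues — is at most
  $p-1$.

The $1/p$ pooling treats every group identically regardless of size; it
is the conventional multilevel choice, though not the Gaussian maximum
likelihood one. The ML weighting $n_j/n$ is available via
`fit_mpca(weighting = "size")` for comparison. Each level is
eigendecomposed on its own; modes are orthonormal within a level but not
across levels.

**Eigendecomposition.** Every covariance here is $Z^{\top}Z$ for a scaled
deviation matrix $Z$. When $Z$ has fewer rows than columns the nonzero
eigen-pairs come from the small Gram matrix $ZZ^{\top}$ (the snapshot
method) — identical nonzero spectrum, and the only practical route when
$L$ runs into the thousands (the blink design has $L = 32\times101 = 3232$).
Reproducibility niceties: eigenvalues are clamped at zero; an eigenvalue
counts as nonzero when it exceeds $10^{-8}\max(\theta_1, 1)$; each
eigenvector's sign is fixed so its largest-magnitude entry is positive;
exactly tied eigenvalues keep backend order, and no result should depend
on the basis inside a tied eigenspace.

**Scores.** A new trajectory $X$ is expanded as
$X \approx \eta + \sum_l a^1_l \psi^1_l + \sum_l a^2_l \psi^2_l$. The
coefficients minimize the squared residual; since the objective is
quadratic, the global optimum is the closed-form least-squares solution
over the concatenated mode matrix, computed by SVD with the minimum-norm
convention when modes are collinear across levels. Collinearity is not
exotic: in both Monte Carlo designs the between-group direction lies
inside the span of the within-group modes, in which case the joint fit
splits a group offset between levels. For reconstructing *group mean*
trajectories, fit with `m2 = 0` (level-1 modes only) — that is also how
the recovery analysis below is run. By default `m1` is the full level-1
rank and `m2` the smallest count reaching 95% of level-2 variance.

**Standardization.** Scores are divided by $\sqrt{\theta_l}$, the mode's
standard deviation, so training scores have unit sample variance per
mode. (Dividing by $\theta_l$ itself would make the conventional
$\pm1.96\sqrt{\theta}$ prediction band dimensionally inconsistent, which
settles the choice.) Modes with numerically zero eigenvalues are
reported absent rather than divided by; asking for them is an error.

**Small-sample pathology.** Between-group PCA concentrates *any*
difference between group means — including pure sampling noise — into at
most $p-1$ modes, so spurious group separation appears when group sizes
are small relative to $L$. The package warns (class
`dynshape_pathology_warning`) whenever some $n_j < L$, following the
rule of thumb that per-group training size should exceed the feature
length. It deliberately does not "correct" anything; cross-validated
variants are out of scope.

## What the generators emulate

All three simulators are seeded and reproducible; equal seeds give
bitwise-identical data.

**Sine waves** (`simulate_sine`): scalar trajectories
$x(t) = (A_j + \varepsilon_i)\sin(2\pi t/P_j)$, group 1 with period 2 and
amplitude 0.5, group 2 with period 1.5 and amplitude 0.4, observed at
$T = 101$ regular times on a window of one full group-1 period, with one
amplitude perturbation $\varepsilon_i \sim N(0, 0.03^2)$ per subject.
"Magnitude 0.03" is read as a standard deviation (not a uniform
half-width). Between-group variance then dominates within-group variance
by roughly two orders of magnitude. Under this scalar-noise reading each
group's deviations span a single direction, so the pooled level-2
covariance has rank exactly 2; a per-time-point noise variant
(`noise = "timepoint"`) is provided because a frame-wise reading would
instead give a full-rank level 2 — the choice is documented, not
resolvable from the design description alone.

**Blink** (`simulate_blink`): 16 points on two parabolic lid arcs through
shared eye corners. The blink class closes to 2% of the rest aperture at
mid-trajectory *by dropping the upper lid onto the fixed lower lid* —
anatomically, the upper lid does the closing — while the surprise class
widens the whole aperture to 130% symmetrically. The asymmetry matters:
it makes the two class deformation patterns linearly independent, so the
pooled within-group covariance has exactly two modes (one amplitude
mode per class); a symmetric-scaling blink would collapse them into one.
Per-subject scalar amplitude noise ($\sigma = 0.03$) multiplies the
class deformation.

**Smile-like** (`simulate_smile_like`): an explicitly synthetic stand-in
for dynamic 3D mouth captures — 12 lip landmarks, two sex groups (31/29),
$T = 60$ grid ($L = 60\times12\times3 = 2160$). Its structure: a shared
smile deformation (corners pulled outwards and backwards, returning
towards rest), per-subject amplitude noise, a per-subject resting
curvature mode (upturned vs downturned mouth), a small between-sex mean
offset (default near zero: the emulated finding is a *weak* sex effect),
irregular frame counts at jittered time stamps, and frame-level
landmark-tracking jitter (`jitter_sd = 0.01`). The jitter term is what a
dynamic scanner actually leaves on every frame; it keeps the
within-group covariance full-rank. Without it the generator's
within-group space is two-dimensional, and group-mean sampling noise
then reproduces across independent draws — held-out comparisons behave
qualitatively unlike real data. Passing tests on this generator
demonstrate the machinery, not any claim about real faces.

## Validation design and problem sizes

The test suite checks the implementation against independent oracles:
brute-force double-loop covariance summation (to $10^{-10}$ at small
$L$), dense-versus-snapshot spectra (to $10^{-8}$), normal-equations and
random-search checks of the score fit, and exact spline reproduction of
cubics. End-to-end checks run at $n_j = 1000$ per group with $T = 101$
for both Monte Carlo designs — for the blink design that is a deliberate
desk-scale reduction from $n_j = 10{,}000$; the eigenvalue ranks and the
level-1/level-2 dominance ratio are population quantities insensitive to
$n_j$ at these sizes. Group-mean recovery reconstructs each group's
analytic sine from the grand mean plus the level-1 centroid score
(`m2 = 0`) on a held-out set and asserts a maximum absolute error below
0.02, comfortably above the $O(\sigma/\sqrt{n_j})$ sampling scale.

## Known limitations

* **The single-mode within-group band undercovers.** The band
  $\pm1.96\sqrt{\theta^2_1}\,\psi^2_1$ around a group's fitted trajectory
  is only an approximate 95% prediction interval. With two groups whose
  noise directions differ, the $1/p$ pooling mixes both directions into
  mode 1: the mode carries only about half of each group's own variance
  along its own direction, and its shape is a compromise between groups.
  On the sine design the empirical pointwise coverage of the group-1
  band is about 79%, not 95% — reproduced by `scripts/acceptance.R` as
  `sine_level2_band_coverage_pct`. Coverage improves with more level-2
  modes or with group-specific within-group covariances; the package
  keeps the conventional pooled model and reports the number honestly.
* Exactly two levels; the containers would admit an $N$-level
  generalization but none is implemented.
* No Procrustes superimposition, size normalization, nonlinear time
  registration, or classification of new subjects into groups.
* Standardized level-1 centroid separations on *training* data are
  scale-free (for $p = 2$ they are pinned at $\sqrt2$ regardless of
  effect size); judging whether a group effect is real requires held-out
  data, as in the comparative tests.
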