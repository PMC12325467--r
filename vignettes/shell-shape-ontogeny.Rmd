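---
title: "Ontogenetic shell shape trajectories and adult-size thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontogenetic shell shape trajectories and adult-size thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellont)
```

## The problem

Comparative studies of turtle shell shape usually want adult morphologies,
but specimen collections mix juveniles, subadults and adults, and there is
no agreed size at which a shell "counts" as adult. `shellont` operationalises
that decision: given 3D landmark configurations of shells spanning a
species' growth range, it quantifies how shape changes with size and derives
the minimum straight carapace length (SCL) at which a species' adult shell
shape is effectively reached, expressed as a percentage of the largest SCL
ever recorded for that species.

## The model, step by step

**Superimposition.** All configurations are superimposed by generalized
Procrustes analysis: each is centred and scaled to unit centroid size, then
iteratively rotated onto the running mean shape until the consensus changes
by less than `tol = 1e-8` (root-mean-squared coordinate change). Reflections
are never allowed — shell landmarks have left/right anatomical identity —
so the optimal rotation's determinant is forced to +1. Residual coordinates
are pure shape. Before PCA the aligned shapes are orthogonally projected
onto the tangent space at the consensus (removing the radial direction);
the projection can be disabled (`tangent = FALSE`) for sensitivity checks,
and none of the downstream regressions depend on it.

**Allometry.** For each species, flattened shape coordinates are regressed
on log10 centroid size. Significance comes from residual randomization in a
permutation procedure (RRPP): residuals of the intercept-only reduced model
are permuted (999 permutations by default, giving a p resolution of 0.001),
the multivariate F is recomputed each time, and
p = (1 + #\{F\* ≥ F\}) / (1 + n~perm~). The effect size Z is the
standardised position of ln F among the permuted ln F values. With n ≤ 8
the permutations can be enumerated exhaustively, making p exact. For the
shape ~ size + sex model, terms are evaluated sequentially (size first),
each against its own reduced model; specimens of unknown sex are excluded
from sex models only.

**Shape proxies.** Two one-dimensional summaries of allometric progress are
carried forward. The common allometric component (CAC) is the unit vector
in shape space of size-associated change (covariance of centred shapes with
centred size, normalised); specimen scores are projections onto it.
PredLine ("multivariate shape") is the first principal component of the
model's fitted values. Both are sign-oriented to correlate non-negatively
with size, so growth curves rise. The two behave differently by
construction: CAC scores retain the nonlinear along-trajectory signal,
whereas PredLine scores are an affine function of log size for the
single-predictor model, so PredLine-based growth curves plateau only as far
as the log transform does. This mirrors the observation that CAC-based
curves plateau more cleanly than multivariate-shape curves.

**Gompertz shape-growth curves.** Shape scores are modelled against SCL with
f(x) = c + (d − c)·exp(−exp(−k·(x − x₀))), lower asymptote c free (scores
can be negative), upper asymptote d the adult shape level, rate k, and
inflection x₀. Fitting is Levenberg–Marquardt nonlinear least squares from
a data-driven self-start (c₀ = min score, d₀ = max score, x₀ at the
steepest local score change, k₀ = e / IQR(SCL)) plus at least five seeded
jittered starts; the lowest-RSS converged fit wins, and a fit that stops
without formal convergence is returned flagged rather than dropped. k is
bounded positive; everything else is free.

**Threshold 1 — asymptote confidence bound.** From the fit's covariance
matrix, the Wald lower bound of the asymptote at the 90% level,
L = d − z₀.₉₅·SE(d), is intersected with the curve in closed form,
x = x₀ − ln(−ln((L − c)/(d − c)))/k. When the bound does not cut the rising
limb (L ≤ c or L ≥ d, which includes SE(d) = 0 and wildly uncertain
asymptotes), no threshold is inferred — the analogue of declining to draw a
threshold for species without a visible stationary phase. Note the
direction of the level: lowering `ci_level` narrows the interval, raises L,
and moves the threshold later.

**Threshold 2 — 85% of the juvenile-to-maximum shape distance.** The
trajectory score is evaluated at 1000 evenly spaced sizes from the smallest
sampled specimen to the species' maximum recorded SCL, scores are mapped to
landmark configurations by linear regression of shape on score, and the
Procrustes distance d(x) from the smallest-size shape is accumulated
(monotonized by running maximum so numerical noise cannot create spurious
early crossings). The threshold is the size at which d(x) reaches 85% of
d(max), linearly interpolated between the bracketing grid points — exact
for linear trajectories and within one grid step otherwise. The default
score-on-size model is the fitted Gompertz curve; a linear model is
available (`trajectory = "linear"`), but a linear trajectory makes the
predicted shape path linear in size, which forces the threshold to
min + 0.85·range for every species regardless of the data — so the Gompertz
trajectory is the scientifically meaningful default. Thresholds are
reported as percentages of the per-sex maximum recorded SCL; for species
with strong sexual size dimorphism (an analyst-supplied flag, not
auto-detected) the larger sampled sex's record is used.

**Staging and disparity.** Within each species, specimens are clustered on
(standardised) proxy score and SCL — standardisation matters, raw mm would
swamp the scores — by Ward agglomeration on Euclidean distances, cut at
three groups labelled small/intermediate/large by ascending mean SCL.
Pooled across species, stage disparity is measured two ways: sum of ranges
of the PC scores (all axes with variance above 1e-12 of the leading one)
and Procrustes variance of the aligned coordinates (mean squared distance
to the stage mean shape). Both are bootstrapped (1000 replicates,
percentile 95% CIs); the range-based sum of ranges is additionally rarefied
to the smallest stage's size, since ranges grow with n and the large stage
is typically about twice the small one. Stages are compared by Zou's
overlapping-CI test, reconstructed as a midpoint/implied-SE z statistic:
with interval midpoints m and implied SE = width/(2z), the statistic is
|m₁ − m₂|/√(SE₁² + SE₂²), with two-sided normal p and Bonferroni correction
over the three pairs.

## The synthetic-data generator

Real shell growth series cannot ship with the package, so every stage is
validated against a generator with analytic ground truth. A species is a
schematic half-ellipsoid carapace of K = 20 landmarks (index 1 anteriormost,
index 12 posteriormost, so the anterior–posterior chord is the SCL), unit
centroid size, deformed along a fixed unit direction in shape space — by
default "elongate and narrow", the dominant ontogenetic trend in turtle
shells — by a Gompertz function of SCL. Isotropic Gaussian landmark noise,
optional sexual size/shape dimorphism and a random digitising frame
(rotation, translation, scaling so that the landmark-1-to-12 distance
equals the specimen's SCL in mm) complete a specimen. Sizes are sampled
with a bias toward large specimens, museum-style, and each series is
anchored at its range endpoints, emulating the inclusion criterion that a
usable ontogenetic series spans juveniles to adults. The analytic
85%-distance threshold of the planted trajectory solves
(g(x) − g(x~min~))/(g(x~max~) − g(x~min~)) = 0.85 in closed form and is the
recovery target for the whole pipeline.

Default calibration: deformation range d − c = 0.15 Procrustes units with
per-coordinate noise 0.003 (2% of the signal range along the trajectory).
The amplitude is deliberately small: unit-centroid-size normalisation is
nonlinear in the deformation magnitude, and small amplitudes keep the
planted trajectory in its linear regime so the analytic truth stays exact.
The noise keeps score-level noise at 2%, which makes threshold recovery
accurate to well under one percentage point at zero noise and about one
point at the default.

**What the generator does not emulate.** Real data are messier in ways that
matter: the multivariate R² of the synthetic allometric fits (≈ 0.5–0.85)
is higher than the 0.09–0.46 observed across real turtle species, species
in the default panel share one base shape, and landmark noise is isotropic
while digitising error is not. Passing the recovery tests therefore shows
the estimators are correct and well-behaved under clean Gompertz growth; it
does not show that thresholds from small noisy museum samples carry small
uncertainties — on real data they demonstrably do not, which is why the
asymptote-bound threshold is reported but not emphasised. In the default
ten-species panel, each species mixes a shared elongation trend (weight
0.7) with a species-specific deformation direction, so juveniles resemble
each other while adults diverge — reproducing the ontogenetic disparity
increase that motivates the staging analysis.

One known sequential-model artefact is worth naming: with a strongly
nonlinear (Gompertz) trajectory and a large sex difference in size
distributions, curvature lack-of-fit from the linear size term leaks into
the sex term of the size + sex model and can inflate its false-positive
rate. At the ~15% size dimorphism typical of the study taxa the sex term
holds its nominal level; at extreme confounding (30%+ with pile-up at the
recorded maximum) it does not, and conclusions about sexual shape
dimorphism in such species should rely on sex-balanced sampling instead.

## Numerical choices and degenerate inputs

- GPA convergence: RMS consensus change < 1e-8, 100-iteration cap, error on
  non-convergence; degenerate (zero-centroid-size) configurations are
  rejected at input validation.
- Procrustes distance between already-aligned shapes is the plain Euclidean
  norm; between raw shapes both are unit-scaled and optimally rotated first.
- The permutation Z uses the permuted ln F values only; with 999
  permutations the difference from including the observed value is
  negligible.
- Gompertz fits on flat data (zero score variance) are an error, not a
  degenerate fit; a fit whose every start fails raises a convergence error.
- `distance85_threshold` errors on flat trajectories (zero total distance)
  rather than returning an arbitrary size; the pipeline records such
  species in its manifest and continues.
- Zou's test with two zero-width intervals returns statistic 0/p 1 at equal
  midpoints and an infinite statistic (flagged) otherwise.
- Stage clustering with zero variance in both variables is an error; with
  exactly k specimens each forms its own stage, ordered by SCL.

## Reproducibility and problem sizes

Every stochastic step (permutations, bootstrap, multi-start jitter,
simulation) takes an explicit integer seed; the pipeline expands one global
seed into independent per-species streams, so adding a species never
perturbs another species' inference. The packaged validation suite runs at
deliberately desk-scale sizes — ten-specimen superimposition oracles,
exhaustive permutations at n = 5, a ten-species recovery panel of ~214
specimens, and fifty seeded disparity simulations at stage sizes
195/367/351 — chosen so the full suite completes in a few minutes while
still exercising every code path at the study's group sizes where it
matters.

## Limitations

- Thresholds inherit the Gompertz assumption; shape change that never
  plateaus (or follows a different sigmoid) yields curves whose asymptote
  bound is rightly absent, and the 85%-distance threshold then reflects the
  fitted, not the true, trajectory.
- The asymptote-bound threshold uses a Wald interval from the NLS
  covariance; profile-likelihood intervals are out of scope.
- Ward linkage and variable standardisation for staging are defensible but
  not uniquely determined choices; both are exposed as arguments.
- Sliding semilandmarks, missing-landmark estimation and phylogenetic
  corrections are out of scope.
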