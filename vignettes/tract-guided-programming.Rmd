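---
title: "Tract-guided programming of STN DBS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract-guided programming of STN DBS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Programming a subthalamic (STN) deep brain stimulation (DBS) system with an
8-contact directional lead means searching a large space of contacts, levels
and amplitudes during time-consuming monopolar reviews. Two white-matter
pathways anchor the search: activation of the **hyperdirect pathway (HDP)**,
cortico-subthalamic fibers terminating in the dorsolateral STN, is
associated with the therapeutic effect (rigidity reduction), while
activation of the **corticospinal tract (CST)** in the adjacent internal
capsule produces capsular side effects. `tractstim` implements a pipeline
that turns weighted tractography of these two pathways into programming
suggestions and evaluates them against the clinical review.

The pipeline has five stages:

1. **Geometry** — an 8-contact directional lead (1-3-3-1 layout: distal
   ring, two levels of three 120° segments, proximal ring) is placed from a
   pose (tip, axis, marker rotation). For any configuration (contact C1–C8,
   level/pseudoring L1–L4) and amplitude, a simplified volume of tissue
   activated (VTA) is produced.
2. **Activation** — for each VTA, the fraction of each pathway's total
   streamline weight (SIFT2 convention) carried by streamlines intersecting
   the VTA.
3. **Stimulation models** — one logistic regression per pathway mapping
   activation fraction to the probability of (side) effect, trained on
   monopolar-review thresholds, under nested leave-one-subject-out (LOSO)
   cross-validation.
4. **Suggestions** — per-configuration effect and side-effect thresholds,
   and best/worst level and contact under three strategies.
5. **Evaluation** — balanced accuracy against the clinical labels,
   right-tailed permutation tests, and threshold-error statistics.

A synthetic-cohort generator reproduces the statistical structure of such a
study from a known ground truth, so every stage is exercisable and testable
without patient data.

## The VTA model

The clinical pipelines this package interoperates with compute VTAs as
thresholded electric fields from a finite-element model. `tractstim`'s
kernel is deliberately simpler and pluggable: the homogeneous point source.
A current $I$ in a medium of conductivity $\sigma$ produces
$E(r) = I / (4\pi\sigma r^2)$; thresholding at $E_t$ gives a sphere of
radius

$$ r(I) = \sqrt{\frac{I}{4\pi\,\sigma\,E_t}} . $$

Defaults are $\sigma = 0.33$ S/m (grey matter) and $E_t = 0.2$ V/mm, giving
$r(1\,\mathrm{mA}) = 1.10$ mm and $r(8\,\mathrm{mA}) = 3.11$ mm —
millimeter-scale VTAs consistent with clinical experience. The activation
threshold is sometimes quoted in V/m in the literature; at 0.2 V/m a 1 mA
point source would activate a centimeter-scale sphere, so V/mm is adopted
as the unit here. A single conductivity is used because the homogeneous
kernel admits only one; the white-matter value (0.14 S/m) is accepted in
`vta_params()` for completeness.

Ring contacts and pseudorings (all three segments of a level driven
together) produce a sphere at the level centroid; the package applies the
full amplitude to the pseudoring sphere since no current-splitting rule is
imposed. A directional segment produces a sphere at the radially offset
segment centroid, clipped to an angular sector about the segment's outward
normal. The default sector width of 180° covers the 120° contact span plus
spread; it is configurable. VTAs of the same configuration are nested in
amplitude by construction, which makes activation profiles monotone — a
property the test suite checks on random geometry.

## Streamline activation

A streamline counts as "inside" a VTA if any part of its polyline
intersects it — segment intersection, not vertex membership — so the test
is robust to the streamline step size. For sphere VTAs the exact
point-to-segment distance is used; sector VTAs additionally require an
in-sector point on the portion of the segment inside the sphere (sampled
at 0.01 mm for single queries, 0.05 mm for bundle profiles; the radius
increment between adjacent 0.5 mA grid steps is at least 0.25 mm, so this
sampling cannot reorder profile values). Voxel-mask VTAs densify the
polyline to half the voxel size and vertex-test, recovering the
vertex-in-voxel convention of Lead-DBS-style pipelines.

Because a VTA at fixed configuration only grows with amplitude, each
streamline has a *critical radius*: the smallest VTA radius at which it is
hit. Activation profiles over the amplitude grid are computed by
thresholding critical radii once per configuration, which makes the
monotonicity of profiles structural rather than numerical.

The activation of a bundle is the sum of the weights of the hit
streamlines divided by the bundle's total weight, a scale-invariant ratio
in $[0,1]$. Activation is always computed against the bundle of the lead's
hemisphere; cross-hemisphere activation is taken to be zero.

## Stimulation models

For every tested configuration, the training set receives one negative
sample — the activation at 0.5 mA, a setting with some spread of small
activations but no clinical effect — and, when the relevant threshold was
observed before the 8 mA sweep end, one positive sample at the threshold
activation (effect threshold for the HDP model, side-effect threshold for
the CST model). Censored thresholds (">8") contribute no positive sample.
Negatives are built only for configurations that actually appear in the
review; inventing rows for untested contacts would fabricate clinical
data.

The fit is an L2-penalized logistic regression with a single predictor
(the activation fraction, untransformed). The intercept is unpenalized and
the penalty is parameterized by its inverse strength $C$, following the
convention of the scikit-learn implementation this mirrors; the solver is
a damped Newton iteration on the two-parameter objective. $C$ is selected
from a log grid $\{10^{-2}, \dots, 10^3\}$ by subject-grouped inner
cross-validation (5 groups) maximizing the balanced accuracy of pooled
out-of-fold predictions, with ties resolved toward stronger
regularization. Pooling the out-of-fold predictions avoids degenerate
single-class inner folds. Classification uses a probability cutoff of 0.5
with ties classified as "effect".

The outer loop is leave-one-subject-out: one fold per subject, inner
selection restricted to the training subjects, per-fold accuracy on the
held-out subject's samples, and a normal-approximation 95% CI across
folds. The *pooled boundary* reported by `loso_cv()` is the mean of the
per-fold decision boundaries $-\beta_0/\beta_1$ (the activation at 50%
probability), mirroring the averaged-curve summary such studies report.
Model cards also report the inverse activation at several probabilities
(0.5, 0.95, 0.99) rather than fixing a single "certain effect" cutoff,
because the logistic curve approaches 1 only asymptotically.

## Suggestion strategies

`suggest_threshold()` returns the smallest amplitude on the 1–8 mA grid
whose activation the model classifies as effect, or a censored result.
Three strategies label each lead:

* **initial** — best level/contact is the lowest suggested effect
  threshold (HDP model); worst is the lowest suggested side-effect
  threshold (CST model).
* **combined** — configurations whose suggested effect threshold exceeds
  the suggested side-effect threshold by more than 1 mA are excluded
  (side effects would precede full effect); among the rest, lowest effect
  threshold wins. A censored side-effect threshold keeps a configuration;
  a censored effect threshold excludes it.
* **window** — largest therapeutic window (side-effect minus effect
  threshold) wins.

Censored side-effect thresholds substitute 8.5 mA — one grid step past the
sweep end — in window arithmetic, preserving the ordering without
inventing a finite observation. Tie-breaking is deterministic: for "best",
(1) larger therapeutic window, (2) lower effect threshold, (3) more distal
configuration; for "worst", (1) smaller window, (2) more distal. Level
candidates are the distal ring (L1 = C1), the two pseudorings (L2, L3) and
the proximal ring (L4 = C8); contact candidates are C1–C8, with rings and
segments competing on equal terms.

## Evaluation

Best/worst labels are scored as paired binary vectors with one entry per
candidate per lead (4 levels or 8 contacts), concatenated across leads —
a highly unbalanced design (one positive in four or eight), hence the
balanced accuracy $\tfrac12(\mathrm{TPR} + \mathrm{TNR})$ as the statistic.
The permutation test shuffles the concatenated suggestion vector uniformly
(a within-lead mode exists as a sensitivity option) and applies a
right-tailed test; under a uniform shuffle of a binary vector the true
positive count is hypergeometric, so the implementation draws it directly,
which is identical in distribution to explicit shuffling and makes 100,000
permutations cheap. The p-value uses the add-one correction
$p = (1 + \#\{T^\ast \ge T\}) / (1 + n)$ so it is never exactly zero; the
plain fraction is available behind a flag.

Threshold errors compare suggested with clinical thresholds per
configuration; pairs with a censored member are excluded (no numeric
difference is defined for ">8") and their count reported. Contact
distances between suggested and clinical best contacts use the lead
geometry (same-level flag and centroid distance).

## The synthetic cohort

The generator emulates the study conditions the analysis assumes: 20
subjects with bilateral 8-contact leads, review sweeps from 1 to 8 mA in
0.5 mA steps, and 60.8% of directional contacts tested. Its geometry is a
stylized hemisphere in world mm (x lateral, y anterior, z superior; the
left side mirrors x):

* **STN** — an ellipsoid with semi-axes (5, 3, 3) mm centered at
  (12, −13, −7), with a dorsolateral pole direction (1, 0, 1)/√2 and a 45°
  dorsolateral sector cone.
* **HDP** — 500 streamlines per hemisphere descending as cubic Bézier
  curves from an 8 mm motor-cortex disc and terminating inside the
  dorsolateral sector, approaching from the dorsolateral side; the
  approach control points fan out with a 4 mm standard deviation so the
  funnel has a realistic few-millimeter waist at the border instead of
  collapsing onto a line. Lengths are capped at 90 mm (over-long paths are
  straightened toward the chord).
* **CST** — 2000 streamlines in a 2 mm tube descending through the
  internal-capsule region, its core offset (4.5, −4.2) mm posterolateral
  of the STN center with per-streamline tilts of at most 0.005 rad: close
  enough that clinical amplitudes clip its near edge, far enough that no
  streamline enters the STN. Lengths fall in [80, 135] mm.
* **Leads** — anchored with the closest level near the dorsolateral
  border: 1.2 mm outside it along the dorsolateral direction, with a
  ±2 mm axial depth draw (implantation depth varies between patients by
  more than the transverse targeting error; without this the best level
  would degenerately be level 2 for every lead), 1 mm isotropic Gaussian
  jitter, up to 10° axis tilt and uniform marker rotation.
* **Weights** — log-normal(0, 0.8), heavy-tailed like SIFT2 weights.

Reviews are simulated from ground-truth logistic models with boundaries
$a_{50} = 0.10$ (HDP) and $0.01$ (CST) and slopes 60 and 600: the true
threshold of a configuration is the first grid amplitude whose activation
reaches the boundary. Observed thresholds jitter by one grid step with
probability 0.2 — noise acts on thresholds, not on per-amplitude Bernoulli
draws, because a monopolar review records monotone sweep outcomes — and
the sweep aborts (censoring the effect threshold) when side effects
precede full effect, as clinical sweeps do.

What the generator does *not* emulate: cortical and capsular anatomy
beyond these stylized shapes, FEM field inhomogeneity, fiber-diameter- or
orientation-dependent activation thresholds, rater variability beyond
one-step jitter, and any correlation between a subject's two hemispheres.
Passing tests on this cohort therefore demonstrate that the pipeline's
statistics recover a known generating mechanism of the assumed form — not
that the clinical effect sizes would reproduce on real data.

## Numerical choices and degenerate inputs

* Thresholds are validated against the 0.5 mA grid at 1e-9 tolerance;
  censoring (">8") and missingness (untested, empty field) are distinct
  states throughout.
* The Newton solver damps its step until the penalized objective
  decreases and stops at a 1e-10 parameter change; single-class training
  sets are an error (or a skipped fold with a warning inside LOSO).
* Duplicating every training sample changes the fit only through the
  fixed ridge term; with a weak penalty and overlapping classes the
  boundary is invariant, and with separated classes the penalty is what
  keeps the optimum finite at all.
* `balanced_accuracy()` refuses empty classes rather than returning NaN.
* All-censored candidate sets yield the label `"none"`, which scores as
  all-zero suggestion entries rather than dropping the lead; leads without
  any clinical label are dropped with a warning.
* Sector membership at the VTA center (zero radius vector) is defined as
  inside.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full default cohort (20
subjects, 40 leads, 500 + 2000 streamlines per hemisphere), a noiseless
variant, 1000-cohort permutation calibrations, and oracle comparisons on
hundreds of random geometries. These sizes were chosen so the entire suite
completes in a few minutes on one core while every statistical claim is
still exercised at the cohort scale the models assume.

## Known limitations

* The point-source VTA ignores tissue heterogeneity, anisotropy and
  electrode encapsulation; it preserves the thresholded-e-field semantics,
  not FEM accuracy. The kernel is a parameter (`vta_params()`) precisely
  so a better field model can be dropped in.
* Pseudoring VTAs apply the full amplitude at the level centroid; no
  current-splitting model is attempted.
* The stimulation models are univariate per pathway; multi-pathway or
  interaction models are out of scope.
* TRK-format tractograms, spatial normalization and tract extraction from
  whole-brain tractograms are out of scope; bundles arrive as TCK +
  weights in the same physical space as the lead poses, so atlas-derived
  bundles can be supplied exactly like patient-specific ones.
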