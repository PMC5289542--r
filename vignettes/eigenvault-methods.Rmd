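---
title: "Extended eigenshape analysis of cranial vault outlines: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended eigenshape analysis of cranial vault outlines: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(eigenvault)
library(dplyr)
```

## The problem

Intentional cranial modification reshapes the infant skull by bandaging, and
different binding techniques leave different vault profiles: annular
(circumferential) binding produces tall/vertical or obliquely sloping
elongated vaults, while a two-bandage variant (a circular bandage plus a
vertical crown-to-chin bandage) restricts vault height and leaves a
depression near bregma. Given 2D outlines of crania in left lateral view,
anchored at four craniometric landmarks — the occiput point on the cranial
base line, lambda, bregma, and glabella — the task is to quantify vault shape,
ordinate specimens in a morphospace, and ask how well group membership
(different modification traditions, plus an unmodified baseline sample) can
be recovered from shape alone.

`eigenvault` implements this as a pipeline of classical outline
morphometrics: landmark-anchored segmentation, equal-arc semi-landmarks,
Generalized Procrustes Analysis (GPA), Zahn–Roskies phi-functions, a
covariance singular value decomposition ("eigenshapes"), and stepwise
Wilks'-lambda discriminant analysis.

## The model, step by step

**Segmentation.** Each outline is split at its anchors into three open
curves: occipital (occiput to lambda), parietal (lambda to bregma) and
frontal (bregma to glabella). The straight inferior base segment from
glabella back to the occiput carries no curvature and is excluded. Segments
share their joint landmarks; wherever segments are concatenated the
duplicated joint vertex is dropped, so the whole-outline and per-segment
analyses use one consistent data structure.

**Semi-landmarks.** Within each segment, points are placed at equal arc
length along the piecewise-linear digitized curve. No spline is fitted: at a
200-point digitizing density the polyline approximation error is far below
the shape signal, and a spline would add an unspecified smoothing parameter.
Counts are harmonized across specimens per segment; the default policy takes
the maximum raw count observed for that segment, so the specimen with the
most complex curvature sets the sampling density. A fixed-count override
exists for controlled experiments. Note that equal-arc resampling of a
polyline is exactly idempotent only when the resampled vertices have uniform
chords (straight lines, constant curvature); for general curves a second
resampling moves points by O(step^3).

**Procrustes alignment.** Configurations (the concatenated segments) are
centred, scaled to exactly unit centroid size, and iteratively rotated to
the evolving consensus; reflections are excluded because all specimens are
digitized in the same lateral view. Convergence is declared when the
consensus root-mean-square change falls below 1e-10 (at most 100
iterations); at these problem sizes the loop converges in a handful of
iterations. Two conventions pin otherwise arbitrary freedoms: the consensus
(and with it the whole aligned set) is rotated onto the first
configuration's input orientation, and scaling is applied exactly rather
than left to the least-squares fit. Aligned shapes are therefore
reproducible up to a single global rotation; the test suite checks
invariance properties after removing that gauge.

**Phi-functions.** Each aligned segment is converted to its cumulative
tangent-angle representation: the signed turning angle between successive
chords (atan2-based, wrapped to (-pi, pi]), accumulated from the segment's
second vertex — the standard Zahn–Roskies construction for open curves, with
n - 2 values for an n-point curve. Step lengths and the start pose are
retained, so the transform inverts exactly (round-trip error is at machine
precision; the suite drives this over 1,000 random curves). Phi is invariant
to translation and rotation by construction, which makes the preceding
Procrustes step partly redundant: alignment is performed anyway, both
because the source procedure does so and because it standardizes the start
headings that anchor reconstructed shape models. One discretization property
is worth stating explicitly: for an open curve sampled in m equal arcs the
accumulated turning is (m - 1)/m of the continuous total curvature (the two
end tangents contribute half-turns the chord construction cannot see), so a
quarter circle at 100 arcs accumulates 0.99 × pi/2, not pi/2. Closed curves
include the wrap-around turns and recover the full turning number 2*pi
exactly.

**Eigenshapes.** The composite phi vectors (occipital, parietal, frontal
concatenated) form a specimen-by-variable matrix. It is mean-centred and
decomposed by SVD — equivalent to an eigen-decomposition of the covariance
matrix with divisor n - 1. Covariance (not correlation) is used: phi
variables share units (radians), and standardizing would inflate
low-curvature regions. No reference phi (circle or straight line) is
subtracted; mean-centring plays that role, and variance fractions are
invariant to the choice. The sign of each eigenshape is pinned so that its
largest-magnitude loading is positive, removing the SVD sign ambiguity from
scores and plots. Per-segment submodels decompose the relevant column block
of the same matrix.

**Shape models.** A phi vector only encodes turning angles, so drawing the
shape at a morphospace position needs a pose: step lengths, a start point
and a start heading. Models fitted through the pipeline store the mean pose
per segment (mean aligned step lengths, mean start point, circular-mean
start heading), so reconstructions are displayed in anatomical orientation;
segments are glued at their shared joints. For bare matrices without pose
information a neutral default (equal steps, vertical start) is used.

**Discriminant analysis.** Eigenscores feed a stepwise Wilks'-lambda
procedure: at each step the candidate minimizing the resulting lambda is
entered if its partial F-to-enter is significant at p < 0.01; after each
entry, any included variable whose partial F-to-remove has p > 0.10 is
dropped; at most six variables are retained. These thresholds are the
procedure's defaults and are all exposed in the configuration. Ties on
lambda are broken toward the lower axis index, so selection is
deterministic. Significance uses Rao's F approximation to Wilks' lambda
(exact for one or two variables or two groups). Classification is the
Gaussian linear discriminant rule with pooled within-group covariance and,
by default, equal priors (the conservative choice when the original tool's
setting is unknown; proportional priors are one option away). With equal
priors and two groups the rule reduces to nearest-Mahalanobis-mean
assignment. Pairwise squared Mahalanobis distances between group means are
reported with Hotelling-type F statistics on (p, n - g - p + 1) degrees of
freedom.

**Cross-validation.** Tables are leave-one-out: each specimen is classified
by a model fitted on all others. By default the stepwise selection is made
once on the full data and reused inside every fold — the presentation most
stepwise-discriminant software prints; a stricter per-fold reselection mode
(`reselect_in_cv = TRUE`) is available and labeled, because selection reuse
lets a small amount of information leak into the folds.

**Per-segment discriminant runs** default to using *all* eigenshapes rather
than stepwise selection, matching the way segment analyses are usually
reported; "all" is capped at n - g - 2 axes and at axes whose relative score
variance exceeds 1e-8, so the pooled covariance stays nonsingular in every
leave-one-out fold. The stepwise variant is available via
`segment_selection = "stepwise"`.

## Numerical choices

- Wilks' lambda is computed as det(solve(T, W)) rather than det(W)/det(T):
  the eigenvalues of T^-1 W lie in (0, 1], which avoids determinant
  underflow when many retained axes carry tiny variance. Scatter matrices
  with reciprocal condition below 1e-12 are rejected with advice to use
  fewer variables.
- Optimal rotations come from the 2x2 SVD of the cross-covariance with the
  determinant corrected to +1 (reflections excluded).
- Zero-length steps in a curve are an error (relative tolerance 1e-12 of
  total length), not silently dropped: a coincident-point outline indicates
  a digitizing fault upstream.
- All percentages in rendered tables are rounded to one decimal, matching
  the conventional presentation of classification tables.

## The synthetic cohort generator

Because the deposited specimen data cannot be redistributed with the
package, a parametric generator stands in for it. The baseline is a smooth
convex half-oval vault over a horizontal base of length 2, traversed
anti-clockwise from the occiput baseline point through lambda (arc fraction
0.30) and bregma (0.60) to glabella, sampled at 200 equal-arc points — the
digitizing density of the source data; the four anchors sit at fixed arc
fractions so landmark homology holds by construction. The spec of 200
points is taken to cover the curved vault only, not the straight base
(which the analysis excludes anyway); this choice is exposed via
`total_points`.

Deformations are applied in order: vertical elongation about the baseline;
a shear tilting superior points posteriorly (oblique annular profiles); a
Gaussian-profile depression around the bregma region (the vertical bandage
of the two-bandage technique); and radial digitizing noise. The noise is a
smooth low-frequency field (six random harmonics over arc fraction, scaled
to a standard deviation of 0.5% of vault scale) rather than independent
per-point jitter: digitizing error on a smooth outline is spatially
correlated, and independent jitter of the same magnitude would dominate the
turning angles at 200-point chord lengths, which no real tracing of a
smooth vault does.

The three presets encode the study conditions: `modern` is unmodified
(elongation 1.00 ± 0.04) with noise only; `hungary` is the two-bandage
profile — moderate elongation (1.25 ± 0.06), slight obliquity, a mild, wide
bregmatic depression (depth 0.12 ± 0.03 of local height, width 0.12 arc
fraction) whose centre varies slightly from pre- to post-bregmatic — with
deliberately small spreads, because the two-bandage tradition is described
as producing uniform, shape-restricted vaults; `georgia` is a mixture of a
tall/vertical component (elongation 1.60 ± 0.15), an oblique component
(elongation 1.25 ± 0.10, obliquity 0.35 ± 0.08 rad) and a 10% minority
two-bandage component, reflecting the diversity of binding styles in that
sample. The depression parameters were set mild and wide because a deep,
narrow, position-varying dent concentrates enormous variance into the phi
representation and would contradict the low-variance character the
two-bandage group is defined by.

What the generator does *not* emulate: asymmetry and pathology, digitizing
gaps, the face and cranial base (excluded from the analysis anyway),
allometry, sex differences, and any within-group correlation structure
beyond the parameter distributions. Passing the synthetic checks therefore
shows that the pipeline recovers group structure and generating parameters
under controlled conditions, not that real data will classify at the same
accuracies. Sampling variability matters at n = 20 per group: the
qualitative contrasts (complete modern/modified separation, Georgian
dispersion exceeding Hungarian) hold at the default seed and most others,
but single draws can blur them; the tests pin the seed for that reason.

## Problem sizes used in the tests

Unit tests run the full pipeline at 80–120 outline points and 5–8 specimens
per group; the acceptance-level checks use the full study conditions (200
points, 20 specimens per group, three groups) and 1,000 random curves for
the phi round trip. The complete suite runs in well under a minute.

## A worked run

```{r run}
cohort <- generate_study_cohorts(n = 20, seed = 1)
report <- run_whole_outline(cohort)
report
```

```{r variance}
generics::tidy(report$eigenshape) |> head(5)
```

```{r plots}
plot_scores(report)
plot_shape_axis(report, axis = 1)
```

Per-segment analyses of the two modified groups:

```{r segments}
segrep <- run_segments(cohort, groups = c("georgia", "hungary"))
sapply(c("frontal", "parietal", "occipital"),
       function(s) round(100 * segrep[[s]]$eigenshape$variance_fractions[1], 1))
```

## Known limitations

- The stepwise procedure follows the classic enter/remove partial-F scheme;
  other implementations differ in F approximations and tie handling, so
  reproduced classification tables can deviate by single specimens.
- Ternary displays of the first three eigenshapes use normalized squared
  scores as proportions; signed scores have no canonical ternary embedding,
  so the plot is an interpretation aid, not part of the model.
- Closed-curve eigenshape analysis (rotational phase alignment) and sliding
  semi-landmarks are out of scope; segment anchors are treated as fixed,
  homologous points.
- The GPA consensus orientation is pinned to the first specimen; analyses
  that must be invariant to specimen order should compare Procrustes
  distances or remove the gauge, as the tests do.
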