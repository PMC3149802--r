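---
title: "Methods: statistical shape modelling and ASM search in spineasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical shape modelling and ASM search in spineasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spineasm)
```

`spineasm` segments vertebral bodies in grey-level images with an Active
Shape Model: a point-distribution model of landmark coordinates constrains
a local, profile-driven search. This vignette records the modelling
assumptions, the parameter defaults and why they were chosen, the numerical
decisions, and what the synthetic validation does and does not establish.

## Landmark representation

A vertebra contour carries `L` landmarks (default 20), corners plus
equidistant points on each edge, ordered counter-clockwise on screen from
the upper anterior corner; corners sit at landmarks `1, L/4+1, L/2+1,
3L/4+1`. The classic published layout shows 16 points with corners at
1, 5, 9, 13; experiments in the source literature use 20 points per
vertebra without stating the layout, so the equal-points-per-edge scheme is
generalised to any `L` divisible by 4 — a documented choice, not a given.
Coordinates are continuous (subpixel), 0-based, origin at the top-left
pixel centre, y downward. The anterior side is assumed to be the
smaller-x side of the image; mirrored images must be flipped beforehand.

## Alignment and the shape model

Pairwise alignment minimises the weighted sum of squared distances between
corresponding landmarks over similarity transforms; the solution is the
exact complex least-squares fit, so no iterative pair optimisation is
needed. Weights default to uniform: the alignment is described as
"weighted" in the source method but no weights are defined, so the hook is
exposed (`weights` argument) and left at 1.

Generalized Procrustes analysis follows the quoted loop: align everything
to the first shape, then iterate mean computation, mean re-normalisation
against the first shape, and re-alignment of all shapes to the mean. The
mean is re-normalised to *the first shape* (the alternative "default size,
orientation and origin" is not specified in the source and is omitted).
Convergence is declared when the RMS displacement of the normalised mean
between iterations falls below `tol = 1e-6` with a cap of 100 iterations
(no values are given in the source; these are tight enough that the
anchored frame is reproducible to well below the 1e-5 tolerance used in the
invariance tests). The recorded per-iteration objective is divided by the
squared centroid size of the current mean so values are comparable across
re-normalisations.

The shape model retains the smallest `t` leading eigenvectors of the
sample covariance reaching `variance_fraction = 0.98` of total variance
(the source does not state how `t` is chosen; 0.98 is conventional for
ASMs), capped at the covariance rank `min(2n, f − 1)`. A `1e-12` slack on
the retention boundary prevents eigenvalue rounding from flipping exact
boundary cases. Eigenvector signs are fixed (first component of magnitude
above 1e-12 made positive) for reproducibility.

**Mode bounds.** The plausibility interval for the mode weights is
`|b_i| <= 3 * sqrt(lambda_i)` by default. The source text prints the bound
as `±3 λ_i`, but three *standard deviations* (`±3 √λ_i`) is the standard
ASM constraint and the printed form is most plausibly a typesetting loss of
the radical; both are available (`bound = "sqrt"` or `"raw"`). Weights are
clamped every iteration of the search (the alternative — only testing
acceptability — is supported by calling `clamp_modes` yourself).

## Grey-level profiles

At each landmark the contour normal is the perpendicular to the chord
joining its two neighbours on the closed contour, oriented away from the
vertebra centroid. `k_p + 1 = 8` grey levels are sampled bilinearly at
half-integer offsets symmetric about the landmark (spacing = 5 % of the
vertebra size, i.e. the distance between that vertebra's upper and lower
anterior corner landmarks — the source scales by "vertebra size" without
defining the measure, and the corner distance is what the initializer
provides). First differences give the `k_p = 7` gradient values.

Normalization follows the source wording: every gradient is divided by the
sum of the sampled grey levels (`norm = "grey_sum"`). This is unusual —
the classic ASM normalizer is the sum of absolute gradients — so
`"abs_grad_sum"` and `"none"` are selectable. Note the grey-sum form is
*not* invariant to adding a constant to the image; the classic form is.
A zero normalizer (all-black window) yields an all-zero profile rather
than a division error.

Per-landmark covariances are symmetrised and inverted after ridge
regularization `eps = 1e-6 * trace(S)/k_p` (or `1e-6` if the trace is 0,
e.g. identical training images), since small training sets make `S`
singular; `eps` is recorded in the model file.

## Semiautomatic initialization

Two user clicks (upper anterior corner of the first vertebra, lower
anterior of the last) bound the search window (margin 25 px) and set the
geometric prior: with anchor distance `d` and `N` vertebrae, vertebra
height `alpha = 4 d / (5 N - 1)` and gap `beta = alpha / 4`, which satisfy
`d = N alpha + (N - 1) beta` exactly.

Candidates come from a Harris detector (k = 0.04, tensor window sigma = 2,
derivative smoothing sigma = 1, non-max suppression radius 3 px, responses
at least 1 % of the maximum) run on the grey window, with a Canny edge map
(smoothing sigma = 1.5, hysteresis thresholds at the 70th/90th percentiles
of nonzero gradient magnitude) computed in parallel for the filters; no
detector parameters are given in the source, so these are conventional
defaults, all exposed. Raw response peaks localise corners 1–3 px inside
the body (the structure tensor smears the corner), so each candidate is
refined by the gradient-orthogonality condition (every window gradient
must be orthogonal to its offset from the corner point — the standard
subpixel corner solve), and refined duplicates within 2 px are merged.

Two filters then prune candidates, both by tracing the 8-connected Canny
contour from the nearest edge pixel (association radius 3 px):

* *contour support*: a candidate survives only if the traced contour
  reaches an arc length of one estimated vertebra height;
* *angle*: the angle at the candidate between the two contour points at
  arc distance `0.25 * alpha` either side must lie in 10°–160°. The
  neighbour distance is "fixed experimentally" in the source with no
  value; a quarter vertebra height keeps the probe inside one edge
  segment. Candidates with fewer than two traceable neighbours are
  dropped.

The 2N anterior corners are the shortest alternating path from the top
anchor to the bottom anchor: an upper corner must be followed by a lower
corner at distance within `alpha ± delta_alpha`, a lower by an upper
within `beta ± delta_beta`, with `delta_alpha = 0.4 alpha` and
`delta_beta = 0.75 beta` (the windows are "fixed experimentally" in the
source; these accommodate the generator's shape variation and tilt without
admitting cross-column shortcuts). The literal progression rule ("the next
point's y-coordinate lower than the current") reads, in image coordinates
with a downward spine, as monotone progression toward the bottom anchor;
the implementation therefore requires each added point's projection onto
the anchor axis to increase strictly, which also handles tilted spines
(`literal_y = TRUE` restores the literal reading). The final step that
appends the bottom anchor is required to satisfy the `alpha`-window too,
so every returned sequence satisfies all window constraints. Ties in total
path length break by lexicographic candidate index. A depth-first search
with branching capped at the 8 nearest feasible candidates and at most
10,000 complete sequences guards complexity; the caps are reported in the
diagnostics when hit, and optimality is verified against exhaustive
enumeration on small instances in the test suite.

## Search

The mean shape is placed on the detected corner pairs: per vertebra an
exact two-point similarity map of the model's anterior corner landmarks
onto the pair (vertebra model), or one joint least-squares similarity over
all 2N correspondences (column model). Each iteration moves every landmark
to the minimum-Mahalanobis position among `2m + 1` candidates along its
normal (`m = 5`, step = profile spacing; the source does not state the
extent) — ties prefer the smallest, then the negative, offset — and then
re-fits pose and clamped weights by alternation (inner tolerance 1e-6, cap
20). Pose updating can be disabled (`pose_update = FALSE`) since the
source's search loop does not spell out pose handling.

A landmark counts as "moved" when it is displaced by more than 0.5 px
between iterations, so subpixel jitter cannot stall the convergence
counter. The search stops when the moved count falls to 10 % of the
previous count (or to zero — the stricter full-stability rule), with a
250-iteration cap. With a vertebra model, each vertebra is segmented
independently. Profile spacing is fixed at the initialization scale per
vertebra, keeping the search deterministic: identical inputs give
identical outputs.

## Synthetic phantom

The generator renders `N = 5` bright convex quadrilateral bodies
(intensity 180 on background 60, mimicking radiograph contrast on the
0–255 grey scale) of height `alpha = 40` px with gap `beta = 10` px
(the 4:1 prior holds by construction), width 1.25·alpha, on a canvas with
25 px margins. Each body is deformed by exactly two generative modes —
anisotropic width scaling (4 % per unit weight) and horizontal shear
(0.06 px per px height per unit weight), weights drawn N(0, 1) — so a
correct PCA has a known two-dimensional answer. Each image draws a spine
tilt uniform in ±2°; rendering is anti-aliased (4×4 coverage
supersampling), followed by Gaussian blur (sigma 1 px) and additive
Gaussian noise (sd 3 grey levels). Ground-truth landmarks come from the
same corner geometry via `default_marking`, so they lie exactly on the
pre-blur outline; the two anchors are the true outer anterior corners.
All randomness flows from one seed.

These defaults are the package's study conditions: training sets of 75
images and 20 held-out test images are used by the acceptance script and
the end-to-end tests (smaller sets, f = 12–25, are used in unit tests for
speed), matching the 75-image sample size the source identifies as a good
compromise in its sample-size study.

What the phantom does *not* emulate: posterior vertebral elements and
spinous processes, overlapping anatomy and soft tissue, exposure and
contrast variation, scatter, pathology (osteophytes, fractures), and
out-of-plane projection. Passing the synthetic suite shows the
implementation is correct and self-consistent under the method's own
assumptions; it does not certify clinical accuracy, and the published
success rates on clinical radiographs are not comparable quantities.

## Evaluation

Point-to-line error is the distance from each segmented landmark to the
closed polygonal ground-truth contour of its vertebra; point-to-point is
the distance between corresponding landmarks (never smaller). The source
describes both under its error measure, so both are reported. A vertebra
counts as a success when its mean point-to-line error is at or below a
threshold, 2 px by default on synthetic data — the source's own success
threshold is unstated, so rates are not comparable with its clinical
table. An optional pixel-spacing converts errors to millimetres.

## Known limitations

* The contour tracer assumes thin (non-maximum-suppressed) edges; dense
  edge clutter can misdirect the angle probe at junctions.
* The shortest-path criterion can prefer a straighter impostor sequence if
  corner candidates are systematically displaced inward; subpixel corner
  refinement exists precisely to prevent this, but heavy blur beyond the
  defaults would degrade it.
* Profile statistics are learned at the training image scale; large scale
  mismatches between training and test vertebrae are only partly absorbed
  by the vertebra-size-proportional spacing.
* The column model shares one pose for the whole spine, so strong local
  curvature trades off against individual vertebra fit — the reason the
  vertebra model is the default.
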