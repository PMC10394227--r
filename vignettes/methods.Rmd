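---
title: "Voting decoders, body priors and uncertainty-weighted 2D-3D correction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voting decoders, body priors and uncertainty-weighted 2D-3D correction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posevote)
```

# The problem

Keypoint detectors for articulated bodies emit one heatmap per joint:
a low-resolution grid whose mass concentrates near the joint's image
position. Two chronic problems follow. First, the classical argmax (or
local-window soft-argmax) readout discards most of the map and gives
no usable confidence. Second, purely 2D readouts know nothing about
body structure, so occluded joints land wherever the (corrupted)
heatmap says. `posevote` implements the two counter-measures as
reusable, deterministic numerics: a whole-map voting decoder with
per-axis uncertainties, and an iterative correction of the 2D joints
against a normalized 3D body prior in which unreliable joints carry
less weight.

# The voting decoder

For a `w x h` map the decoder sums the grid along each axis,
producing the voting weight vectors `z_u` (length `w`) and `z_v`
(length `h`). Each vector is softmax-normalized into a distribution
`z*` over the position enumeration `e = (1, ..., n)`, and

- coordinate: `x = sum_j z*_j e_j`,
- uncertainty: `c = sqrt( sum_j z*_j (e_j - x)^2 )`,

i.e. the expectation and standard deviation of the vote distribution.
The softmax makes the decode invariant to adding any constant to the
map, so raw (even negative) network outputs need no rectification.
Coordinates are 1-based grid units internally, matching the
enumeration; the JSON writers convert to 0-based pixel coordinates at
the file boundary.

Two readings of "standard deviation of the voting values" are
possible: the standard deviation of the distribution `z*` over the
positions `e` (implemented), or the standard deviation of the products
`z*_j e_j` themselves. We implement the distributional reading because
it is exactly the scale parameter that the decoder's Gaussian
likelihood loss

`L_KB = sum_i [ log(sqrt(2*pi) c_i) + (x_i - xhat_i)^2 / (2 c_i^2) ] + omega_c sum_i 1/(2 c_i^2)`

interprets as the per-coordinate sigma; the product reading has no
such role. The constant inside the logarithm is the exact negative
log of the Gaussian density (`sqrt(2*pi) c`); an alternative reading
(`2*pi*c`) differs by an additive constant and cannot affect
optimization, so the choice is cosmetic and recorded here. With every
`c` frozen at 1 the loss is half the summed squared error plus a
constant, which the tests assert exactly. `omega_c` defaults to 0.2;
it penalizes confidence inflation (`c -> infinity` hides errors) and
gives the loss an interior optimum in `c` at `sqrt(err^2 + omega_c)`.

## Decoder bias and the marginal gain

The softmax exponentiates the *accumulated* map, so the sharpness of
the vote depends on the scale of the heatmap values — a property worth
making explicit because it drives every accuracy figure in this
package. If the axis marginal peaks at `g` ("marginal gain"), far-off
grid columns each carry softmax mass about `exp(-g) / Z`. That tail
mass does not move with the bump, and it pulls the expectation toward
the grid center by roughly `w * exp(-g) * (center - x)`. Three regimes
matter:

- small `g` (weak responses, e.g. attenuated/occluded bumps): the vote
  is nearly uniform, the coordinate collapses toward the grid center,
  and `c` is large — which is exactly the behavior the correction
  stage exploits;
- moderate `g` (default renderer gain 10): subpixel decoding with mean
  error a few hundredths of a grid unit and residual center pull on
  the order of 1e-3;
- large `g` (gain 25 in the equivariance tests): the tail mass is
  ~1e-9, and integer-shift equivariance of the decode holds to 1e-6.

Because of this the synthetic renderer (below) controls amplitude via
the marginal gain rather than a raw peak value, emulating the logit
scale a trained head produces. Uncertainty then grows monotonically
with bump width at fixed gain, as a calibrated confidence should.

# Body parameters

Shape is a 10-vector `beta` (the openly available coefficients of
statistical body models), typically in `(-1.5, 1.5)`; the shape loss
is a Smooth-L1 with its quadratic region widened to that range
(`(2/9) d^2` inside, `(2/3)|d| - 0.5` outside, continuous with equal
slope `2/3` at the seam). Per-joint rotations use scalar-last unit
quaternions built from axis-angle with angle in `(-pi, pi]`, which
pins the hemisphere (`cos(a/2) >= 0`) and removes the `(q, -q)`
double-cover ambiguity from the L1 pose loss
`||theta - theta_hat||_1 + omega_p |1 - ||theta||_2^2|`. The
regularizer is applied per joint and the loss summed over joints; the
formula is stated for a single joint in its source context and the
reduction is our choice, made for consistency with the other summed
losses. The combined objective weights default to
`lambda_shape = 0.2, lambda_pose = 0.25, lambda_SMPL = 0.15,
lambda_KB = 0.3, lambda_DET = 0.4`; the detector loss itself is out of
scope and enters as a number.

# The synthetic kinematic body

A true statistical mesh model is deliberately not shipped; the
downstream geometry only needs the interface
`(beta, theta) -> 3D joints`. The stand-in is a 17-joint COCO-like
kinematic tree (pelvis root, spine-neck-head chain, two arms, two
legs) with base bone lengths in plausible adult proportions (units are
arbitrary — normalization removes scale). A fixed, internally seeded
sparse basis maps `beta` to bone-length offsets, scaled so offsets
stay within 30% of the base length over `|beta| <= 1.5`; bones are
checked positive. Forward kinematics composes quaternion rotations
down the tree, so bone lengths are pose-invariant by construction.

Scenes are drawn as: `beta ~ U(-1.5, 1.5)^10`, local joint rotations
with angles `U(-0.3, 0.3)` rad about random axes (moderate
articulation; extreme contortions are not the regime of interest), a
global orientation uniform on SO(3), orthographic projection at 5 grid
units per skeleton unit centered on a 32 x 32 grid (keeping joints
usually >= 3 sigma inside the borders), Gaussian bumps with
`sigma = 1.5`, i.i.d. pixel noise, and per-joint occlusion that
*attenuates* the bump to 10% amplitude rather than deleting it — so
occluded joints still decode, but badly and with high uncertainty,
which is the premise the weighting is designed around.

What the generator does **not** emulate: perspective, limb
foreshortening interacting with a real camera, structured background
clutter, multi-peak ambiguity (left/right confusion), inter-person
occlusion, and any learned-detector error correlation. Passing tests
therefore certify the algebra and geometry of the pipeline under
controlled corruption — not performance on photographs.

# Weighted alignment and the iterative correction

The weighted Kabsch problem
`min_{R,t} sum_i (1/2) w_i ||R p_i + t - q_i||^2` is solved by
centering both sets at their weighted centroids and taking the SVD of
the weighted cross-covariance `C = sum_i w_i q_i p_i^T = U S V^T`,
with `R = U D V^T`, `D = diag(1, 1, det(U V^T))`. The determinant
factor selects the best *proper* rotation when the unconstrained
optimum is a reflection (mirrored skeletons are anatomically invalid);
mirrored inputs exercise this branch in the tests. Configurations with
cross-covariance rank below 2 (collinear points) are rejected. The
solver's optimality is tested against a brute-force oracle: its
objective must not exceed the best of 1e5 rotations sampled uniformly
from SO(3) on a thousand random weighted instances.

The correction takes the decoded 2D pose and a normalized 3D prior
(zero centroid, unit pooled standard deviation over all `3k`
coordinates) and proceeds:

1. weights `w_i = 1/c_i`, with `c_i` the mean of the two axis
   uncertainties floored at `1e-3` grid units (the floor keeps
   weights finite; it is far below any decodable uncertainty);
2. normalize the 2D set: remove the weighted centroid, divide by the
   pooled standard deviation;
3. initialize depths by a scaled-orthographic fit: solve the
   *unconstrained* least-squares `2 x 3` map `M ~ s R[1:2,]` from the
   centered prior to the normalized 2D, orthonormalize its rows by
   SVD, complete the third row by the cross product (proper by
   construction), and set `z_i = s * r_3 . q_i`;
4. iterate (default 3 times): lift `(u, v, z)`, re-normalize the
   lifted set, align the prior onto it with the weighted Kabsch
   (rotation only — scale is absorbed by the two normalizations),
   update the depths from the aligned prior, record the weighted
   residual restricted to the `(u, v)` components;
5. output the aligned prior's projection, mapped back to input units.

The depth initialization deserves its own paragraph. Initializing with
a flat lift (`z = 0`) makes the first alignment fit a 3D body onto a
plane; the rotation is then biased toward flattening the prior, and
the alternation converges only linearly — far too slowly for the
3-iteration budget on rotations with substantial depth variation. The
closed-form scaled-orthographic start is exact on noise-free input
(the least-squares `M` recovers `s R[1:2,]` whenever the prior has
rank 3), so the Kabsch iterations begin at — and provably remain at —
the fixed point: corrected 2D equals the observation and the depths
match the true normalized depths to machine precision, up to the
single global depth sign that orthographic projection cannot
determine. Under noise the iterations do the real work of trading
observation against prior. Residuals are recorded per iteration and
are non-increasing on clean input; the per-iteration re-normalization
of the lifted set is what lets a rotation-only alignment account for
the scale difference between a 2D pooled norm and a 3D pooled norm.

By default the corrected output *replaces* the decoded `(u, v)`. An
optional per-joint convex blend (`blend = TRUE`) keeps a fraction
`1/(1 + c_i)` of the observation, so confident joints move less; it is
off by default because the appropriate mixing degree depends on how
well calibrated the uncertainties are, which the package cannot know
for externally supplied heatmaps.

# Metrics and the benchmark

MPJPE is the mean Euclidean joint error in the input units (grid units
for synthetic 2D; no physical-unit conversion is attempted without a
calibrated camera). PA-MPJPE first aligns prediction to truth by the
closed-form least-squares similarity (rotation, translation, uniform
scale — the scale via the standard ratio of the aligned cross-term
trace to the prediction's scatter), then evaluates MPJPE. Because the
alignment minimizes *squared* error, the numeric oracle in the tests
minimizes the SSE and reads the mean distance at its optimum; the
identity transform is always feasible, so PA-MPJPE never exceeds
MPJPE.

`correction_benchmark()` draws seeded scenes and scores three
conditions on identical inputs: raw decode, unweighted correction,
weighted correction (2D MPJPE against the projected truth, medians
with bootstrap confidence intervals). At the default study conditions
— 200 scenes, occlusion rate 0.2, pixel noise 0.05 — the weighted
correction's median error is far below the raw decode's, while the
unweighted correction hovers near the raw level: with uniform weights
the grossly wrong occluded joints drag the alignment, and the
correction redistributes rather than removes their error. That gap
between the weighted and unweighted conditions, not the absolute
numbers, is the substantive claim; `scripts/acceptance.R` recomputes
all three medians from scratch.

# Numerical choices and degenerate inputs

- Enumeration is 1-based (`e = 1..n`) internally; file I/O is 0-based.
- Uncertainty floor `1e-3` grid units before any `1/c`.
- The scalar `c_i` used for weights is the arithmetic mean of `c_u`
  and `c_v`; whether a single pooled `c_i` or per-axis weights are
  intended is ambiguous in the source formulation, and per-axis
  weights would require an anisotropic alignment objective that the
  SVD solution does not cover.
- Degenerate rejections: all-equal 2D points, collinear alignment
  input, rank-deficient prior in the depth initialization, non-unit
  rotation axes, near-zero quaternions, non-positive bone lengths.
- Problem sizes in the shipped tests (500 decoder scenes, 1000 oracle
  alignment instances against 1e5 sampled rotations, 200 correction
  and benchmark scenes) were chosen so the full suite documents each
  property at meaningful scale while running in well under a minute.

# Known limitations

- Orthographic camera only; the depth sign is unrecoverable and
  reported up to a global flip.
- The correction trusts the 3D prior's *proportions*; a wrong prior
  confidently corrupts good 2D estimates.
- Uncertainties are per-axis standard deviations of a softmax vote;
  they are informative ordinally, but their absolute calibration
  depends on the heatmap's logit scale, as described above.
- The synthetic body is a kinematic stand-in: results on it bound the
  geometry, not real-image performance.
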