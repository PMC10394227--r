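# posevote

Markerless articulated pose estimation tooling for the stage *after* a
network has produced per-joint heatmaps: decoding those heatmaps into
subpixel 2D keypoints with honest uncertainties, and correcting the
keypoints against a 3D body-structure prior. It is aimed at people
building or evaluating human/animal pose pipelines who need the
geometry and loss layer as plain, testable R functions — no GPU, no
training code, no external datasets.

## What it implements

**Voting decoder ("k-block").** A heatmap for joint *i* is a `w x h`
response grid. The decoder accumulates the grid along each axis,
softmax-normalizes the two marginal vectors into vote distributions
over the position enumeration `e = (1, 2, ..., n)`, and reads off

- the coordinate as the vote expectation `x_i = sum_j z*_j e_j`, and
- the uncertainty `c_i` as the standard deviation of the vote
  distribution —

so the whole map votes, and diffuse (occluded, ill-lit) joints
announce themselves through large `c_i`. The matching training loss is
the Gaussian negative log-likelihood with a `1/(2c^2)` regularizer
(weight `omega_c = 0.2`).

**Body-parameter losses.** Smooth-L1 shape loss with its quadratic
region widened to `|delta| <= 1.5` (the typical range of the 10 open
shape coefficients); an L1 quaternion pose loss with unit-norm
regularizer (`omega_p = 1`), using scalar-last quaternions
`(x' sin(a/2), y' sin(a/2), z' sin(a/2), cos(a/2))`; squared-error 3D
keypoint loss; and the weighted total
`L = 0.2 L_shape + 0.25 L_pose + 0.15 L_SMPL + 0.3 L_KB + 0.4 L_DET`.

**Uncertainty-weighted 2D–3D correction.** The core geometry: the
weighted Kabsch/Procrustes problem
`min_R sum_i (1/2) w_i || R p_i + t - q_i ||^2` solved in closed form
by SVD of the weighted cross-covariance (with the reflection
correction forcing `det R = +1`), and an iterative scheme that lifts
the 2D keypoints orthographically with per-joint depths, aligns the
normalized 3D prior onto the lifted set with weights `w_i = 1/c_i`,
and re-estimates the depths — replacing each 2D keypoint by the
aligned prior's projection. Depths are initialized by a closed-form
scaled-orthographic fit, so on noise-free input the default 3
iterations reproduce the observations to machine precision.

**Synthetic kinematic body.** A 17-joint COCO-like kinematic tree with
shape-dependent bone lengths stands in for a statistical body model:
`(beta, theta) -> 3D joints -> orthographic 2D -> rendered heatmaps`
with controllable noise and per-joint occlusion attenuation. Every
fixture in the test suite is generated by this module from a seed.

**Metrics.** MPJPE, Procrustes-aligned PA-MPJPE (closed-form
similarity alignment), and a seeded Monte-Carlo benchmark comparing
raw decoding against unweighted and uncertainty-weighted correction.

## Worked example

```r
library(posevote)

sc  <- sample_scene(seed = 7, noise_sigma = 0.05, occlusion_rate = 0.2)
sc
#> <scene> 17 joints, 32 x 32 grid, noise 0.05, 2 occluded, seed 7

dec <- decode_heatmaps(sc$heatmaps)
head(as.data.frame(dec), 4)
#>   joint         u        v       c_u       c_v
#> 1     1 14.907214 16.13767 0.5446385 0.5741267
#> 2     2 12.130756 16.15633 0.6157592 0.5507890
#> 3     3  9.810817 16.36141 0.7027517 0.6771574
#> 4     4  7.911265 16.60602 0.7576311 0.6908416

# the two occluded joints expose themselves through their uncertainty
dec$c_u[sc$occluded]    #> 8.97 9.48   (unoccluded joints sit near 0.5-0.7)

corr <- iterative_correction(dec, sc$truth3d)
corr
#> <correction_result> 17 joints, 3 iterations, final (u,v) residual 0.8295

mpjpe(as.matrix(dec[, c("u", "v")]), sc$truth2d)   #> 1.342 grid units
mpjpe(corr$corrected2d, sc$truth2d)                #> 1.021 grid units
```

Decoded coordinates are in 1-based grid units (`u` along columns, `v`
along rows); uncertainties are in the same units. The correction pulls
the badly decoded occluded joints back toward the configuration the 3D
prior supports, cutting the 2D error; over 200 such scenes the
weighted correction roughly halves the median error while unweighted
correction barely helps (see the benchmark below).

A shell interface covers the same pipeline
(`simulate / decode / correct / evaluate / bench`); after installation:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "posevote", package = "posevote"))') \
  bench --n 200 --seed 1 --noise 0.05 --occlusion 0.2 --out bench.json
```

## Scope

The package deliberately contains no convolutional backbone, detector,
mesh model, or training loop, and no perspective camera: heatmaps and
3D priors come in from outside (or from the synthetic module), and
everything here is deterministic geometry, losses and evaluation. See
`vignettes/methods.Rmd` for the model, the numerical choices and the
known limitations.
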