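---
title: "Landmark-based affine registration of a parametric cochlear model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based affine registration of a parametric cochlear model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochreg)
```

## The problem

Cochlear implant planning relies on preoperative CT, but conventional
scanners resolve only about 0.3 mm isotropic — on a cochlea of roughly
9 × 7 × 4 mm that is coarse enough that individual anatomy (turn count,
quadrant proportions, height) is hard to read directly from the image.
`cochreg` addresses this by fitting a parametric model of the cochlear
spiral to a handful of ordered landmarks picked on the cochlea's lateral
wall, either on a binary segmentation or directly in the CT volume. After
registration the model carries the patient's geometry, and its parameters
can be read off the fitted transform.

The pipeline is: build a model centerline from four quadrant extents →
place ordered landmarks on it at regular angular spacing → estimate the
affine transform that maps model landmarks onto the picked landmarks by
minimising the sum of squared distances (SSD) → optionally prune the
worst-fitting landmarks and re-register.

## The cochlear model

The model centerline is a spiral centered at the origin, parameterised by
the unwound angle $\theta$ (degrees, $0$ at the basal start on the $+x$
axis, increasing counter-clockwise seen from the apex). Four quadrant
extents anchor the basal footprint: the planar radius equals $A_a$, $B_a$,
$A_b$, $B_b$ at $\theta = 0°, 90°, 180°, 270°$ of the first turn. The mean
cochlea has $A_a = 5.97$, $A_b = 3.26$, $B_a = 3.95$, $B_b = 2.85$ mm.

Between and beyond the anchors the implementation uses

$$r(\theta) = q(\theta \bmod 360°)\, d^{\,\theta/360°}, \qquad
  z(\theta) = h\,\frac{\theta}{360\,\tau},$$

where $q$ is a periodic cubic through the (decay-corrected) quadrant
anchors, $d = 0.6$ is the per-turn radial decay, $h$ is the apical height
(default 4 mm, a typical cochlear height) and $\tau$ the number of turns.
These are deliberate modelling choices: the published description of the
underlying anatomical model constrains the quadrant anchors, the inward
coiling and the apex height but not the radial decay law, so the decay
constant and the linear height profile were fixed once at anatomically
plausible values and the whole centerline generator sits behind a small
interface (`build_centerline()`, `point_at_angle()`) so a more detailed
spiral law can replace it without touching registration.

The number of turns is derived from the quadrant extents through their
shape only,

$$\tau = 2.875 + \log\frac{(A_a + A_b)/(B_a + B_b)}{(5.97+3.26)/(3.95+2.85)},$$

clamped to $(1.6, 3.4)$. The anchor value 2.875 makes the mean cochlea
produce exactly 12 landmarks under the 90° scheme (below), and the
logarithmic ratio term makes the count scale-invariant: an isotropically
larger cochlea has the same number of turns. An explicitly supplied turn
count always overrides the formula — `cochlear_params(..., turns = 2.4)` —
which is how a graphically estimated turn count enters.

```{r}
mean_cochlea()
```

## Landmark placement and counting

`place_landmarks()` puts one landmark every $\Delta \in \{45°, 90°, 180°\}$
along the spiral, labelled consecutively from 1; the label order carries
the correspondence between model and target and must never be permuted.
The terminal landmark marks the end of the last turn. When the leftover
angle past the last regular multiple exceeds $\Delta/2$ the terminal
landmark is appended; otherwise the last regular landmark is *moved* to the
end of the turn, so the apex is always marked and never duplicated. This
rule reproduces all the documented counts — 12 on the mean cochlea at 90°,
and 11 / 6 / 20 at 90° / 180° / 45° when the turn count is fixed at 2.4 —
which a naive "append the terminal whenever the angle is not an exact
multiple" rule does not (it would give 13 and 21 in two of those cases).
The `"minimal5"` scheme places landmarks at 0°, 90°, 180°, 270° and the
apex only.

```{r}
cl <- build_centerline(mean_cochlea())
nrow(place_landmarks(cl, 90))
nrow(place_landmarks(build_centerline(mean_cochlea(turns = 2.4)), 90))
```

## Quadrant estimation from picked chords

The quadrant extents of a patient cochlea are measured by picking the four
points where two perpendicular basal chords meet the lateral wall.
`estimate_quadrant_params()` reconstructs the spiral center $M$ and returns
the four distances. In a 2D slice the chords intersect and $M$ is the
intersection; points picked on a 3D voxel grid give slightly skew chords,
so $M$ is computed as the closed-form least-squares closest point to the
two lines, which reduces exactly to the intersection when the chords are
coplanar. Note that this is a planar-slice measurement by construction: if
the four points are taken from the 3D model spiral itself (whose height
climbs along the first turn) they should be projected into the basal plane
first, otherwise the out-of-plane spread biases the distances by the height
gained per quarter turn (about 0.05 mm for the default height profile).

```{r}
estimate_quadrant_params(c(5.71, 0, 0), c(-3.29, 0, 0),
                         c(0, 4.37, 0), c(0, -2.75, 0))$params
```

## The registration model

The model landmarks $\mathbf l_{M,i}$ are mapped by a composition of
shearing, anisotropic scaling, rotation + translation, and reflection:

$$f_T(\mathbf l) = (f_F \circ f_{R,t} \circ f_C \circ f_S)(\mathbf l),$$

and the objective is
$\mathcal F(\mathbf p^\ast) = \sum_i \lVert f_T(\mathbf l_{M,i}, \mathbf p^\ast) - \mathbf l_{C,i}\rVert_2^2$
over the 12-vector
$\mathbf p^\ast = (\alpha, \beta, \gamma, t_x, t_y, t_z, c_x, c_y, c_z, s_{xy}, s_{xz}, s_{yz})$.
Conventions fixed by this package: the rotation is
$R = R_z(\gamma) R_y(\beta) R_x(\alpha)$; the shear matrix is unit upper
triangular with $s_{xy}, s_{xz}, s_{yz}$ above the diagonal; scales must be
strictly positive. Together $R\,C\,S$ spans every orientation-preserving
invertible linear map (an RQ-type factorisation exists for any such
matrix), so reflection is the only part the continuous parameters cannot
reach. The three reflection sign flags therefore live outside
$\mathbf p^\ast$; `register(..., reflection_search = TRUE)` optimises all
8 sign assignments and keeps the best, which is how a left-ear model meets
a right-ear target. The default leaves reflection at identity.

### Optimisation

`register()` minimises the SSD with a quasi-Newton (BFGS) descent:
Armijo backtracking line search, damped inverse-Hessian update, numerical
central-difference gradient. The parameter vector starts at the identity
transform, and iterations stop when the SSD change between accepted
iterations falls below `tol` ($10^{-6}$ mm², the conventional optimiser
tolerance) or after `max_iterations` (default 100) major iterations. The
per-iteration SSD is recorded in `ssd_history` and is non-increasing by
construction.

One descent from the identity is not sufficient in general: the Euler
angles make the objective multimodal, and when the target pose is rotated
far from the model the descent can converge into the wrong rotational
basin (this is a property of the parametrisation, not of the optimiser —
the same happens with any local method). `register()` therefore also seeds
a second descent at the global optimum of the *unconstrained* affine
problem, which is available in closed form by linear least squares and is
refactored into $(\alpha, \ldots, s_{yz})$ via a Cholesky-based RQ
factorisation whenever its determinant sign is compatible with the
reflection flags. The run with the lower final SSD wins; ties prefer the
identity start. Because the closed-form optimum *is* the global optimum of
the SSD whenever the best map is orientation-preserving, this start makes
the quasi-Newton result agree with the closed-form fit to well below the
stopping tolerance, which is the package's primary correctness check.

### Error reporting

The per-landmark error is the Euclidean distance in mm between each
transformed model landmark and its target; the mean absolute error (MAE)
is their arithmetic mean, the headline quality figure. With four affinely
independent pairs the 12 linear degrees of freedom interpolate exactly
(SSD at machine zero), so at least five pairs are needed before the MAE
says anything about fit quality.

```{r}
ph <- make_phantom(phantom_spec(noise = "quantize", seed = 1))
fit <- register(ph$model_landmarks, ph$target_landmarks)
glance(fit)
```

## Worst-landmark pruning

`prune_landmarks()` automates the case-study refinement loop: register,
rank landmarks by error (descending, ties to the lower label), delete the
worst batch from *both* sides, renumber, re-register. The published
workflow used visual inspection to decide that the apex landmark — which
anchors the cochlear height — should be kept even when it carries the
largest error; the package replaces that judgement with the `protected`
label set: a protected landmark is skipped in the deletion ranking and the
next-worst deletable landmark goes instead. Batches truncate at
`min_landmarks` (at least 4). Each re-registration restarts from the
identity by default; `warm_start = TRUE` starts from the previous optimum
instead — the restart default was chosen because it makes every step's
result independent of the path that led to it. Percent reductions between
steps are computed from full-precision MAEs and displayed at two decimals.

## The synthetic phantom

`make_phantom()` provides ground truth where no patient data can: model
landmarks are posed by a random affine transform (rotations over the full
circle, translations within ±20 mm, scales in [0.8, 1.2], shears within
±0.2 — ranges chosen to stay within plausible anatomical deformation) and
then perturbed. The primary noise model is **voxel quantization**: every
coordinate is rounded to the nearest multiple of the 0.3 mm voxel pitch,
which is exactly the error a human picker cannot avoid on a conventional
CT grid (each coordinate moves at most 0.15 mm, each landmark at most
$0.15\sqrt3 \approx 0.26$ mm). A Gaussian mode exists for robustness
sweeps. Everything is deterministic given the seed.

What the phantom does *not* emulate: CT intensities and partial-volume
blur, the surrounding temporal bone, segmentation errors, and — most
importantly — the shape mismatch between a real cochlea and the model
family (a real cochlea is not an affine image of the model). Passing the
phantom tests therefore shows that the estimator is correct and that
quantization-level noise keeps the MAE below scanner resolution; it does
not show how well the affine family approximates real anatomy.

`rasterize_mask()` voxelizes a tube around the centerline into a binary
mask (default tube radius 0.5 mm, giving the expected ≈10 × 7.5 × 5 mm
footprint at the mean parameters), written as NIfTI with the spacing in
the header, emulating a segmentation at CT resolution.

## Numerical choices and problem sizes

* Optimiser tolerance $10^{-6}$ mm² absolute on the SSD change; gradient
  step $10^{-6}\max(1, |p_i|)$ central differences; line search halves the
  step until the Armijo condition with $c_1 = 10^{-4}$ holds.
* Scales are kept positive by an objective barrier at $10^{-8}$;
  reflections are discrete flags, never relaxed.
* Ties in error ranking break to the lower label so pruning is
  deterministic.
* Test and acceptance runs use 20-seed phantom ensembles, 12–20 landmarks
  per set and 90 centerline samples per turn — sizes at which every check
  runs in seconds while the ensembles still average over the pose and
  quantization distributions.

## Known limitations

* The radial decay law and height profile are plausible stand-ins
  constrained only at the quadrant anchors; patient-specific conclusions
  about arc length or inter-turn spacing should not be read off the
  default centerline.
* Affine registration cannot rebalance quadrant proportions between model
  and target (that would need elastic deformation, deliberately excluded);
  the quadrant-estimation step exists precisely to absorb that mismatch
  before registration.
* The turns formula is a calibrated one-parameter law, not an anatomical
  derivation; supply a measured turn count when one is available.
* With `reflection_search = FALSE` and a mirrored target the fit converges
  to the best orientation-preserving map, which is poor by design — enable
  the search when ear side is unknown.
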