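# cochreg

Landmark-based affine registration of a parametric cochlear model to
conventional CT.

## What it is for

Cochlear implant planning uses preoperative CT, but conventional scanners
resolve only ~0.3 mm isotropic — coarse for an organ of roughly
9 × 7 × 4 mm. Rather than measuring the cochlea in the image directly,
`cochreg` fits a parametric model of the cochlear spiral to a small set of
ordered landmarks picked on the lateral wall (of a binary segmentation or
of the raw CT), so the registered model carries the patient's geometry.
It is aimed at researchers working on cochlear anatomy estimation and
implant planning pipelines.

The model centerline is anchored by four quadrant extents
(A_a, A_b, B_a, B_b: distances from the spiral center to the lateral wall
along two perpendicular basal axes; mean cochlea 5.97 / 3.26 / 3.95 /
2.85 mm), a turn count derived from them (overridable), and an apical
height. Model landmarks **l**\_M are mapped onto picked landmarks
**l**\_C by the composition

    f_T(l) = (f_F ∘ f_{R,t} ∘ f_C ∘ f_S)(l)

(shear, anisotropic scale, rotation + translation, reflection), and the
12-vector p\* = (α, β, γ, t_x, t_y, t_z, c_x, c_y, c_z, s_xy, s_xz, s_yz)
is found by quasi-Newton minimisation of the SSD
Σᵢ ‖f_T(l\_{M,i}, p\*) − l\_{C,i}‖₂² with tolerance 1e-6 on the SSD change
(reflection handled as discrete sign flags, optionally searched
exhaustively). Results are reported as per-landmark Euclidean errors and
their mean (MAE, mm). An iterative refinement deletes the worst-fitting
landmarks (with protected labels, e.g. the apex) and re-registers.
A synthetic phantom generator — known affine pose plus 0.3 mm
voxel-quantization noise — provides ground truth for testing everything
without patient data.

## Worked example

```r
library(cochreg)

mean_cochlea()
#> <cochlear_params>
#>   quadrant extents (mm): A_a = 5.970, A_b = 3.260, B_a = 3.950, B_b = 2.850
#>   turns = 2.8750, height = 4.00 mm

cl <- build_centerline(mean_cochlea())
lm <- place_landmarks(cl, 90)     # one landmark every 90 degrees + apex
nrow(lm)
#> [1] 12

# phantom: known affine pose + 0.3 mm voxel quantization on the target side
ph  <- make_phantom(phantom_spec(noise = "quantize", seed = 1))
fit <- register(ph$model_landmarks, ph$target_landmarks)
fit
#> <cochlear_registration>
#>   12 landmark pairs, 1 iterations (converged)
#>   SSD = 0.14145 mm^2, MAE = 0.1026 mm per landmark

prune_landmarks(ph$model_landmarks, ph$target_landmarks,
                batch_sizes = c(1, 1))
#> <cochlear_case_report>
#>   step 1: 12 landmarks, MAE = 0.1026 mm (1 iterations)
#>   step 2: 11 landmarks (deleted 12), MAE = 0.0904 mm (1 iterations)
#>   step 3: 10 landmarks (deleted 10), MAE = 0.0816 mm (1 iterations)
#>   overall MAE reduction: 20.41%
```

The MAE of 0.1026 mm is the mean 3D distance between the transformed model
landmarks and the picked landmarks — here well below the 0.3 mm scanner
resolution, meaning the fit error is dominated by the voxel grid, not by
the transform. Each pruning step deletes the worst-fitting landmark from
both sides and re-registers; `tidy()`, `glance()` and `autoplot()` methods
expose the per-landmark errors, fit summaries and SSD descent.

A command-line wrapper with `model`, `fit`, `prune`, `phantom` and
`params-estimate` subcommands is installed at
`system.file("scripts", "cochreg.R", package = "cochreg")`.

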