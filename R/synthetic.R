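#' Phantom specification
#'
#' Describes a ground-truth phantom: a model cochlea, an affine pose sampled
#' from stated ranges, and a landmark noise model emulating how conventional
#' CT limits landmark picking. The default voxel pitch is 0.3 mm isotropic,
#' the resolution of conventional CT; quantization noise rounds every
#' coordinate to the nearest voxel multiple, the dominant picking error at
#' that resolution. Pose ranges keep the deformation anatomically plausible:
#' full-circle rotations, translations within ±20 mm, scales in [0.8, 1.2],
#' shears within ±0.2.
#'
#' @param params A [cochlear_params()] (default: the mean cochlea).
#' @param spacing Landmark placement scheme passed to [place_landmarks()].
#' @param voxel_mm Voxel pitch in mm (default 0.3).
#' @param noise One of `"none"`, `"quantize"`, `"gaussian"`.
#' @param sigma_mm Gaussian noise SD in mm (used when `noise = "gaussian"`).
#' @param translation_mm,scale_range,shear_range Pose sampling ranges.
#' @param seed Integer seed; recorded in every output.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(params = mean_cochlea(), spacing = 90,
                         voxel_mm = 0.3,
                         noise = c("quantize", "none", "gaussian"),
                         sigma_mm = 0.15,
                         translation_mm = 20,
                         scale_range = c(0.8, 1.2),
                         shear_range = c(-0.2, 0.2),
                         seed = 1L) {
  noise <- match.arg(noise)
  if (voxel_mm <= 0) stop("`voxel_mm` must be positive", call. = FALSE)
  if (any(scale_range <= 0)) {
    stop("`scale_range` must be strictly positive", call. = FALSE)
  }
  structure(
    list(params = params, spacing = spacing, voxel_mm = voxel_mm,
         noise = noise, sigma_mm = sigma_mm,
         translation_mm = translation_mm, scale_range = scale_range,
         shear_range = shear_range, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a ground-truth phantom
#'
#' Places landmarks on the canonical model cochlea, draws a random affine
#' pose from the spec's ranges (determinant positive: reflections are a
#' registration concern, not a pose concern), applies it, and perturbs the
#' posed landmarks with the chosen noise model. With `noise = "quantize"`
#' every coordinate is rounded to the nearest `voxel_mm` multiple, so each
#' coordinate moves at most `voxel_mm / 2`. Deterministic given the seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `true_pose` ([affine_params()]), `true_matrix` (4x4),
#'   `model_landmarks`, `target_landmarks` ([landmark_set()]s in
#'   correspondence), `centerline`, and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  cl <- build_centerline(spec$params)
  model_lm <- place_landmarks(cl, spec$spacing)
  withr::with_seed(spec$seed, {
    pose <- affine_params(
      alpha = stats::runif(1, -pi, pi),
      beta  = stats::runif(1, -pi, pi),
      gamma = stats::runif(1, -pi, pi),
      t_x = stats::runif(1, -spec$translation_mm, spec$translation_mm),
      t_y = stats::runif(1, -spec$translation_mm, spec$translation_mm),
      t_z = stats::runif(1, -spec$translation_mm, spec$translation_mm),
      c_x = stats::runif(1, spec$scale_range[1], spec$scale_range[2]),
      c_y = stats::runif(1, spec$scale_range[1], spec$scale_range[2]),
      c_z = stats::runif(1, spec$scale_range[1], spec$scale_range[2]),
      s_xy = stats::runif(1, spec$shear_range[1], spec$shear_range[2]),
      s_xz = stats::runif(1, spec$shear_range[1], spec$shear_range[2]),
      s_yz = stats::runif(1, spec$shear_range[1], spec$shear_range[2])
    )
    Tm <- compose_transform(pose)
    target <- apply_transform(Tm, model_lm)
    xyz <- lm_coords(target)
    xyz <- switch(spec$noise,
      none = xyz,
      quantize = round(xyz / spec$voxel_mm) * spec$voxel_mm,
      gaussian = xyz + stats::rnorm(length(xyz), sd = spec$sigma_mm)
    )
    target_lm <- landmark_set(xyz, labels = target$label,
                              source = "segmented",
                              angle_deg = model_lm$angle_deg)
  })
  list(true_pose = pose, true_matrix = Tm,
       model_landmarks = model_lm, target_landmarks = target_lm,
       centerline = cl, spec = spec)
}

#' Rasterize the model as a binary voxel mask
#'
#' Voxelizes a tube around the centerline on an isotropic grid, emulating a
#' binary cochlear segmentation at CT resolution. The tube radius may vary
#' with the unwound angle (the cochlear duct tapers toward the apex).
#'
#' @param centerline A centerline from [build_centerline()].
#' @param tube_radius Tube radius in mm: a constant or a function of the
#'   unwound angle in degrees (default: constant 0.5 mm).
#' @param voxel_mm Isotropic voxel pitch in mm (default 0.3).
#' @return An object of class `voxel_mask`: list with `array` (logical 3D),
#'   `spacing` (mm), `origin` (mm position of the center of voxel [1,1,1]).
#' @export
rasterize_mask <- function(centerline, tube_radius = 0.5, voxel_mm = 0.3) {
  stopifnot(inherits(centerline, "cochlear_centerline"))
  if (voxel_mm <= 0) stop("`voxel_mm` must be positive", call. = FALSE)
  if (nrow(centerline) == 0) stop("empty centerline", call. = FALSE)
  radius_fn <- if (is.function(tube_radius)) tube_radius
               else function(theta) rep(tube_radius, length(theta))
  r <- radius_fn(centerline$angle_deg)
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("tube radius must be positive", call. = FALSE)
  }
  pts <- as.matrix(centerline[, c("x_mm", "y_mm", "z_mm")])
  extent <- apply(pts, 2, range)
  if (max(r) > (max(extent[2, ] - extent[1, ]) / 2)) {
    warning("tube radius exceeds half the model extent; mask may be degenerate")
  }
  lo <- extent[1, ] - max(r) - voxel_mm
  hi <- extent[2, ] + max(r) + voxel_mm
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_mm)) + 1L)
  origin <- lo
  mask <- array(FALSE, dim = dims)
  # stamp a ball of radius r[i] around every centerline sample
  for (i in seq_len(nrow(pts))) {
    ctr_idx <- (pts[i, ] - origin) / voxel_mm + 1
    w <- ceiling(r[i] / voxel_mm)
    ix <- max(1L, floor(ctr_idx[1] - w)):min(dims[1], ceiling(ctr_idx[1] + w))
    iy <- max(1L, floor(ctr_idx[2] - w)):min(dims[2], ceiling(ctr_idx[2] + w))
    iz <- max(1L, floor(ctr_idx[3] - w)):min(dims[3], ceiling(ctr_idx[3] + w))
    gx <- origin[1] + (ix - 1) * voxel_mm
    gy <- origin[2] + (iy - 1) * voxel_mm
    gz <- origin[3] + (iz - 1) * voxel_mm
    d2 <- outer(outer((gx - pts[i, 1])^2, (gy - pts[i, 2])^2, `+`),
                (gz - pts[i, 3])^2, `+`)
    mask[ix, iy, iz] <- mask[ix, iy, iz] | (d2 <= r[i]^2)
  }
  if (!any(mask)) stop("rasterization produced an empty mask", call. = FALSE)
  structure(list(array = mask, spacing = voxel_mm, origin = origin),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("<voxel_mask>\n")
  cat(sprintf("  dims %s, spacing %.3f mm, %d foreground voxels\n",
              paste(dim(x$array), collapse = " x "), x$spacing,
              sum(x$array)))
  invisible(x)
}

#' Write a voxel mask as NIfTI
#'
#' Isotropic spacing goes in the header pixdim; the origin (mm position of
#' the first voxel center) in the qform offset.
#'
#' @param mask A `voxel_mask`.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  img <- array(as.integer(mask$array), dim = dim(mask$array))
  xform <- diag(c(rep(mask$spacing, 3), 1))
  xform[1:3, 4] <- mask$origin
  nii <- RNifti::asNifti(img)
  nii <- RNifti::`sform<-`(nii, structure(xform, code = 2L))
  RNifti::pixdim(nii) <- rep(mask$spacing, 3)
  RNifti::writeNifti(nii, path)
  invisible(path)
}
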