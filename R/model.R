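#' Cochlear model parameters
#'
#' Bundles the four quadrant extents of the basal cochlear footprint with the
#' number of spiral turns and the apical height. The quadrant extents are the
#' distances from the spiral center (the coordinate origin) to the lateral
#' wall along two perpendicular in-plane axes: `A_a` on the positive first
#' axis, `A_b` on its negative side, `B_a` and `B_b` on the perpendicular
#' axis. All lengths are millimetres.
#'
#' `turns` may be left `NULL`, in which case it is derived from the four
#' extents via [compute_turns()]; an explicit value always wins and detaches
#' the turn count from the quadrant parameters.
#'
#' @param A_a,A_b,B_a,B_b Quadrant extents in mm, all strictly positive.
#'   `A_a >= A_b` is not required: measured cochleae such as
#'   (5.71, 3.29, 4.37, 2.75) have `B_a > A_b`.
#' @param turns Number of full revolutions of the spiral (non-integer allowed,
#'   must exceed 1), or `NULL` to compute it from the extents.
#' @param height Apical extent of the spiral in mm (default 4, the typical
#'   height of a human cochlea).
#' @return An object of class `cochlear_params`: a named list with fields
#'   `A_a`, `A_b`, `B_a`, `B_b`, `turns`, `height`.
#' @examples
#' cochlear_params(5.97, 3.26, 3.95, 2.85)           # mean cochlea
#' cochlear_params(5.71, 3.29, 4.37, 2.75, turns = 2.4)
#' @export
cochlear_params <- function(A_a, A_b, B_a, B_b, turns = NULL, height = 4) {
  ext <- c(A_a = A_a, A_b = A_b, B_a = B_a, B_b = B_b)
  if (!all(is.finite(ext)) || any(ext <= 0)) {
    stop("all four quadrant extents must be finite and strictly positive",
         call. = FALSE)
  }
  if (!is.finite(height) || height <= 0) {
    stop("`height` must be strictly positive", call. = FALSE)
  }
  if (is.null(turns)) {
    turns <- compute_turns(A_a, A_b, B_a, B_b)
  } else if (!is.finite(turns) || turns <= 1) {
    stop("`turns` must exceed 1", call. = FALSE)
  }
  structure(
    list(A_a = A_a, A_b = A_b, B_a = B_a, B_b = B_b,
         turns = turns, height = height),
    class = "cochlear_params"
  )
}

#' Mean cochlea parameters
#'
#' The average human cochlea: quadrant extents A_a = 5.97, A_b = 3.26,
#' B_a = 3.95, B_b = 2.85 mm, turns derived from the extents.
#'
#' @param ... Passed on to [cochlear_params()] (e.g. `turns`, `height`).
#' @return A `cochlear_params` object.
#' @export
mean_cochlea <- function(...) {
  cochlear_params(5.97, 3.26, 3.95, 2.85, ...)
}

#' @export
print.cochlear_params <- function(x, ...) {
  cat("<cochlear_params>\n")
  cat(sprintf("  quadrant extents (mm): A_a = %.3f, A_b = %.3f, B_a = %.3f, B_b = %.3f\n",
              x$A_a, x$A_b, x$B_a, x$B_b))
  cat(sprintf("  turns = %.4f, height = %.2f mm\n", x$turns, x$height))
  invisible(x)
}

# Calibration of the turns law: the mean cochlea maps to 2.875 turns, the
# midpoint of the interval for which the 90-degree placement scheme yields
# exactly 12 landmarks.
.turns_anchor <- 2.875
.turns_ref_log_ratio <- log((5.97 + 3.26) / (3.95 + 2.85))

#' Number of cochlear turns from the quadrant extents
#'
#' Derives the number of spiral revolutions from the four quadrant extents.
#' The dependence is on the shape only — the ratio of the summed extents along
#' the two axes — so uniformly rescaling a cochlea leaves its turn count
#' unchanged: `turns = 2.875 + log(((A_a + A_b) / (B_a + B_b)) / r0)` with
#' `r0` the mean-cochlea ratio, clamped to the anatomically plausible range
#' (1.6, 3.4).
#'
#' @inheritParams cochlear_params
#' @return Number of turns (dimensionless, non-integer).
#' @examples
#' compute_turns(5.97, 3.26, 3.95, 2.85)  # mean cochlea -> 2.875
#' @export
compute_turns <- function(A_a, A_b, B_a, B_b) {
  ext <- c(A_a, A_b, B_a, B_b)
  if (!all(is.finite(ext)) || any(ext <= 0)) {
    stop("all four quadrant extents must be finite and strictly positive",
         call. = FALSE)
  }
  t <- .turns_anchor + log((A_a + A_b) / (B_a + B_b)) - .turns_ref_log_ratio
  min(max(t, 1.6), 3.4)
}

# Per-turn radial decay: planar radius shrinks by this factor every 360 deg.
.radial_decay <- 0.6

# Periodic interpolator of the four quadrant anchors, corrected for the
# per-turn decay so the first-turn radii hit the extents exactly.
.quadrant_interpolator <- function(params) {
  phase <- c(0, 90, 180, 270)
  anchors <- c(params$A_a, params$B_a, params$A_b, params$B_b) /
    .radial_decay^(phase / 360)
  stats::splinefun(c(phase, 360), c(anchors, anchors[1]), method = "periodic")
}

.planar_radius <- function(theta, params) {
  q <- .quadrant_interpolator(params)
  q(theta %% 360) * .radial_decay^(theta / 360)
}

#' Build the cochlear lateral-wall centerline
#'
#' Samples the spiral centerline of the model cochlea. The spiral is centered
#' at the origin, starts on the positive first axis at planar radius `A_a`
#' and height 0, and winds counter-clockwise (seen from the apex) while the
#' planar radius decays geometrically per turn and the height rises linearly
#' to `height` at the final unwound angle `360 * turns`. On the first turn
#' the planar radii at 0, 90, 180 and 270 degrees equal `A_a`, `B_a`, `A_b`
#' and `B_b` exactly; between the anchors the radius follows a periodic cubic.
#'
#' @param params A [cochlear_params()] object.
#' @param samples_per_turn Number of samples per full revolution (>= 8;
#'   default 90, i.e. one sample every 4 degrees).
#' @return A tibble of class `cochlear_centerline` with columns `angle_deg`
#'   (strictly increasing, 0 to `360 * turns`), `x_mm`, `y_mm`, `z_mm`. The
#'   generating parameters are attached as attribute `params`.
#' @examples
#' cl <- build_centerline(mean_cochlea())
#' cl[1, ]  # starts at (A_a, 0, 0)
#' @export
build_centerline <- function(params, samples_per_turn = 90) {
  stopifnot(inherits(params, "cochlear_params"))
  if (samples_per_turn < 8) {
    stop("`samples_per_turn` must be at least 8", call. = FALSE)
  }
  theta_total <- 360 * params$turns
  n <- max(2L, ceiling(samples_per_turn * params$turns)) + 1L
  theta <- seq(0, theta_total, length.out = n)
  # Anchor angles must be sampled exactly so the quadrant radii are exact.
  anchors <- seq(0, theta_total, by = 90)
  theta <- sort(unique(c(theta, anchors, theta_total)))
  r <- .planar_radius(theta, params)
  cl <- tibble::tibble(
    angle_deg = theta,
    x_mm = r * cos(theta * pi / 180),
    y_mm = r * sin(theta * pi / 180),
    z_mm = params$height * theta / theta_total
  )
  attr(cl, "params") <- params
  class(cl) <- c("cochlear_centerline", class(cl))
  cl
}

#' Evaluate the centerline at an unwound angle
#'
#' Linear interpolation between the bracketing centerline samples; exact at
#' sampled angles.
#'
#' @param centerline A centerline from [build_centerline()].
#' @param theta Unwound angle in degrees, within `[0, 360 * turns]`.
#' @return A tibble with one row per angle and columns `angle_deg`, `x_mm`,
#'   `y_mm`, `z_mm`.
#' @export
point_at_angle <- function(centerline, theta) {
  stopifnot(inherits(centerline, "cochlear_centerline"))
  rng <- range(centerline$angle_deg)
  if (any(theta < rng[1] - 1e-9) || any(theta > rng[2] + 1e-9)) {
    stop(sprintf("angle outside the centerline range [%g, %g] degrees",
                 rng[1], rng[2]), call. = FALSE)
  }
  theta <- pmin(pmax(theta, rng[1]), rng[2])
  tibble::tibble(
    angle_deg = theta,
    x_mm = stats::approx(centerline$angle_deg, centerline$x_mm, theta)$y,
    y_mm = stats::approx(centerline$angle_deg, centerline$y_mm, theta)$y,
    z_mm = stats::approx(centerline$angle_deg, centerline$z_mm, theta)$y
  )
}

#' Write a centerline to CSV or JSON
#'
#' CSV has columns `angle_deg,x_mm,y_mm,z_mm`; JSON additionally records the
#' generating model parameters.
#'
#' @param centerline A centerline from [build_centerline()].
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_centerline <- function(centerline, path) {
  stopifnot(inherits(centerline, "cochlear_centerline"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    p <- attr(centerline, "params")
    jsonlite::write_json(
      list(
        params = list(A_a = p$A_a, A_b = p$A_b, B_a = p$B_a, B_b = p$B_b,
                      turns = p$turns, height = p$height),
        units = "mm",
        samples = as.data.frame(centerline)
      ),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    readr::write_csv(as.data.frame(centerline), path)
  }
  invisible(path)
}
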