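#' Affine transform parameters
#'
#' The 12-vector optimised during registration — three Euler rotation angles
#' (radians), a translation (mm), three anisotropic scale factors and three
#' shear coefficients — plus three discrete reflection sign flags that are
#' handled outside the continuous parameter vector (a continuous optimiser
#' cannot cross the determinant sign).
#'
#' @param alpha,beta,gamma Rotation angles about x, y, z in radians.
#' @param t_x,t_y,t_z Translation components in mm.
#' @param c_x,c_y,c_z Scale factors, strictly positive.
#' @param s_xy,s_xz,s_yz Shear coefficients (entries of a unit
#'   upper-triangular matrix).
#' @param reflection Length-3 vector of signs in \{-1, +1\}.
#' @return An object of class `affine_params`.
#' @export
affine_params <- function(alpha = 0, beta = 0, gamma = 0,
                          t_x = 0, t_y = 0, t_z = 0,
                          c_x = 1, c_y = 1, c_z = 1,
                          s_xy = 0, s_xz = 0, s_yz = 0,
                          reflection = c(1, 1, 1)) {
  if (any(c(c_x, c_y, c_z) <= 0)) {
    stop("scale factors must be strictly positive", call. = FALSE)
  }
  if (length(reflection) != 3 || !all(reflection %in% c(-1, 1))) {
    stop("`reflection` must be three signs in {-1, +1}", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         t_x = t_x, t_y = t_y, t_z = t_z,
         c_x = c_x, c_y = c_y, c_z = c_z,
         s_xy = s_xy, s_xz = s_xz, s_yz = s_yz,
         reflection = as.numeric(reflection)),
    class = "affine_params"
  )
}

p_star <- function(params) {
  with(params, c(alpha, beta, gamma, t_x, t_y, t_z,
                 c_x, c_y, c_z, s_xy, s_xz, s_yz))
}

params_from_p <- function(p, reflection = c(1, 1, 1)) {
  affine_params(p[1], p[2], p[3], p[4], p[5], p[6],
                p[7], p[8], p[9], p[10], p[11], p[12],
                reflection = reflection)
}

#' @export
print.affine_params <- function(x, ...) {
  cat("<affine_params>\n")
  cat(sprintf("  rotation (rad): alpha = %.4f, beta = %.4f, gamma = %.4f\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  translation (mm): (%.4f, %.4f, %.4f)\n", x$t_x, x$t_y, x$t_z))
  cat(sprintf("  scale: (%.4f, %.4f, %.4f)\n", x$c_x, x$c_y, x$c_z))
  cat(sprintf("  shear: s_xy = %.4f, s_xz = %.4f, s_yz = %.4f\n",
              x$s_xy, x$s_xz, x$s_yz))
  cat(sprintf("  reflection: (%+d, %+d, %+d)\n",
              as.integer(x$reflection[1]), as.integer(x$reflection[2]),
              as.integer(x$reflection[3])))
  invisible(x)
}

#' Compose the homogeneous transform matrix
#'
#' Builds the 4x4 homogeneous matrix of the registration transform as the
#' product `F %*% (R | t) %*% C %*% S`: a point is first sheared (unit
#' upper-triangular `S`), then scaled (`C = diag(c_x, c_y, c_z)`), then
#' rotated and translated, then reflected (`F = diag(reflection)`). The
#' rotation uses the convention `R = Rz(gamma) %*% Ry(beta) %*% Rx(alpha)`.
#'
#' @param params An [affine_params()] object.
#' @return A 4x4 numeric matrix with last row (0, 0, 0, 1).
#' @export
compose_transform <- function(params) {
  stopifnot(inherits(params, "affine_params"))
  hom <- function(L, t = c(0, 0, 0)) {
    m <- diag(4)
    m[1:3, 1:3] <- L
    m[1:3, 4] <- t
    m
  }
  S <- matrix(c(1, params$s_xy, params$s_xz,
                0, 1,          params$s_yz,
                0, 0,          1), 3, 3, byrow = TRUE)
  C <- diag(c(params$c_x, params$c_y, params$c_z))
  ca <- cos(params$alpha); sa <- sin(params$alpha)
  cb <- cos(params$beta);  sb <- sin(params$beta)
  cg <- cos(params$gamma); sg <- sin(params$gamma)
  Rx <- matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  R <- Rz %*% Ry %*% Rx
  Fm <- diag(params$reflection)
  hom(Fm) %*% hom(R, c(params$t_x, params$t_y, params$t_z)) %*%
    hom(C) %*% hom(S)
}

#' Apply a homogeneous transform to points
#'
#' Applies a 4x4 homogeneous matrix to every point of a landmark set,
#' centerline, or plain coordinate table, leaving labels and ordering
#' untouched.
#'
#' @param matrix A 4x4 homogeneous matrix (last row 0, 0, 0, 1).
#' @param points A `landmark_set`, `cochlear_centerline`, or data frame with
#'   columns `x_mm`, `y_mm`, `z_mm`.
#' @return The same type of object with transformed coordinates.
#' @export
apply_transform <- function(matrix, points) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(4, 4)))
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-12) {
    stop("last row of a homogeneous transform must be (0, 0, 0, 1)",
         call. = FALSE)
  }
  xyz <- as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
  out <- t(matrix[1:3, 1:3] %*% t(xyz) + matrix[1:3, 4])
  points$x_mm <- out[, 1]
  points$y_mm <- out[, 2]
  points$z_mm <- out[, 3]
  points
}

#' Sum of squared landmark distances
#'
#' The registration objective: the sum over corresponding landmark pairs of
#' the squared Euclidean distance between the transformed model landmark and
#' the target landmark, in mm^2.
#'
#' @param model,target Corresponding [landmark_set()]s of equal length.
#' @param params An [affine_params()] object (default identity).
#' @return Non-negative scalar, mm^2; zero iff the transformed model
#'   coincides with the target.
#' @export
ssd <- function(model, target, params = affine_params()) {
  if (nrow(model) != nrow(target)) {
    stop("model and target landmark sets must have equal length", call. = FALSE)
  }
  Tm <- compose_transform(params)
  moved <- lm_coords(apply_transform(Tm, model))
  sum((moved - lm_coords(target))^2)
}

#' Per-landmark registration errors and their mean
#'
#' `landmark_errors()` returns the Euclidean distance in mm between each
#' transformed model landmark and its target; `mae()` is the arithmetic mean
#' of a vector of such distances (the mean absolute error per landmark).
#'
#' @param model,target Corresponding [landmark_set()]s.
#' @param matrix 4x4 homogeneous transform applied to the model side.
#' @param errors Numeric vector of per-landmark distances, mm.
#' @return `landmark_errors()`: a tibble with columns `label` and `error_mm`;
#'   `mae()`: a scalar in mm.
#' @export
landmark_errors <- function(model, target, matrix = diag(4)) {
  moved <- lm_coords(apply_transform(matrix, model))
  d <- sqrt(rowSums((moved - lm_coords(target))^2))
  tibble::tibble(label = model$label, error_mm = d)
}

#' @rdname landmark_errors
#' @export
mae <- function(errors) {
  if (length(errors) == 0) stop("`errors` must be non-empty", call. = FALSE)
  mean(errors)
}

#' Closed-form full-affine least-squares fit
#'
#' Solves for the unconstrained 3x4 affine map minimising the sum of squared
#' landmark distances by ordinary linear least squares (12 coefficients,
#' 3n equations). Because the composed transform spans all invertible linear
#' maps plus translation, this is the global optimum of the registration
#' objective and serves as a reference for the quasi-Newton fit.
#'
#' @param model,target Corresponding [landmark_set()]s, n >= 4, model points
#'   affinely independent.
#' @return A list with `matrix` (4x4 homogeneous) and `ssd` (mm^2).
#' @export
affine_least_squares <- function(model, target) {
  X <- cbind(lm_coords(model), 1)
  Y <- lm_coords(target)
  if (nrow(X) < 4) stop("at least 4 landmark pairs are required", call. = FALSE)
  if (qr(scale(X[, 1:3], scale = FALSE))$rank < 3) {
    stop("model landmarks are affinely degenerate", call. = FALSE)
  }
  B <- qr.solve(X, Y)                     # 4x3 coefficients
  Tm <- diag(4)
  Tm[1:3, 1:4] <- t(B)
  list(matrix = Tm, ssd = sum((X %*% B - Y)^2))
}
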