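#' Construct a landmark set
#'
#' A landmark set is an ordered table of labelled 3D points in millimetres.
#' The ordering carries the correspondence between model and target sides:
#' the i-th model landmark is matched with the i-th target landmark, so the
#' order must be preserved through every operation.
#'
#' @param points A data frame or matrix with columns/coordinates x, y, z (mm).
#' @param labels Integer labels; default consecutive from 1.
#' @param source One of `"model"`, `"segmented"`, `"ct"`.
#' @param angle_deg Optional unwound placement angle per landmark (degrees).
#' @return A tibble of class `landmark_set` with columns `label`, `x_mm`,
#'   `y_mm`, `z_mm` (and `angle_deg` if supplied), attribute `source`.
#' @export
landmark_set <- function(points, labels = NULL, source = "model",
                         angle_deg = NULL) {
  source <- match.arg(source, c("model", "segmented", "ct"))
  pts <- as.matrix(as.data.frame(points))
  if (ncol(pts) != 3) stop("`points` must have three coordinates", call. = FALSE)
  n <- nrow(pts)
  if (n == 0) stop("a landmark set cannot be empty", call. = FALSE)
  if (is.null(labels)) labels <- seq_len(n)
  labels <- as.integer(labels)
  if (length(labels) != n || anyDuplicated(labels)) {
    stop("`labels` must be unique and one per point", call. = FALSE)
  }
  if (anyDuplicated(pts) > 0) {
    stop("duplicate landmark coordinates are not allowed", call. = FALSE)
  }
  lm <- tibble::tibble(label = labels,
                       x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3])
  if (!is.null(angle_deg)) lm$angle_deg <- angle_deg
  attr(lm, "source") <- source
  class(lm) <- c("landmark_set", class(lm))
  lm
}

lm_coords <- function(lm) {
  unname(as.matrix(lm[, c("x_mm", "y_mm", "z_mm")]))
}

#' Angular landmark-placement schemes
#'
#' Returns the unwound angles at which landmarks are placed on a spiral of
#' total angle `theta_total`.
#'
#' Regular schemes put one landmark every `spacing` degrees starting at 0.
#' The terminal landmark marks the end of the last turn (the apex): when the
#' remainder past the last regular multiple exceeds half the spacing, the
#' terminal landmark is appended; otherwise the last regular landmark is
#' moved to the end of the turn, so it *is* the terminal landmark and the gap
#' before it stays below 1.5 spacings. This reproduces the printed counts:
#' 12 landmarks on the mean cochlea at 90 degrees, and 11/6/20 on a 2.4-turn
#' cochlea at 90/180/45 degrees. The `"minimal5"` scheme places landmarks at
#' 0, 90, 180, 270 degrees of the basal turn plus the apex.
#'
#' @param theta_total Total unwound angle, degrees (`360 * turns`).
#' @param spacing Angular spacing in degrees (one of 45, 90, 180), or the
#'   string `"minimal5"`.
#' @param include_terminal Place the terminal (apex) landmark (default TRUE).
#' @return Numeric vector of placement angles, strictly increasing.
#' @export
placement_angles <- function(theta_total, spacing = 90,
                             include_terminal = TRUE) {
  if (!is.finite(theta_total) || theta_total <= 0) {
    stop("`theta_total` must be positive", call. = FALSE)
  }
  if (identical(spacing, "minimal5")) {
    return(c(0, 90, 180, 270, theta_total))
  }
  spacing <- as.numeric(spacing)
  if (!spacing %in% c(45, 90, 180)) {
    stop("`spacing` must be 45, 90 or 180 degrees, or \"minimal5\"",
         call. = FALSE)
  }
  angles <- seq(0, theta_total, by = spacing)
  if (!include_terminal) return(angles)
  remainder <- theta_total - angles[length(angles)]
  if (remainder > spacing / 2) {
    angles <- c(angles, theta_total)
  } else {
    angles[length(angles)] <- theta_total
  }
  angles
}

#' Place landmarks on a centerline
#'
#' Places ordered landmarks on the model lateral wall at the angles of a
#' placement scheme (see [placement_angles()]); labels run consecutively
#' from 1 in order of increasing angle.
#'
#' @param centerline A centerline from [build_centerline()].
#' @inheritParams placement_angles
#' @return A [landmark_set()] with `source = "model"` and an `angle_deg`
#'   column recording the placement angles.
#' @examples
#' cl <- build_centerline(mean_cochlea())
#' nrow(place_landmarks(cl, 90))  # 12
#' @export
place_landmarks <- function(centerline, spacing = 90,
                            include_terminal = TRUE) {
  stopifnot(inherits(centerline, "cochlear_centerline"))
  theta_total <- max(centerline$angle_deg)
  angles <- placement_angles(theta_total, spacing, include_terminal)
  pts <- point_at_angle(centerline, angles)
  landmark_set(pts[, c("x_mm", "y_mm", "z_mm")], source = "model",
               angle_deg = angles)
}

#' Estimate quadrant parameters from two basal chords
#'
#' Given the four lateral-wall points where the two perpendicular basal-turn
#' chords meet the wall — `P1`/`P2` on the long axis, `Q1`/`Q2` on the short
#' axis — reconstructs the spiral center `M` and returns the quadrant extents
#' as the distances `A_a = |P1 - M|`, `A_b = |M - P2|`, `B_a = |Q1 - M|`,
#' `B_b = |M - Q2|`.
#'
#' In a planar slice the chords intersect and `M` is their intersection. In
#' 3D, points picked on a voxel grid give slightly skew chords, so `M` is the
#' least-squares closest point to the two lines (closed form); this reduces
#' exactly to the intersection in the coplanar case.
#'
#' @param P1,P2,Q1,Q2 Numeric length-3 points in mm.
#' @return A list with elements `params` (a `cochlear_params` object, turns
#'   derived from the extents) and `center` (the estimated `M`, mm).
#' @examples
#' est <- estimate_quadrant_params(c(5.71, 0, 0), c(-3.29, 0, 0),
#'                                 c(0, 4.37, 0), c(0, -2.75, 0))
#' est$params
#' @export
estimate_quadrant_params <- function(P1, P2, Q1, Q2) {
  pts <- lapply(list(P1, P2, Q1, Q2), as.numeric)
  if (any(vapply(pts, length, 1L) != 3)) {
    stop("all chord points must be 3D", call. = FALSE)
  }
  d1 <- pts[[2]] - pts[[1]]
  d2 <- pts[[4]] - pts[[3]]
  n1 <- sqrt(sum(d1^2)); n2 <- sqrt(sum(d2^2))
  if (n1 < 1e-12 || n2 < 1e-12) {
    stop("degenerate chord: endpoints coincide", call. = FALSE)
  }
  d1 <- d1 / n1; d2 <- d2 / n2
  if (abs(abs(sum(d1 * d2)) - 1) < 1e-10) {
    stop("chords are parallel: the spiral center is not determined",
         call. = FALSE)
  }
  # M minimises the summed squared distance to the two lines:
  # sum_i |(I - d_i d_i^T)(M - a_i)|^2, a linear system in M.
  proj <- function(d) diag(3) - tcrossprod(d)
  A <- proj(d1) + proj(d2)
  b <- proj(d1) %*% pts[[1]] + proj(d2) %*% pts[[3]]
  M <- drop(solve(A, b))
  dist <- function(p) sqrt(sum((p - M)^2))
  list(
    params = cochlear_params(A_a = dist(pts[[1]]), A_b = dist(pts[[2]]),
                             B_a = dist(pts[[3]]), B_b = dist(pts[[4]])),
    center = M
  )
}

#' Delete corresponding landmarks from both sides
#'
#' Removes the landmarks with the given labels from *both* the model and the
#' target set, preserving correspondence, and renumbers the remaining labels
#' consecutively from 1.
#'
#' @param model,target Corresponding [landmark_set()]s of equal length.
#' @param labels Integer labels to delete (may be empty).
#' @return A list with elements `model` and `target`, the reduced sets.
#' @export
delete_landmarks <- function(model, target, labels) {
  stopifnot(inherits(model, "landmark_set"), inherits(target, "landmark_set"))
  if (nrow(model) != nrow(target)) {
    stop("model and target landmark sets must have equal length", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) == 0) return(list(model = model, target = target))
  if (!all(labels %in% model$label) || !all(labels %in% target$label)) {
    stop("labels to delete must exist in both landmark sets", call. = FALSE)
  }
  drop_relabel <- function(lm) {
    out <- lm[!lm$label %in% labels, , drop = FALSE]
    out$label <- seq_len(nrow(out))
    out
  }
  list(model = drop_relabel(model), target = drop_relabel(target))
}

#' Read and write landmark files
#'
#' CSV files have a header `label,x_mm,y_mm,z_mm` with 1-based consecutive
#' labels; JSON files carry the same table plus a `source` field and a
#' `units` field (always `"mm"`). Readers validate the ordering.
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @param lm A [landmark_set()] (for writing).
#' @return `read_landmarks()` returns a `landmark_set`;
#'   `write_landmarks()` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(obj$units) && !identical(obj$units, "mm")) {
      stop("landmark file units must be mm", call. = FALSE)
    }
    df <- as.data.frame(obj$points)
    src <- if (is.null(obj$source)) "model" else obj$source
  } else {
    df <- as.data.frame(readr::read_csv(path, show_col_types = FALSE))
    src <- "model"
  }
  req <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(req %in% names(df))) {
    stop("landmark file must have columns label, x_mm, y_mm, z_mm",
         call. = FALSE)
  }
  if (!identical(as.integer(df$label), seq_len(nrow(df)))) {
    stop("landmark labels must be consecutive from 1 in file order",
         call. = FALSE)
  }
  landmark_set(df[, c("x_mm", "y_mm", "z_mm")], labels = df$label,
               source = src,
               angle_deg = if ("angle_deg" %in% names(df)) df$angle_deg)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  df <- as.data.frame(lm)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(source = attr(lm, "source"), units = "mm", points = df),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}
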