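test_that("placement schemes reproduce the printed landmark counts", {
  counts <- list(
    list(turns = 2.4, spacing = 90, n = 11),
    list(turns = 2.4, spacing = 180, n = 6),
    list(turns = 2.4, spacing = 45, n = 20),
    list(turns = 3.0, spacing = 90, n = 13),   # terminal coincides, no duplicate
    list(turns = 2.4, spacing = "minimal5", n = 5)
  )
  for (cs in counts) {
    cl <- build_centerline(mean_cochlea(turns = cs$turns))
    lm <- place_landmarks(cl, cs$spacing)
    expect_identical(nrow(lm), as.integer(cs$n))
    expect_identical(lm$label, seq_len(nrow(lm)))
    expect_true(all(diff(lm$angle_deg) > 0))
  }
  # the mean cochlea with computed turns carries 12 landmarks at 90 degrees
  expect_identical(nrow(place_landmarks(build_centerline(mean_cochlea()), 90)),
                   12L)
})

test_that("landmark count follows the half-spacing terminal rule", {
  for (spacing in c(45, 90, 180)) {
    for (turns in c(2.0, 2.4, 2.875, 3.0)) {
      theta <- 360 * turns
      angles <- placement_angles(theta, spacing)
      rem <- theta %% spacing
      expected <- floor(theta / spacing) + 1 + (rem > spacing / 2)
      expect_length(angles, expected)
      # terminal landmark always marks the end of the last turn
      expect_equal(angles[length(angles)], theta)
      expect_false(anyDuplicated(angles) > 0)
    }
  }
})

test_that("quadrant estimation reproduces the measured chord construction", {
  est <- estimate_quadrant_params(c(5.71, 0, 0), c(-3.29, 0, 0),
                                  c(0, 4.37, 0), c(0, -2.75, 0))
  expect_equal(est$params$A_a, 5.71)
  expect_equal(est$params$A_b, 3.29)
  expect_equal(est$params$B_a, 4.37)
  expect_equal(est$params$B_b, 2.75)
  expect_equal(est$center, c(0, 0, 0))
  # symmetric cross
  sym <- estimate_quadrant_params(c(1, 0, 0), c(-1, 0, 0),
                                  c(0, 1, 0), c(0, -1, 0))
  expect_equal(unlist(sym$params[c("A_a", "A_b", "B_a", "B_b")]),
               c(A_a = 1, A_b = 1, B_a = 1, B_b = 1))
  expect_error(estimate_quadrant_params(c(0, 0, 0), c(1, 0, 0),
                                        c(2, 0, 0), c(3, 0, 0)),
               "parallel")
  expect_error(estimate_quadrant_params(c(1, 1, 1), c(1, 1, 1),
                                        c(0, 1, 0), c(0, -1, 0)),
               "degenerate")
})

test_that("chord center matches a brute-force search for skew 3D chords", {
  # slightly out-of-plane chords, as picked on a voxel grid
  P1 <- c(5.8, 0.1, 0.15); P2 <- c(-3.2, -0.05, -0.1)
  Q1 <- c(0.05, 4.3, -0.12); Q2 <- c(-0.1, -2.8, 0.08)
  est <- estimate_quadrant_params(P1, P2, Q1, Q2)

  # independent oracle: refined grid search for the point minimising the
  # summed squared distance to the two chord lines
  line_dist2 <- function(M, a, b) {
    d <- (b - a) / sqrt(sum((b - a)^2))
    v <- M - a
    sum(v^2) - sum(v * d)^2
  }
  obj <- function(M) line_dist2(M, P1, P2) + line_dist2(M, Q1, Q2)
  center <- (P1 + P2 + Q1 + Q2) / 4
  half <- 2
  for (level in 1:21) {
    grid <- expand.grid(x = seq(center[1] - half, center[1] + half, length.out = 11),
                        y = seq(center[2] - half, center[2] + half, length.out = 11),
                        z = seq(center[3] - half, center[3] + half, length.out = 11))
    vals <- apply(grid, 1, obj)
    center <- as.numeric(grid[which.min(vals), ])
    half <- half / 2
  }
  expect_lt(max(abs(est$center - center)), 1e-6)
  expect_lt(abs(est$params$A_a - sqrt(sum((P1 - center)^2))), 1e-6)
  expect_lt(abs(est$params$B_b - sqrt(sum((Q2 - center)^2))), 1e-6)
})

test_that("quadrant estimation is invariant under rigid motion of the points", {
  P1 <- c(5.71, 0, 0); P2 <- c(-3.29, 0, 0)
  Q1 <- c(0, 4.37, 0.2); Q2 <- c(0, -2.75, -0.1)
  base <- estimate_quadrant_params(P1, P2, Q1, Q2)
  for (s in 1:5) {
    rot <- withr::with_seed(s, {
      ang <- stats::runif(3, -pi, pi)
      compose_transform(affine_params(ang[1], ang[2], ang[3],
                                      t_x = stats::runif(1, -10, 10),
                                      t_y = stats::runif(1, -10, 10),
                                      t_z = stats::runif(1, -10, 10)))
    })
    mv <- function(p) drop(rot[1:3, 1:3] %*% p + rot[1:3, 4])
    est <- estimate_quadrant_params(mv(P1), mv(P2), mv(Q1), mv(Q2))
    expect_lt(max(abs(unlist(est$params[c("A_a", "A_b", "B_a", "B_b")]) -
                      unlist(base$params[c("A_a", "A_b", "B_a", "B_b")]))),
              1e-9)
  }
})

test_that("corresponding deletion removes the same pairs and renumbers", {
  cl <- build_centerline(mean_cochlea())
  m <- place_landmarks(cl, 90)
  t <- apply_transform(compose_transform(affine_params(t_x = 1)), m)
  # delete the apex landmark from a 12-pair set
  out <- delete_landmarks(m, t, 12L)
  expect_identical(nrow(out$model), 11L)
  expect_identical(nrow(out$target), 11L)
  # no-op deletion
  same <- delete_landmarks(m, t, integer())
  expect_identical(same$model, m)
  # delete {2, 5, 9} from a 20-pair set: old label 3 becomes 2
  cl24 <- build_centerline(mean_cochlea(turns = 2.4))
  m20 <- place_landmarks(cl24, 45)
  t20 <- apply_transform(compose_transform(affine_params(t_y = 2)), m20)
  red <- delete_landmarks(m20, t20, c(2L, 5L, 9L))
  expect_identical(nrow(red$model), 17L)
  expect_identical(red$model$label, 1:17)
  expect_equal(unlist(red$model[2, c("x_mm", "y_mm", "z_mm")]),
               unlist(m20[3, c("x_mm", "y_mm", "z_mm")]))
  # the i-th pair after deletion is the same pair as before
  keep <- setdiff(1:20, c(2, 5, 9))
  expect_equal(lapply(red$target, c)[c("x_mm", "y_mm", "z_mm")],
               lapply(t20[keep, ], c)[c("x_mm", "y_mm", "z_mm")])
  expect_error(delete_landmarks(m, t, 99L), "exist")
})

test_that("landmark files round-trip losslessly through CSV and JSON", {
  lm <- random_landmarks(7, seed = 42, source = "segmented")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, csv)
  write_landmarks(lm, js)
  back_csv <- read_landmarks(csv)
  back_js <- read_landmarks(js)
  expect_equal(lm_coords_test(back_csv), lm_coords_test(lm))
  expect_equal(lm_coords_test(back_js), lm_coords_test(lm))
  expect_identical(attr(back_js, "source"), "segmented")
  # readers validate ordering
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,x_mm,y_mm,z_mm", "2,0,0,0", "1,1,1,1"), bad)
  expect_error(read_landmarks(bad), "consecutive")
})
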