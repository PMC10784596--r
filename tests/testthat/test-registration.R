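test_that("transform composition matches the explicit factor product", {
  # identity parameters give the identity matrix
  expect_equal(compose_transform(affine_params()), diag(4))
  # pure translation
  Tt <- compose_transform(affine_params(t_x = 1, t_y = 2, t_z = 3))
  expect_equal(drop(Tt %*% c(0, 0, 0, 1)), c(1, 2, 3, 1))
  # rotation about x after anisotropic scaling: build the four factor
  # matrices independently and compare entrywise
  p <- affine_params(alpha = pi / 2, c_x = 2, s_xy = 0.3, s_yz = -0.2,
                     t_y = 5)
  S <- rbind(c(1, 0.3, 0), c(0, 1, -0.2), c(0, 0, 1))
  C <- diag(c(2, 1, 1))
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(pi / 2), -sin(pi / 2)),
              c(0, sin(pi / 2), cos(pi / 2)))
  L <- Rx %*% C %*% S
  expected <- diag(4)
  expected[1:3, 1:3] <- L
  expected[1:3, 4] <- c(0, 5, 0)
  expect_equal(compose_transform(p), expected)
  # the scaled basis vector lands where the factor product says
  expect_equal(drop(compose_transform(p) %*% c(1, 0, 0, 1))[1:3],
               drop(L %*% c(1, 0, 0)) + c(0, 5, 0))
  expect_error(affine_params(c_x = -1), "positive")
})

test_that("reflection flags and rotations compose with the expected determinant", {
  for (s in 1:5) {
    p <- withr::with_seed(s, affine_params(
      alpha = stats::runif(1, -pi, pi), beta = stats::runif(1, -pi, pi),
      gamma = stats::runif(1, -pi, pi),
      c_x = stats::runif(1, 0.5, 2), c_y = stats::runif(1, 0.5, 2),
      c_z = stats::runif(1, 0.5, 2),
      s_xy = stats::runif(1, -0.3, 0.3),
      reflection = sample(c(-1, 1), 3, replace = TRUE)
    ))
    Tm <- compose_transform(p)
    expect_equal(Tm[4, ], c(0, 0, 0, 1))
    det_expected <- prod(p$reflection) * p$c_x * p$c_y * p$c_z
    expect_equal(det(Tm[1:3, 1:3]), det_expected)
  }
})

test_that("rigid parameters (unit scale, zero shear) preserve pairwise distances", {
  lm <- random_landmarks(8, seed = 3)
  p <- affine_params(alpha = 0.7, beta = -1.2, gamma = 2.9,
                     t_x = 4, t_y = -6, t_z = 2)
  moved <- apply_transform(compose_transform(p), lm)
  expect_lt(max(abs(dist(lm_coords_test(moved)) - dist(lm_coords_test(lm)))),
            1e-9)
})

test_that("SSD matches its definition", {
  lm <- random_landmarks(5, seed = 11)
  expect_identical(ssd(lm, lm), 0)
  # single pair at distance 2 contributes 4 mm^2
  a <- landmark_set(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  b <- landmark_set(rbind(c(2, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(ssd(a, b), 4)
  # naive-loop oracle on random pairs
  tgt <- random_landmarks(5, seed = 12)
  acc <- 0
  for (i in 1:5) {
    acc <- acc + sum((lm_coords_test(lm)[i, ] - lm_coords_test(tgt)[i, ])^2)
  }
  expect_equal(ssd(lm, tgt), acc)
  expect_error(ssd(lm, random_landmarks(4, seed = 1)), "equal length")
})

test_that("apply_transform composes associatively and round-trips", {
  lm <- random_landmarks(6, seed = 21)
  expect_equal(apply_transform(diag(4), lm), lm)
  T1 <- compose_transform(affine_params(alpha = 0.3, t_x = 2))
  T2 <- compose_transform(affine_params(gamma = -0.8, c_y = 1.4))
  expect_equal(apply_transform(T2, apply_transform(T1, lm)),
               apply_transform(T2 %*% T1, lm))
  # translation then inverse translation
  back <- apply_transform(solve(T1), apply_transform(T1, lm))
  expect_lt(max(abs(lm_coords_test(back) - lm_coords_test(lm))), 1e-12)
  expect_identical(back$label, lm$label)
})

test_that("MAE is the mean per-landmark distance", {
  expect_equal(mae(c(0.1, 0.3)), 0.2)
  expect_equal(mae(rep(0, 5)), 0)
  expect_error(mae(numeric()), "non-empty")
  # with equal per-landmark errors, MAE = sqrt(SSD / n)
  e <- rep(0.25, 8)
  expect_equal(mae(e), sqrt(sum(e^2) / 8))
})

test_that("registration recovers a known affine transform exactly", {
  lm <- mean_model_landmarks()
  pose <- affine_params(alpha = 0.4, beta = -0.3, gamma = 1.1,
                        t_x = 5, t_y = -3, t_z = 7,
                        c_x = 1.1, c_y = 0.9, c_z = 1.05,
                        s_xy = 0.1, s_xz = -0.05, s_yz = 0.15)
  target <- apply_transform(compose_transform(pose), lm)
  fit <- register(lm, target)
  expect_lt(fit$mae, 1e-4)
  expect_lt(max(abs(fit$matrix - compose_transform(pose))), 1e-3)
  expect_true(fit$converged)
  # self-registration is a fixed point of the identity start
  self <- register(lm, lm)
  expect_lt(self$mae, 1e-8)
  expect_equal(self$matrix, diag(4), tolerance = 1e-6)
  expect_lte(self$iterations, 5)
})

test_that("SSD history is monotone and bounded by the initial SSD", {
  ph <- make_phantom(phantom_spec(noise = "quantize", seed = 7))
  fit <- register(ph$model_landmarks, ph$target_landmarks)
  expect_true(all(diff(fit$ssd_history) <= 0))
  expect_lte(fit$ssd, fit$ssd_history[1])
  expect_lte(fit$iterations, 100)
  expect_equal(fit$mae, mean(fit$errors$error_mm))
})

test_that("four affinely independent pairs are interpolated exactly", {
  m <- landmark_set(rbind(c(0, 0, 0), c(6, 0, 0), c(0, 5, 0), c(0, 0, 4)))
  t <- landmark_set(rbind(c(1, 1, 0), c(8, 2, 1), c(-1, 7, 2), c(0, 1, 9)))
  fit <- register(m, t)
  expect_lt(fit$ssd, 1e-10)
})

test_that("mirrored targets need the reflection search", {
  lm <- mean_model_landmarks()
  mirror <- diag(c(-1, 1, 1, 1))
  target <- apply_transform(mirror, lm)
  with_refl <- register(lm, target, reflection_search = TRUE)
  expect_lt(with_refl$mae, 1e-4)
  without <- register(lm, target, reflection_search = FALSE)
  expect_gt(without$mae, 0.1)
})

test_that("optimized SSD agrees with the closed-form least-squares oracle", {
  for (s in 1:5) {
    m <- random_landmarks(9, seed = s)
    t <- random_landmarks(9, seed = s + 500)
    fit <- register(m, t, reflection_search = TRUE)
    expect_lt(abs(fit$ssd - oracle_affine_ssd(m, t)), 1e-6)
  }
})

test_that("degenerate inputs are rejected", {
  flat <- landmark_set(cbind(matrix(runif(10), ncol = 2), 0))
  tgt <- random_landmarks(5, seed = 2)
  expect_error(register(flat, tgt), "degenerate")
  expect_error(register(random_landmarks(3, seed = 1),
                        random_landmarks(3, seed = 2)),
               "at least 4")
})

test_that("tidy and glance summarise a fit", {
  ph <- make_phantom(phantom_spec(noise = "none", seed = 3))
  fit <- register(ph$model_landmarks, ph$target_landmarks)
  td <- generics::tidy(fit)
  expect_identical(names(td), c("label", "error_mm"))
  expect_identical(nrow(td), fit$n)
  gl <- generics::glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$mae_mm, fit$mae)
})

test_that("registration JSON export carries the full result", {
  ph <- make_phantom(phantom_spec(noise = "none", seed = 5))
  fit <- register(ph$model_landmarks, ph$target_landmarks)
  path <- withr::local_tempfile(fileext = ".json")
  write_registration(fit, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_length(obj$p_star, 12)
  expect_equal(matrix(obj$matrix_row_major, 4, 4, byrow = TRUE), fit$matrix)
  expect_equal(obj$mae_mm, fit$mae)
  expect_equal(obj$ssd_history_mm2, fit$ssd_history)
})
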