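# Shared fixtures: small landmark sets and phantoms built in code.

mean_model_landmarks <- function(spacing = 90) {
  place_landmarks(build_centerline(mean_cochlea()), spacing)
}

# n well-spread, affinely independent random landmarks in a ~10 mm box
random_landmarks <- function(n, seed, source = "model") {
  withr::with_seed(seed, {
    pts <- matrix(stats::runif(n * 3, -5, 5), ncol = 3)
  })
  landmark_set(pts, source = source)
}

lm_coords_test <- function(lm) {
  unname(as.matrix(lm[, c("x_mm", "y_mm", "z_mm")]))
}

# closed-form full-affine least-squares SSD, computed independently of the
# package's fit path (plain base-R normal equations)
oracle_affine_ssd <- function(model, target) {
  X <- cbind(as.matrix(model[, c("x_mm", "y_mm", "z_mm")]), 1)
  Y <- as.matrix(target[, c("x_mm", "y_mm", "z_mm")])
  B <- solve(crossprod(X), crossprod(X, Y))
  sum((X %*% B - Y)^2)
}
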