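test_that("centroid size matches the closed form and the direct formula", {
  sq <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), 0)
  expect_equal(centroid_size(sq), sqrt(8))
  expect_equal(centroid_size(3 * sq), 3 * sqrt(8))  # homogeneity
  cfg <- rand_config(12, seed = 5)
  brute <- sqrt(sum(sweep(cfg, 2, colMeans(cfg))^2))
  expect_equal(centroid_size(cfg), brute)
  expect_error(centroid_size(matrix(1, 4, 3)), "degenerate")
})

test_that("OPA recovers rigid motions exactly and never reflects", {
  ref <- rand_config(12, seed = 6)
  mob <- ref %*% rot_z(pi / 2) + 5
  res <- opa_align(mob, ref)
  expect_lt(res$residual, 1e-10)

  expect_equal(opa_align(ref, ref)$residual, 0, tolerance = 1e-12)
  expect_equal(opa_align(ref, ref)$rotation, diag(3), tolerance = 1e-9)

  # mirrored configuration cannot be recovered: residual strictly positive,
  # and no proper rotation from a coarse grid beats the SVD solution
  mir <- ref %*% diag(c(-1, 1, 1))
  res_m <- opa_align(mir, ref)
  expect_gt(res_m$residual, 0.1)
  refc <- sweep(ref, 2, colMeans(ref))
  mirc <- sweep(mir, 2, colMeans(mir))
  angles <- seq(0, 2 * pi, length.out = 13)[-13]
  grid_best <- Inf
  for (a in angles) for (b in angles) for (c in angles) {
    rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
    ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
    grid_best <- min(grid_best,
                     sqrt(sum((mirc %*% (rx %*% ry %*% rot_z(c)) - refc)^2)))
  }
  expect_lte(res_m$residual, grid_best + 1e-9)

  expect_error(opa_align(rand_config(5), rand_config(6)), "mismatch")
})

test_that("GPA collapses similarity-transformed copies onto one shape", {
  base <- shell_base_shape()
  set.seed(7)
  configs <- lapply(1:6, function(i)
    sweep((base %*% rand_rotation()) * runif(1, 0.2, 5), 2, rnorm(3), "+"))
  names(configs) <- paste0("c", 1:6)
  fit <- gpa(lm_array(configs))
  for (i in 2:6) {
    expect_lt(max(abs(fit$aligned[, , i] - fit$aligned[, , 1])), 1e-6)
  }
  # aligned configs are centred with unit centroid size
  for (i in 1:6) {
    expect_lt(max(abs(colMeans(fit$aligned[, , i]))), 1e-8)
    expect_equal(centroid_size(fit$aligned[, , i]), 1, tolerance = 1e-8)
  }
  expect_equal(centroid_size(fit$consensus), 1, tolerance = 1e-8)
})

test_that("GPA consensus is equidistant from two configs and locally optimal", {
  a <- shell_base_shape()
  set.seed(8)
  b <- a + matrix(rnorm(60, sd = 0.05), 20)
  fit <- gpa(lm_array(list(a = a, b = b)))
  da <- procrustes_distance(fit$consensus, fit$aligned[, , 1])
  db <- procrustes_distance(fit$consensus, fit$aligned[, , 2])
  expect_equal(da, db, tolerance = 1e-8)

  # no randomly perturbed consensus candidate fits the sample better
  configs <- lapply(1:6, function(i) a + matrix(rnorm(60, sd = 0.05), 20))
  names(configs) <- paste0("r", 1:6)
  fit2 <- gpa(lm_array(configs))
  obj <- function(cons) {
    cons <- sweep(cons, 2, colMeans(cons))
    cons <- cons / sqrt(sum(cons^2))
    sum(vapply(1:6, function(i)
      opa_align(fit2$aligned[, , i], cons)$residual^2, numeric(1)))
  }
  ss_cons <- obj(fit2$consensus)
  for (rep in 1:100) {
    cand <- fit2$consensus + matrix(rnorm(60, sd = 0.01), 20)
    expect_lte(ss_cons, obj(cand) + 1e-12)
  }
})

test_that("Procrustes distance is a symmetric pre-metric matching OPA residuals", {
  a <- rand_config(12, seed = 9)
  b <- rand_config(12, seed = 10)
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
               tolerance = 1e-9)
  an <- sweep(a, 2, colMeans(a)); an <- an / sqrt(sum(an^2))
  bn <- sweep(b, 2, colMeans(b)); bn <- bn / sqrt(sum(bn^2))
  expect_equal(procrustes_distance(a, b), opa_align(an, bn)$residual,
               tolerance = 1e-10)
  # unchanged when both are jointly rotated
  r <- rand_rotation(seed = 11)
  expect_equal(procrustes_distance(a %*% r, b %*% r), procrustes_distance(a, b),
               tolerance = 1e-6)
})

test_that("shape PCA matches an independent eigendecomposition", {
  fx <- allometric_fixture(n = 15, seed = 12)
  pc <- shape_pca(fx$fit, tangent = FALSE)
  # orthonormal axes, centred scores
  expect_equal(crossprod(pc$axes), diag(ncol(pc$axes)), tolerance = 1e-8)
  expect_lt(max(abs(colMeans(pc$scores))), 1e-10)
  # variances equal eigenvalues of the covariance matrix of flattened shapes
  flat <- flatten_shapes(fx$fit$aligned)
  ev <- eigen(cov(flat), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pc$variances, ev[seq_along(pc$variances)], tolerance = 1e-8)
  expect_equal(sum(pc$variances), sum(diag(cov(flat))), tolerance = 1e-8)
  # reconstruction from all axes reproduces the centred data
  centred <- sweep(flat, 2, colMeans(flat))
  expect_equal(pc$scores %*% t(pc$axes), centred, tolerance = 1e-8)
  expect_error(shape_pca(gpa(lm_array(list(
    a = rand_config(6, seed = 1), b = rand_config(6, seed = 2))))),
    "at least 3")
})

test_that("one-dimensional data yields a single non-trivial axis", {
  base <- shell_base_shape()
  v <- elongation_axis(base)
  configs <- lapply(1:8, function(i)
    unflatten_shapes(as.vector(t(base)) + (i / 40) * v))
  names(configs) <- paste0("d", 1:8)
  fit <- gpa(lm_array(configs))
  pc <- shape_pca(fit)
  expect_lt(max(pc$variances[-1]) / pc$variances[1], 1e-8)
})

test_that("similarity transforms leave at most 3K - 7 non-trivial axes", {
  base <- shell_base_shape()
  set.seed(13)
  # tiny dispersion keeps the rotation-removal residue below the threshold
  configs <- lapply(1:12, function(i) {
    cfg <- base + matrix(rnorm(60, sd = 1e-5), 20)
    sweep((cfg %*% rand_rotation()) * runif(1, 0.5, 2), 2, rnorm(3), "+")
  })
  names(configs) <- paste0("t", 1:12)
  pc <- shape_pca(gpa(lm_array(configs)))
  k <- nrow(base)
  nontrivial <- sum(pc$variances > 1e-8 * pc$variances[1])
  expect_lte(nontrivial, 3 * k - 7)
})

test_that("landmark displacement maps normalise to the unit interval", {
  a <- rand_config(12, seed = 14)
  expect_equal(landmark_displacement_map(a, a), rep(0, 12))
  b <- a; b[5, ] <- b[5, ] + c(1, 0, 0)
  d <- landmark_displacement_map(a, b)
  expect_equal(d[5], 1)
  expect_equal(d[-5], rep(0, 11))
  b2 <- a + matrix(runif(36), 12)
  expect_equal(max(landmark_displacement_map(a, b2)), 1)
})

test_that("GPA serialisation round-trips the aligned sample", {
  fx <- allometric_fixture(n = 6, seed = 15)
  dir <- tempfile()
  write_gpa(fx$fit, dir)
  back <- read_landmarks(file.path(dir, "aligned.csv"), "csv-long")
  expect_lt(max(abs(back - fx$fit$aligned)), 1e-9)
  cs <- read.table(file.path(dir, "centroid_sizes.tsv"), header = TRUE, sep = "\t")
  expect_equal(cs$centroid_size, unname(fx$fit$centroid_sizes), tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
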