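test_that("perfectly allometric shapes give R2 = 1 and the minimal p", {
  set.seed(31)
  n <- 12
  v <- rnorm(30); v <- v / sqrt(sum(v^2))
  s <- runif(n, 1, 3)
  flat <- outer(s, v)
  f <- fit_allometry(flat, s, n_perm = 199, seed = 1)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_equal(f$p_value, 1 / 200)
})

test_that("R2 agrees with an independent residual computation", {
  fx <- allometric_fixture(n = 18, seed = 32)
  f <- fit_allometry(fx$flat, fx$log_size, n_perm = 49, seed = 1)
  res <- apply(fx$flat, 2, function(col) resid(lm(col ~ fx$log_size)))
  tot <- sweep(fx$flat, 2, colMeans(fx$flat))
  expect_equal(f$r2, 1 - sum(res^2) / sum(tot^2), tolerance = 1e-8)
})

test_that("exhaustive permutation p matches an independent enumeration at n = 5", {
  set.seed(33)
  n <- 5
  x <- c(1.0, 1.3, 1.9, 2.2, 2.8)
  flat <- outer(log(x), rnorm(9)) + matrix(rnorm(n * 9, sd = 0.4), n)
  f <- fit_allometry(flat, x, n_perm = "exhaustive")

  # oracle: every ordering of the response rows, F from per-column lm fits
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ]
  expect_equal(nrow(perms), factorial(n))
  f_of <- function(y) {
    ss_tot <- sum(sweep(y, 2, colMeans(y))^2)
    ss_res <- sum(vapply(seq_len(ncol(y)), function(j)
      sum(resid(lm(y[, j] ~ x))^2), numeric(1)))
    ((ss_tot - ss_res) / 1) / (ss_res / (n - 2))
  }
  f_obs <- f_of(flat)
  f_all <- apply(perms, 1, function(p) f_of(flat[p, , drop = FALSE]))
  expect_equal(f$f_stat, f_obs, tolerance = 1e-10)
  expect_equal(f$p_value, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
})

test_that("permutation test holds its nominal type-I error on null data", {
  set.seed(34)
  reject <- vapply(1:500, function(r) {
    n <- 20
    flat <- matrix(rnorm(n * 12), n)
    s <- runif(n, 1, 3)
    fit_allometry(flat, s, n_perm = 99, seed = 10000 + r)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("CAC recovers a planted allometric direction", {
  set.seed(35)
  n <- 40
  v <- rnorm(60); v <- v / sqrt(sum(v^2))
  s <- runif(n, 0, 1)
  flat <- outer(s, v) + matrix(rnorm(n * 60, sd = 0.002), n)
  cc <- cac_scores(flat, s)
  expect_gte(abs(sum(cc$axis * v)), 0.99)
  expect_equal(sqrt(sum(cc$axis^2)), 1, tolerance = 1e-10)
  # sign convention and centring
  expect_gte(cor(cc$scores, s), 0)
  expect_equal(mean(cc$scores), 0, tolerance = 1e-10)
  expect_error(cac_scores(flat, rep(1, n)), "zero variance")
})

test_that("PredLine equals PC1 of the fitted values by independent eigendecomposition", {
  fx <- allometric_fixture(n = 16, seed = 36)
  f <- fit_allometry(fx$flat, fx$log_size, n_perm = 49, seed = 1)
  fitted <- vapply(seq_len(ncol(fx$flat)), function(j)
    fitted(lm(fx$flat[, j] ~ fx$log_size)), numeric(nrow(fx$flat)))
  fc <- sweep(fitted, 2, colMeans(fitted))
  e1 <- eigen(cov(fc), symmetric = TRUE)$vectors[, 1]
  oracle <- as.vector(fc %*% e1)
  if (cor(oracle, fx$log_size) < 0) oracle <- -oracle
  expect_equal(f$predline_scores, oracle, tolerance = 1e-8)
  # one predictor: perfect rank correlation with size
  expect_equal(cor(f$predline_scores, fx$log_size, method = "spearman"), 1)
})

test_that("zero-slope models give all-zero PredLine scores", {
  set.seed(37)
  n <- 10
  flat <- matrix(rep(rnorm(12), each = n), n)  # constant shapes
  flat <- flat + outer(rep(0, n), rnorm(12))
  expect_error(fit_allometry(flat, runif(n, 1, 2)), "degenerate response")
  # shape variation essentially orthogonal to size: fitted values are flat
  s <- rep(c(1, 2), length.out = n)
  sc <- s - mean(s)
  y <- matrix(0, n, 12)
  y[, 1] <- rnorm(n)
  y[, 1] <- y[, 1] - mean(y[, 1]) - sc * sum(y[, 1] * sc) / sum(sc^2)
  y[, 2] <- 1e-11 * s
  f <- fit_allometry(y, s, n_perm = 9, seed = 1)
  expect_lt(max(abs(f$predline_scores)), 1e-10)
})

test_that("CAC and PredLine scores are invariant under joint rotation", {
  fx <- allometric_fixture(n = 14, seed = 38)
  f1 <- fit_allometry(fx$flat, fx$log_size, n_perm = 19, seed = 2)
  q <- rand_rotation(seed = 39)
  rot <- flatten_shapes(unflatten_shapes(fx$flat))  # identity reshape
  arr <- unflatten_shapes(fx$flat)
  for (i in seq_len(dim(arr)[3])) arr[, , i] <- arr[, , i] %*% q
  f2 <- fit_allometry(flatten_shapes(arr), fx$log_size, n_perm = 19, seed = 2)
  expect_equal(f2$cac_scores, f1$cac_scores, tolerance = 1e-8)
  expect_equal(f2$predline_scores, f1$predline_scores, tolerance = 1e-8)
})

test_that("shape predictions are exact on linear data and hit the mean shape", {
  set.seed(40)
  n <- 15
  v <- rnorm(36)
  mu <- rnorm(36)
  sc <- runif(n, -1, 1)
  flat <- t(vapply(sc, function(s) mu + s * v, numeric(36)))
  pred <- predict_shape_at(sc, flat, c(mean(sc), 0.25))
  expect_equal(as.vector(t(pred[, , 1])), colMeans(flat), tolerance = 1e-8)
  expect_equal(as.vector(t(pred[, , 2])), mu + 0.25 * v, tolerance = 1e-8)
  # percentile endpoints match a hand-rolled least-squares oracle
  fx <- allometric_fixture(n = 20, seed = 41)
  cc <- cac_scores(fx$flat, fx$log_size)
  qs <- quantile(cc$scores, c(0.05, 0.95), names = FALSE)
  pred2 <- predict_shape_at(cc$scores, fx$flat, qs)
  for (j in 1:2) {
    oracle <- vapply(seq_len(ncol(fx$flat)), function(col) {
      cf <- coef(lm(fx$flat[, col] ~ cc$scores))
      cf[1] + cf[2] * qs[j]
    }, numeric(1))
    expect_equal(as.vector(t(pred2[, , j])), unname(oracle), tolerance = 1e-8)
  }
  expect_error(predict_shape_at(rep(1, 5), matrix(rnorm(15), 5), 0),
               "zero variance")
})

test_that("sex covariate model separates size and sex effects", {
  # size-driven data with random sex labels: sex rarely significant
  set.seed(42)
  pvals <- vapply(1:100, function(r) {
    n <- 20
    v <- rnorm(18); v <- v / sqrt(sum(v^2))
    s <- runif(n, 1, 3)
    flat <- outer(s, v) + matrix(rnorm(n * 18, sd = 0.2), n)
    sex <- sample(rep(c("female", "male"), length.out = n))
    fit_allometry_with_sex(flat, s, sex, n_perm = 99, seed = 500 + r)$p_sex
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.90)

  # strong additive sex offset, no size effect: sex dominates
  set.seed(43)
  n <- 24
  w <- rnorm(18); w <- w / sqrt(sum(w^2))
  sex <- rep(c("female", "male"), each = n / 2)
  s <- runif(n, 1, 3)
  flat <- outer(as.numeric(sex == "male"), w) +
    matrix(rnorm(n * 18, sd = 0.05), n)
  sm <- fit_allometry_with_sex(flat, s, sex, n_perm = 199, seed = 7)
  expect_gt(sm$z_sex, sm$z_size)
  expect_lt(sm$delta_z, 0)
  expect_lt(sm$p_sex, 0.05)

  # swapping the labels leaves the test invariant (same seed, same perms)
  swapped <- ifelse(sex == "male", "female", "male")
  sm2 <- fit_allometry_with_sex(flat, s, swapped, n_perm = 199, seed = 7)
  expect_equal(sm2$p_sex, sm$p_sex)

  # unknown-sex specimens are excluded; single-sex data is an error
  sex3 <- sex; sex3[1:3] <- "unknown"
  sm3 <- fit_allometry_with_sex(flat, s, sex3, n_perm = 49, seed = 1)
  expect_equal(sm3$n_excluded, 3)
  expect_equal(sm3$n, n - 3)
  expect_error(fit_allometry_with_sex(flat, s, rep("female", n), n_perm = 9),
               "both sexes")
})
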