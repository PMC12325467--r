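gomp <- function(x, c, d, k, x0) c + (d - c) * exp(-exp(-k * (x - x0)))

test_that("noiseless Gompertz data is recovered to high precision", {
  x <- seq(10, 100, length.out = 20)
  y <- gomp(x, 0, 1, 0.1, 50)
  f <- fit_gompertz(x, y, seed = 1)
  expect_true(f$converged)
  expect_equal(f$lower_c, 0, tolerance = 1e-6)
  expect_equal(f$upper_d, 1, tolerance = 1e-6)
  expect_equal(f$rate_k, 0.1, tolerance = 1e-6)
  expect_equal(f$inflection_x0, 50, tolerance = 1e-6)
  # value at the inflection is c + (d - c)/e
  expect_equal(predict(f, 50), 0 + 1 / exp(1), tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
})

test_that("flat data and tiny samples are rejected", {
  expect_error(fit_gompertz(1:10, rep(2, 10)), "flat data")
  expect_error(fit_gompertz(1:4, c(1, 2, 3, 4)), "at least 5")
  expect_error(fit_gompertz(c(-1, 2, 3, 4, 5), 1:5), "positive")
})

test_that("asymptote estimation is accurate under moderate noise", {
  set.seed(51)
  errs <- vapply(1:200, function(r) {
    x <- runif(200, 5, 120)
    y <- gomp(x, 0.2, 1.2, 0.08, 55) + rnorm(200, sd = 0.05 * 1)
    f <- fit_gompertz(x, y, seed = r)
    abs(f$upper_d - 1.2)
  }, numeric(1))
  expect_lt(median(errs), 0.02 * 1)
})

test_that("asymptote threshold matches the closed-form inversion", {
  # construct a fit whose Wald lower bound is exactly 0.95
  se_d <- (1 - 0.95) / qnorm(0.95)
  cov <- diag(c(0, se_d^2, 0, 0))
  fit <- structure(list(lower_c = 0, upper_d = 1, rate_k = 0.1,
                        inflection_x0 = 50, covariance = cov,
                        converged = TRUE, rss = 0, n = 20,
                        scl_range = c(10, 100), fix_lower = FALSE),
                   class = "gompertz_fit")
  thr <- asymptote_threshold(fit, ci_level = 0.90)
  expect_equal(thr, 50 - 10 * log(-log(0.95)), tolerance = 1e-10)
  expect_equal(thr, 79.6968, tolerance = 1e-3)
  # dense-grid oracle
  grid <- seq(10, 200, by = 0.01)
  oracle <- grid[which(gomp(grid, 0, 1, 0.1, 50) >= 0.95)[1]]
  expect_lt(abs(thr - oracle), 0.01)

  # zero SE: bound equals the asymptote, never attained
  fit0 <- fit; fit0$covariance <- matrix(0, 4, 4)
  expect_true(is.na(asymptote_threshold(fit0)))
  # non-converged fits propagate an error
  fitnc <- fit; fitnc$converged <- FALSE
  expect_error(asymptote_threshold(fitnc), "converge")
})

test_that("narrower asymptote intervals push the threshold later", {
  se_d <- 0.03
  fit <- structure(list(lower_c = 0, upper_d = 1, rate_k = 0.1,
                        inflection_x0 = 50, covariance = diag(c(0, se_d^2, 0, 0)),
                        converged = TRUE, rss = 0, n = 20,
                        scl_range = c(10, 100), fix_lower = FALSE),
                   class = "gompertz_fit")
  t90 <- asymptote_threshold(fit, 0.90)
  t80 <- asymptote_threshold(fit, 0.80)
  t50 <- asymptote_threshold(fit, 0.50)
  expect_gt(t80, t90)
  expect_gt(t50, t80)
})

linear_shape_fixture <- function(n = 12, k = 10, seed = 61) {
  set.seed(seed)
  mu <- rnorm(3 * k)
  v <- rnorm(3 * k)
  scl <- seq(20, 180, length.out = n)
  flat <- t(vapply(scl, function(s) mu + s * v / 200, numeric(3 * k)))
  list(scl = scl, flat = flat, scores = scl)
}

test_that("linear trajectories cross 85% of the distance at 85% of the range", {
  fx <- linear_shape_fixture()
  thr <- distance85_threshold(fx$scl, fx$scores, fx$flat, max_scl_mm = 200,
                              trajectory = "linear")
  expect_equal(thr, 20 + 0.85 * (200 - 20), tolerance = 1e-6)
  thr1 <- distance85_threshold(fx$scl, fx$scores, fx$flat, max_scl_mm = 200,
                               ratio = 1, trajectory = "linear")
  expect_equal(thr1, 200, tolerance = 1e-9)
})

test_that("distance threshold is monotone in the ratio", {
  fx <- linear_shape_fixture(seed = 62)
  thrs <- vapply(c(0.5, 0.7, 0.85, 0.95),
                 function(r) distance85_threshold(fx$scl, fx$scores, fx$flat,
                                                  max_scl_mm = 200, ratio = r,
                                                  trajectory = "linear"),
                 numeric(1))
  expect_true(all(diff(thrs) > 0))
})

test_that("Gompertz trajectories match the analytic distance-85 solution", {
  set.seed(63)
  p <- species_profile("Analyticus zero", n_specimens = 50, noise_sd = 0,
                       gompertz = list(c = 0, d = 0.05, k = 0.03, x0 = 120))
  g <- generate_species(p, seed = 7)
  fit <- gpa(g$dataset$coords)
  flat <- flatten_shapes(fit$aligned)
  cc <- cac_scores(flat, log10(fit$centroid_sizes))
  scl <- g$dataset$meta$scl_mm
  thr <- distance85_threshold(scl, cc$scores, flat, max_scl_mm = 300, seed = 1)
  grid_step <- (300 - min(scl)) / 999
  expect_lt(abs(thr - g$truth$true_distance85_mm), grid_step)
})

test_that("asymptote and distance thresholds agree on clean sigmoid data", {
  # noiseless sigmoid trajectory; the asymptote SE comes from a residual
  # bootstrap of moderately noisy replicates of the same design
  set.seed(64)
  x <- seq(20, 260, length.out = 60)
  y <- gomp(x, 0, 0.08, 0.08, 120)
  f <- fit_gompertz(x, y, seed = 1)
  boot_d <- vapply(1:100, function(b) {
    yb <- y + rnorm(60, sd = 0.20 * 0.08)
    fit_gompertz(x, yb, seed = b)$upper_d
  }, numeric(1))
  f$covariance[2, 2] <- var(boot_d)
  t_asym <- asymptote_threshold(f, ci_level = 0.90)
  mu <- rnorm(30); v <- rnorm(30); v <- v / sqrt(sum(v^2))
  flat <- t(vapply(y, function(s) mu + s * v, numeric(30)))
  t_d85 <- distance85_threshold(x, y, flat, max_scl_mm = 260, seed = 2)
  expect_lt(abs(t_asym - t_d85), 0.05 * 260)
})

test_that("percent-of-maximum reporting respects sexual size dimorphism", {
  maxes <- data.frame(species = "Sp x", max_scl_female_mm = 200,
                      max_scl_male_mm = 160)
  p <- pct_of_max(130, "Sp x", maxes)
  expect_equal(p$pct_female, 65)
  expect_equal(p$pct_male, 81.25)
  expect_equal(p$sex_used, "both")
  expect_equal(pct_of_max(200, "Sp x", maxes)$pct_female, 100)
  pd <- pct_of_max(130, "Sp x", maxes, dimorphic = TRUE, larger_sex = "female")
  expect_equal(pd$sex_used, "female")
  expect_error(pct_of_max(100, "Sp y", maxes), "absent")
  expect_error(pct_of_max(100, "Sp x", maxes, dimorphic = TRUE), "larger_sex")
})

test_that("threshold summaries report medians and extremes per proxy", {
  df <- data.frame(species = c("a", "b", "c"), proxy = "cac",
                   pct_female = c(57, 67, 75), pct_male = c(57, 67, 75),
                   sex_used = "both", asymptote_pct = c(40, NA, 60),
                   stringsAsFactors = FALSE)
  s <- summarize_thresholds(df)
  expect_equal(s$median_pct, 67)
  expect_equal(s$min_pct, 57)
  expect_equal(s$max_pct, 75)
  expect_equal(s$asym_mean_pct, 50)
  s1 <- summarize_thresholds(df[1, ])
  expect_equal(s1$median_pct, s1$min_pct)
  expect_equal(s1$median_pct, s1$max_pct)
  expect_error(summarize_thresholds(df[0, ]), "no threshold")
})
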