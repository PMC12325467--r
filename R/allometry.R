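#' Allometric shape regression with permutation inference
#'
#' Multivariate regression of Procrustes shape coordinates on log10 centroid
#' size, with significance assessed by residual randomization in a
#' permutation procedure (RRPP): residuals of the reduced (intercept-only)
#' model are permuted across specimens, the statistic is recomputed for each
#' permutation, and the p-value is the proportion of permuted F values at or
#' above the observed one (observed case counted once). The effect size Z is
#' the standardised position of ln F among the permuted ln F values.
#'
#' @name allometry
NULL

# run expr with a temporary RNG state seeded from `seed` (NULL = leave RNG alone)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Fit the shape-on-size allometric model
#'
#' @param flat_shapes N x 3K matrix of flattened aligned shapes
#'   (see [flatten_shapes()]).
#' @param log_size N log10 centroid sizes (any finite size proxy works).
#' @param n_perm number of random permutations (default 999), or
#'   `"exhaustive"` to enumerate every ordering (N <= 8).
#' @param seed integer seed making the permutations reproducible.
#' @param species optional label carried into the result.
#' @return object of class `allometric_fit` with `n`, `r2`, `f_stat`,
#'   `z_score`, `p_value`, `coefficients` (2 x 3K: intercept, slope),
#'   `cac_axis`, `cac_scores`, `predline_scores`, `size_values`.
#' @export
fit_allometry <- function(flat_shapes, log_size, n_perm = 999L, seed = NULL,
                          species = NA_character_) {
  y <- as.matrix(flat_shapes)
  n <- nrow(y)
  if (n < 4L) stop("allometric regression needs at least 4 specimens")
  if (!all(is.finite(log_size)) || length(log_size) != n) {
    stop("log_size must be ", n, " finite values")
  }
  xc <- log_size - mean(log_size)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("degenerate predictor: size has zero variance")
  yc <- sweep(y, 2L, colMeans(y))
  ss_tot <- sum(yc^2)
  if (ss_tot == 0) stop("degenerate response: all shapes identical")

  model_ss <- function(perm) {
    v <- crossprod(yc[perm, , drop = FALSE], xc)
    sum(v^2) / sxx
  }
  f_of_ss <- function(ssm) (ssm / 1) / (max(ss_tot - ssm, 0) / (n - 2L))

  ss_obs <- model_ss(seq_len(n))
  f_obs <- f_of_ss(ss_obs)
  r2 <- ss_obs / ss_tot

  if (identical(n_perm, "exhaustive")) {
    if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    f_all <- apply(perms, 1L, function(p) f_of_ss(model_ss(p)))
    p_value <- mean(f_all >= f_obs - 1e-12)
    f_perm <- f_all[-1L]  # first row is the identity ordering
    n_perm_used <- nrow(perms) - 1L
  } else {
    n_perm <- as.integer(n_perm)
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) f_of_ss(model_ss(sample.int(n))),
             numeric(1))
    })
    p_value <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
    n_perm_used <- n_perm
  }
  z_score <- (log(f_obs) - mean(log(f_perm))) / stats::sd(log(f_perm))

  slope <- as.vector(crossprod(yc, xc)) / sxx
  intercept <- colMeans(y) - slope * mean(log_size)
  coef <- rbind(intercept = intercept, slope = slope)

  cac <- cac_scores(y, log_size)
  fitted <- cbind(1, log_size) %*% coef
  pl <- predline_from_fitted(fitted, log_size)

  structure(list(species = species, n = n, r2 = r2, f_stat = f_obs,
                 z_score = z_score, p_value = p_value,
                 n_perm = n_perm_used, coefficients = coef,
                 cac_axis = cac$axis, cac_scores = cac$scores,
                 predline_scores = pl, size_values = log_size),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("allometric fit%s: n = %d, R2 = %.3f, F = %.2f, Z = %.2f, p = %.4g\n",
              if (is.na(x$species)) "" else paste0(" (", x$species, ")"),
              x$n, x$r2, x$f_stat, x$z_score, x$p_value))
  invisible(x)
}

#' Common allometric component
#'
#' The CAC is the unit direction in shape space of size-associated shape
#' change: with centred shapes Y and centred size s, the axis is Y's
#' covariance with s, normalised; specimen scores are projections onto it.
#' The axis sign is fixed so scores correlate non-negatively with size
#' (growth curves then rise).
#'
#' @param flat_shapes N x 3K matrix.
#' @param log_size N finite size values.
#' @return list with unit `axis` (length 3K) and `scores` (length N).
#' @export
cac_scores <- function(flat_shapes, log_size) {
  y <- as.matrix(flat_shapes)
  sc <- log_size - mean(log_size)
  if (sum(sc^2) == 0) stop("degenerate predictor: size has zero variance")
  yc <- sweep(y, 2L, colMeans(y))
  axis <- as.vector(crossprod(yc, sc)) / sum(sc^2)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("no size-associated shape variation (zero CAC axis)")
  axis <- axis / nrm
  scores <- as.vector(yc %*% axis)
  if (stats::cor(scores, log_size) < 0) {
    axis <- -axis
    scores <- -scores
  }
  list(axis = axis, scores = scores)
}

predline_from_fitted <- function(fitted, log_size) {
  fc <- sweep(fitted, 2L, colMeans(fitted))
  if (sum(fc^2) < 1e-20) return(rep(0, nrow(fitted)))
  sv <- svd(fc, nu = 1L, nv = 1L)
  scores <- as.vector(fc %*% sv$v[, 1L])
  if (stats::cor(scores, log_size) < 0) scores <- -scores
  scores
}

#' PredLine ("multivariate shape") scores
#'
#' First principal component of the model's fitted shape values — the shape
#' trajectory implied by the regression — with sign oriented to correlate
#' non-negatively with size. For the single-predictor allometric model the
#' fitted values are one-dimensional, so this is a rigid re-expression of
#' the trajectory.
#'
#' @param fit `allometric_fit` from [fit_allometry()].
#' @param flat_shapes the N x 3K shapes the model was fitted to.
#' @return numeric vector of N scores.
#' @export
predline_scores <- function(fit, flat_shapes) {
  stopifnot(inherits(fit, "allometric_fit"))
  fitted <- cbind(1, fit$size_values) %*% fit$coefficients
  predline_from_fitted(fitted, fit$size_values)
}

#' Shape-on-size model with sex as a covariate
#'
#' Sequential (type-I) decomposition of the model shape ~ size + sex,
#' each term tested by residual randomization of its own reduced model.
#' Specimens of unknown sex are excluded (recorded in the result); both
#' sexes must be represented by at least 2 specimens.
#'
#' @param flat_shapes N x 3K matrix.
#' @param log_size N finite size values.
#' @param sex character vector (female/male/unknown).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return object of class `sex_model_fit`: `z_size`, `z_sex`, `p_size`,
#'   `p_sex`, `delta_z` (= z_size - z_sex), `n`, `n_excluded`.
#' @export
fit_allometry_with_sex <- function(flat_shapes, log_size, sex,
                                   n_perm = 999L, seed = NULL) {
  y <- as.matrix(flat_shapes)
  sex <- normalize_sex(sex)
  keep <- sex != "unknown"
  n_excluded <- sum(!keep)
  y <- y[keep, , drop = FALSE]
  x <- log_size[keep]
  sx <- sex[keep]
  n <- nrow(y)
  if (length(unique(sx)) < 2L || min(table(sx)) < 2L) {
    stop("sex model needs both sexes with at least 2 specimens each")
  }
  sex01 <- as.numeric(sx == "male")

  q1 <- qr.Q(qr(matrix(1, n, 1L)))
  q2 <- qr.Q(qr(cbind(1, x)))
  q3 <- qr.Q(qr(cbind(1, x, sex01)))
  pfit <- function(q, y) q %*% crossprod(q, y)

  term_f <- function(y) {
    f1 <- pfit(q1, y); f2 <- pfit(q2, y); f3 <- pfit(q3, y)
    ss_size <- sum(f2^2) - sum(f1^2)
    ss_sex <- sum(f3^2) - sum(f2^2)
    ss_res <- max(sum(y^2) - sum(f3^2), 0)
    ms_res <- ss_res / (n - 3L)
    c(size = ss_size / ms_res, sex = ss_sex / ms_res)
  }

  f_obs <- term_f(y)
  fit1 <- pfit(q1, y); r1 <- y - fit1
  fit2 <- pfit(q2, y); r2 <- y - fit2

  perm_f <- with_seed(seed, {
    vapply(seq_len(as.integer(n_perm)), function(i) {
      p_size <- sample.int(n)
      p_sex <- sample.int(n)
      c(term_f(fit1 + r1[p_size, , drop = FALSE])[["size"]],
        term_f(fit2 + r2[p_sex, , drop = FALSE])[["sex"]])
    }, numeric(2))
  })

  p_size <- (1 + sum(perm_f[1L, ] >= f_obs[["size"]])) / (1 + ncol(perm_f))
  p_sex <- (1 + sum(perm_f[2L, ] >= f_obs[["sex"]])) / (1 + ncol(perm_f))
  z_size <- (log(f_obs[["size"]]) - mean(log(perm_f[1L, ]))) /
    stats::sd(log(perm_f[1L, ]))
  z_sex <- (log(f_obs[["sex"]]) - mean(log(perm_f[2L, ]))) /
    stats::sd(log(perm_f[2L, ]))

  structure(list(z_size = z_size, z_sex = z_sex,
                 p_size = p_size, p_sex = p_sex,
                 delta_z = z_size - z_sex,
                 n = n, n_excluded = n_excluded),
            class = "sex_model_fit")
}

#' Predict shapes at chosen trajectory scores
#'
#' Linear regression of each shape coordinate on a one-dimensional score
#' (CAC, PredLine, or any trajectory value), evaluated at target scores.
#' The prediction at the mean score is the mean shape. Targets outside the
#' observed score range are extrapolations and are flagged on the result.
#'
#' @param scores N observed scores.
#' @param flat_shapes N x 3K matrix the scores belong to.
#' @param targets scores at which to predict.
#' @return K x 3 x m array of predicted configurations (K x 3 matrix for a
#'   single target), with attribute `extrapolated` marking targets outside
#'   the observed range.
#' @export
predict_shape_at <- function(scores, flat_shapes, targets) {
  y <- as.matrix(flat_shapes)
  n <- nrow(y)
  stopifnot(length(scores) == n)
  sc <- scores - mean(scores)
  sxx <- sum(sc^2)
  if (sxx == 0) stop("degenerate predictor: scores have zero variance")
  slope <- as.vector(crossprod(y, sc)) / sxx
  mean_shape <- colMeans(y)
  pred <- vapply(targets, function(t0) mean_shape + (t0 - mean(scores)) * slope,
                 numeric(ncol(y)))
  out <- unflatten_shapes(t(pred))
  attr(out, "extrapolated") <- targets < min(scores) | targets > max(scores)
  out
}
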