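#' Gompertz shape-growth curves and adult-size thresholds
#'
#' Shape-score-versus-carapace-length data are summarised with the Gompertz
#' sigmoid
#' \deqn{f(x) = c + (d - c)\,\exp(-\exp(-k (x - x_0)))}
#' (lower asymptote c — free, scores can be negative —, upper asymptote d,
#' rate k, inflection x0). Its plateau stands for the adult shell shape; two
#' thresholds translate the curve into a minimum "adult" size: the size at
#' which the curve crosses the Wald lower confidence bound of the asymptote,
#' and the size at which a fraction (default 85%) of the total
#' juvenile-to-maximum-size shape distance is covered.
#'
#' @name gompertz
NULL

gompertz_fun <- function(x, c, d, k, x0) {
  c + (d - c) * exp(-exp(-k * (x - x0)))
}

# invert f(x) = y for a rising Gompertz curve
gompertz_inverse <- function(y, c, d, k, x0) {
  q <- (y - c) / (d - c)
  if (q <= 0 || q >= 1) return(NA_real_)
  x0 - log(-log(q)) / k
}

gompertz_start <- function(scl, score, fix_lower) {
  o <- order(scl)
  xs <- scl[o]; ys <- score[o]
  c0 <- if (fix_lower) 0 else min(score)
  d0 <- max(score)
  # steepest local change locates the inflection
  dx <- diff(xs); dy <- diff(ys)
  slopes <- ifelse(dx > 0, dy / dx, 0)
  x00 <- if (any(dx > 0)) mean(xs[which.max(abs(slopes)) + c(0L, 1L)]) else mean(xs)
  # rate heuristic: maximum Gompertz slope is k (d - c) / e; take the
  # empirical range spread over roughly the IQR of sizes
  spread <- stats::IQR(scl)
  if (spread <= 0) spread <- diff(range(scl)) / 2
  if (spread <= 0) spread <- 1
  k0 <- exp(1) / spread
  list(c = c0, d = d0, k = k0, x0 = x00)
}

#' Fit a Gompertz curve to shape scores along carapace length
#'
#' Nonlinear least squares (Levenberg–Marquardt via
#' [minpack.lm::nlsLM()]) from data-driven self-start values plus jittered
#' multi-starts; the converged fit with the lowest residual sum of squares
#' wins. A fit that stops without formal convergence is returned with
#' `converged = FALSE`, never silently dropped.
#'
#' @param scl n carapace lengths (mm, > 0), n >= 5.
#' @param score n shape-proxy values (CAC or PredLine).
#' @param fix_lower fix the lower asymptote c at 0 (3-parameter variant)?
#' @param seed integer seed for the jittered starts.
#' @param n_starts number of jittered starts beyond the self-start (>= 5).
#' @return object of class `gompertz_fit`: `lower_c`, `upper_d`, `rate_k`,
#'   `inflection_x0`, `covariance`, `converged`, `rss`, `n`, `scl_range`.
#' @export
fit_gompertz <- function(scl, score, fix_lower = FALSE, seed = NULL,
                         n_starts = 5L) {
  n <- length(scl)
  stopifnot(length(score) == n)
  if (n < 5L) stop("Gompertz fit needs at least 5 points")
  if (any(scl <= 0)) stop("carapace lengths must be positive")
  if (stats::sd(score) == 0) stop("flat data: all scores equal")

  st <- gompertz_start(scl, score, fix_lower)
  starts <- list(st)
  jit <- with_seed(seed, {
    lapply(seq_len(max(5L, n_starts)), function(i) {
      list(c = st$c + stats::rnorm(1, 0, 0.1 * (st$d - st$c + 1e-8)),
           d = st$d + stats::rnorm(1, 0, 0.1 * (st$d - st$c + 1e-8)),
           k = st$k * exp(stats::rnorm(1, 0, 0.5)),
           x0 = st$x0 + stats::rnorm(1, 0, 0.25 * diff(range(scl)) + 1e-8))
    })
  })
  starts <- c(starts, jit)

  df <- data.frame(x = scl, y = score)
  fits <- list()
  for (s in starts) {
    f <- tryCatch({
      if (fix_lower) {
        minpack.lm::nlsLM(y ~ gompertz_fun(x, 0, d, k, x0), data = df,
                          start = s[c("d", "k", "x0")],
                          lower = c(d = -Inf, k = 1e-10, x0 = -Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ gompertz_fun(x, c, d, k, x0), data = df,
                          start = s,
                          lower = c(c = -Inf, d = -Inf, k = 1e-10, x0 = -Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L) stop("Gompertz fit failed to converge from every start")

  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  if (fix_lower) cf <- c(c = 0, cf)
  vc <- tryCatch(stats::vcov(best), error = function(e) NULL)
  if (is.null(vc)) {
    p <- if (fix_lower) 3L else 4L
    vc <- matrix(NA_real_, p, p)
  }
  structure(list(lower_c = unname(cf["c"]), upper_d = unname(cf["d"]),
                 rate_k = unname(cf["k"]), inflection_x0 = unname(cf["x0"]),
                 covariance = vc, converged = isTRUE(best$convInfo$isConv),
                 rss = min(rss), n = n, scl_range = range(scl),
                 fix_lower = fix_lower),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf(
    "Gompertz fit: c = %.4g, d = %.4g, k = %.4g, x0 = %.4g (rss %.4g, %s)\n",
    x$lower_c, x$upper_d, x$rate_k, x$inflection_x0, x$rss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Evaluate a fitted Gompertz curve
#'
#' @param object `gompertz_fit`.
#' @param newdata numeric vector of sizes (mm); defaults to the fitted range.
#' @param ... unused.
#' @return predicted scores.
#' @export
predict.gompertz_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- seq(object$scl_range[1L], object$scl_range[2L], length.out = 100L)
  }
  gompertz_fun(newdata, object$lower_c, object$upper_d,
               object$rate_k, object$inflection_x0)
}

#' Adult-size threshold from the asymptote confidence bound
#'
#' Computes the Wald lower bound of the upper asymptote,
#' L = d - z * SE(d) at the requested confidence level (default 90%, so the
#' lower 5% bound), and inverts the fitted curve in closed form,
#' x = x0 - ln(-ln((L - c)/(d - c))) / k, to find the smallest size whose
#' predicted score reaches L. Returns `NA` when the bound does not cut the
#' rising part of the curve (L <= c or L >= d, including SE(d) = 0) — the
#' cases where no plateau-based threshold is inferable.
#'
#' @param fit converged `gompertz_fit`.
#' @param ci_level confidence level of the two-sided interval (default 0.90).
#' @return size in mm, or `NA_real_`.
#' @export
asymptote_threshold <- function(fit, ci_level = 0.90) {
  stopifnot(inherits(fit, "gompertz_fit"))
  if (!fit$converged) stop("Gompertz fit did not converge; no threshold")
  p <- nrow(fit$covariance)
  d_idx <- if (fit$fix_lower) 1L else 2L  # order: (c,) d, k, x0
  se_d <- sqrt(fit$covariance[d_idx, d_idx])
  if (!is.finite(se_d)) return(NA_real_)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  L <- fit$upper_d - z * se_d
  if (L <= fit$lower_c || L >= fit$upper_d) return(NA_real_)
  gompertz_inverse(L, fit$lower_c, fit$upper_d, fit$rate_k, fit$inflection_x0)
}
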