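#' Ontogenetic staging and morphological disparity
#'
#' Within each species, specimens are clustered into three ontogenetic
#' stages ("small", "intermediate", "large") from their shape-proxy score
#' and carapace length. Pooled across species, stage groups are compared by
#' two disparity metrics — sum of ranges of ordination scores and Procrustes
#' variance of aligned shapes — with bootstrap (optionally rarefied)
#' confidence intervals and Zou's overlapping confidence-interval test.
#'
#' @name disparity
NULL

#' Assign specimens to ontogenetic stage clusters
#'
#' Both variables are standardised to zero mean / unit variance (raw mm
#' would otherwise dwarf the shape scores), pairwise Euclidean distances are
#' clustered agglomeratively with Ward linkage (minimising within-cluster
#' variance), and the tree is cut at `k` groups, labelled by ascending
#' cluster-mean carapace length.
#'
#' @param proxy_scores n shape-proxy values.
#' @param scl n carapace lengths (mm).
#' @param k number of stages (default 3: small / intermediate / large).
#' @param linkage hclust method (default `"ward.D2"`).
#' @return factor of length n with levels `small`, `intermediate`, `large`
#'   (or `stage1..stagek` for other k), ordered by mean SCL.
#' @export
stage_clusters <- function(proxy_scores, scl, k = 3L, linkage = "ward.D2") {
  n <- length(scl)
  stopifnot(length(proxy_scores) == n)
  if (n < k) stop("need at least k = ", k, " specimens, got ", n)
  z <- cbind(std_or_zero(proxy_scores), std_or_zero(scl))
  if (all(z == 0)) stop("degenerate input: zero variance in both variables")
  hc <- stats::hclust(stats::dist(z), method = linkage)
  raw <- stats::cutree(hc, k = k)
  means <- vapply(seq_len(k), function(g) mean(scl[raw == g]), numeric(1))
  relabel <- match(raw, order(means))
  labels <- if (k == 3L) c("small", "intermediate", "large")
            else paste0("stage", seq_len(k))
  factor(labels[relabel], levels = labels)
}

std_or_zero <- function(x) {
  s <- stats::sd(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Sum of ranges disparity
#'
#' Total spread of a group in an ordination: the per-axis (max - min)
#' ranges of the scores, summed over axes.
#'
#' @param pc_scores m x D matrix of ordination scores (a vector is treated
#'   as one axis).
#' @return non-negative scalar.
#' @export
sum_of_ranges <- function(pc_scores) {
  m <- as.matrix(pc_scores)
  if (nrow(m) == 0L) stop("empty score matrix")
  sum(apply(m, 2L, function(col) diff(range(col))))
}

#' Procrustes variance per group
#'
#' Mean squared Procrustes distance of each group's members to their group
#' mean shape, computed on aligned coordinates.
#'
#' @param flat_shapes n x 3K matrix of aligned shapes.
#' @param group_labels length-n grouping.
#' @return named numeric vector, one value per group.
#' @export
procrustes_variance <- function(flat_shapes, group_labels) {
  y <- as.matrix(flat_shapes)
  groups <- split(seq_len(nrow(y)), group_labels)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("group '", names(groups)[which(sizes < 2L)[1L]],
         "' has fewer than 2 members")
  }
  vapply(groups, function(idx) {
    sub <- y[idx, , drop = FALSE]
    ctr <- colMeans(sub)
    mean(rowSums(sweep(sub, 2L, ctr)^2))
  }, numeric(1))
}

#' Bootstrap (and rarefy) a disparity metric per group
#'
#' Each replicate resamples a group's members with replacement — to the
#' group's own size, or to a common `rarefy_n` when rarefying (defaulting to
#' the smallest group so unequal sampling cannot drive range-based
#' comparisons) — and recomputes the metric. Percentile confidence
#' intervals are reported.
#'
#' @param data for `metric = "sor"` an n x D matrix of ordination scores;
#'   for `metric = "pv"` an n x 3K matrix of aligned shapes.
#' @param groups length-n grouping.
#' @param metric `"sor"` (sum of ranges) or `"pv"` (Procrustes variance).
#' @param n_boot bootstrap replicates (default 1000; 0 = observed only).
#' @param rarefy_n common resample size, `NA` for none, `"min"` for the
#'   smallest group size.
#' @param ci confidence level (default 0.95).
#' @param seed integer seed.
#' @return data.frame with one row per group: `group`, `n`, `observed`,
#'   `ci_lo`, `ci_hi`, `n_boot`, `rarefy_n`.
#' @export
bootstrap_disparity <- function(data, groups, metric = c("sor", "pv"),
                                n_boot = 1000L, rarefy_n = NA,
                                ci = 0.95, seed = NULL) {
  metric <- match.arg(metric)
  y <- as.matrix(data)
  idx_by_group <- split(seq_len(nrow(y)), groups)
  sizes <- lengths(idx_by_group)
  if (any(sizes == 0L)) stop("empty group")
  if (identical(rarefy_n, "min")) rarefy_n <- min(sizes)
  if (!is.na(rarefy_n) && rarefy_n > min(sizes)) {
    stop("rarefy_n (", rarefy_n, ") exceeds smallest group size (",
         min(sizes), ")")
  }
  metric_fun <- switch(metric,
    sor = sum_of_ranges,
    pv = function(m) mean(rowSums(sweep(m, 2L, colMeans(m))^2)))

  rows <- with_seed(seed, {
    lapply(names(idx_by_group), function(g) {
      idx <- idx_by_group[[g]]
      obs <- metric_fun(y[idx, , drop = FALSE])
      lo <- hi <- NA_real_
      if (n_boot > 0L) {
        m <- if (is.na(rarefy_n)) length(idx) else rarefy_n
        stat <- vapply(seq_len(n_boot), function(b) {
          metric_fun(y[sample(idx, m, replace = TRUE), , drop = FALSE])
        }, numeric(1))
        qs <- stats::quantile(stat, c((1 - ci) / 2, 1 - (1 - ci) / 2),
                              names = FALSE, type = 7)
        lo <- qs[1L]; hi <- qs[2L]
      }
      data.frame(group = g, n = length(idx), observed = obs,
                 ci_lo = lo, ci_hi = hi, n_boot = n_boot,
                 rarefy_n = if (is.na(rarefy_n)) length(idx) else rarefy_n,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Zou's overlapping confidence-interval test
#'
#' Quantifies how far apart the midpoints of two confidence intervals lie
#' relative to their implied standard errors: with midpoints m and implied
#' SE = width / (2 z), the statistic is |m_a - m_b| / sqrt(SE_a^2 + SE_b^2),
#' compared to a standard normal (values above 1.96 indicate
#' non-overlapping 95% intervals at the 0.05 level).
#'
#' @param ci_a,ci_b length-2 numeric `(lo, hi)` intervals.
#' @param ci_level level the intervals were built at (default 0.95).
#' @return list with `statistic` and `p_value`. Zero-width intervals with
#'   equal midpoints give statistic 0 / p 1; with different midpoints the
#'   statistic is infinite and p is 0 (flagged with a warning).
#' @export
zou_ci_test <- function(ci_a, ci_b, ci_level = 0.95) {
  stopifnot(length(ci_a) == 2L, length(ci_b) == 2L,
            ci_a[1L] <= ci_a[2L], ci_b[1L] <= ci_b[2L])
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  m_a <- mean(ci_a); m_b <- mean(ci_b)
  se_a <- diff(ci_a) / (2 * z)
  se_b <- diff(ci_b) / (2 * z)
  denom <- sqrt(se_a^2 + se_b^2)
  if (denom == 0) {
    if (m_a == m_b) return(list(statistic = 0, p_value = 1))
    warning("zero-width intervals with different midpoints")
    return(list(statistic = Inf, p_value = 0))
  }
  stat <- abs(m_a - m_b) / denom
  list(statistic = stat, p_value = 2 * stats::pnorm(-stat))
}

#' Bonferroni correction
#'
#' @param p_values raw p-values in (0, 1].
#' @return adjusted p-values, `min(1, m * p)` with m the number of tests.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Pairwise Zou tests across stage groups
#'
#' @param disp data.frame from [bootstrap_disparity()] (needs `group`,
#'   `ci_lo`, `ci_hi`).
#' @param ci_level level of the intervals.
#' @return data.frame with `pair`, `statistic`, `p_raw`, `p_bonferroni`.
#' @export
pairwise_zou <- function(disp, ci_level = 0.95) {
  g <- disp$group
  combos <- utils::combn(seq_along(g), 2L)
  rows <- apply(combos, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    zt <- zou_ci_test(c(disp$ci_lo[i], disp$ci_hi[i]),
                      c(disp$ci_lo[j], disp$ci_hi[j]), ci_level)
    data.frame(pair = paste(g[i], g[j], sep = "-"),
               statistic = zt$statistic, p_raw = zt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  rownames(out) <- NULL
  out
}
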