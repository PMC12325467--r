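#' Distance-based adult-size threshold
#'
#' Traces the species' allometric shape trajectory from its smallest sampled
#' specimen up to the largest size ever recorded for the species, and finds
#' the size at which a fraction `ratio` (default 85%) of the total
#' juvenile-to-maximum shape distance has been covered:
#' \enumerate{
#'   \item regress the shape-proxy score on carapace length to extract the
#'     trajectory (`trajectory = "gompertz"`, the default, fits the Gompertz
#'     shape-growth curve; `"linear"` uses ordinary least squares);
#'   \item evaluate predicted scores at `n_grid` evenly spaced sizes from the
#'     smallest sampled SCL to `max_scl_mm`;
#'   \item map scores to landmark configurations via [predict_shape_at()];
#'   \item accumulate the Procrustes distance d(x) from the predicted shape
#'     at the smallest size (monotonized by running maximum so numerical
#'     noise cannot create spurious early crossings);
#'   \item return the size where d(x) first reaches `ratio * d(max)`,
#'     linearly interpolated between the bracketing grid points.
#' }
#'
#' @param scl n carapace lengths (mm), n >= 4.
#' @param scores n shape-proxy scores (CAC or PredLine).
#' @param flat_shapes n x 3K aligned shapes the scores belong to.
#' @param max_scl_mm largest recorded size for the species
#'   (>= max sampled SCL).
#' @param n_grid grid resolution (default 1000).
#' @param ratio distance fraction defining "adult" (default 0.85).
#' @param trajectory `"gompertz"` or `"linear"` score-on-size model.
#' @param seed seed for the Gompertz multi-start.
#' @return threshold size in mm.
#' @export
distance85_threshold <- function(scl, scores, flat_shapes, max_scl_mm,
                                 n_grid = 1000L, ratio = 0.85,
                                 trajectory = c("gompertz", "linear"),
                                 seed = NULL) {
  trajectory <- match.arg(trajectory)
  n <- length(scl)
  if (n < 4L) stop("distance threshold needs at least 4 specimens")
  if (max_scl_mm < max(scl)) {
    stop("max_scl_mm (", max_scl_mm, ") below largest sampled SCL (",
         max(scl), ")")
  }
  grid <- seq(min(scl), max_scl_mm, length.out = n_grid)
  pred_scores <- if (trajectory == "gompertz") {
    predict(fit_gompertz(scl, scores, seed = seed), grid)
  } else {
    fit <- stats::lm.fit(cbind(1, scl), scores)
    cbind(1, grid) %*% fit$coefficients
  }
  shapes <- predict_shape_at(scores, flat_shapes, as.vector(pred_scores))
  flat_pred <- flatten_shapes(shapes)
  d <- sqrt(rowSums(sweep(flat_pred, 2L, flat_pred[1L, ])^2))
  d <- cummax(d)  # monotonize
  total <- d[n_grid]
  if (total <= 0) stop("flat trajectory: no shape change along the size range")
  target <- ratio * total
  i <- which(d >= target)[1L]
  if (i == 1L) return(grid[1L])
  # interpolate the crossing within the bracketing grid step
  grid[i - 1L] + (target - d[i - 1L]) / (d[i] - d[i - 1L]) * diff(grid[1:2])
}

#' Express a size threshold as a percentage of the species maximum
#'
#' @param threshold_mm threshold size in mm.
#' @param species species name.
#' @param max_table max-size table ([read_max_sizes()]).
#' @param dimorphic is the species strongly sexually size-dimorphic? (a
#'   per-species judgement supplied by the analyst, not auto-detected).
#' @param larger_sex `"female"` or `"male"`: the larger sampled sex, used as
#'   the reference record when `dimorphic` is TRUE.
#' @return list with `pct_female`, `pct_male`, `sex_used`
#'   (`"both"`, `"female"`, or `"male"`).
#' @export
pct_of_max <- function(threshold_mm, species, max_table,
                       dimorphic = FALSE, larger_sex = NULL) {
  j <- match(species, max_table$species)
  if (is.na(j)) stop("species '", species, "' absent from max-size table")
  pf <- 100 * threshold_mm / max_table$max_scl_female_mm[j]
  pm <- 100 * threshold_mm / max_table$max_scl_male_mm[j]
  sex_used <- "both"
  if (isTRUE(dimorphic)) {
    if (is.null(larger_sex) || !larger_sex %in% c("female", "male")) {
      stop("dimorphic species needs larger_sex = 'female' or 'male'")
    }
    sex_used <- larger_sex
  }
  list(pct_female = pf, pct_male = pm, sex_used = sex_used)
}

headline_pct <- function(pct_female, pct_male, sex_used) {
  ifelse(sex_used == "male", pct_male, pct_female)
}

#' Summarise per-species adult-size thresholds
#'
#' @param results data.frame with columns `species`, `proxy`, `pct_female`,
#'   `pct_male`, `sex_used`, and optionally `asymptote_pct` (asymptote-based
#'   threshold as % of maximum SCL, `NA` when no plateau was inferable).
#' @return data.frame, one row per proxy: median/min/max of the headline
#'   distance-based percentage (the larger sex's record for dimorphic
#'   species), and mean/min/max of the asymptote-based percentages.
#' @export
summarize_thresholds <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("no threshold results to summarise")
  out <- do.call(rbind, lapply(split(results, results$proxy), function(df) {
    pct <- headline_pct(df$pct_female, df$pct_male, df$sex_used)
    asym <- if ("asymptote_pct" %in% names(df)) df$asymptote_pct[!is.na(df$asymptote_pct)] else numeric()
    data.frame(proxy = df$proxy[1L], n_species = nrow(df),
               median_pct = stats::median(pct),
               min_pct = min(pct), max_pct = max(pct),
               asym_mean_pct = if (length(asym)) mean(asym) else NA_real_,
               asym_min_pct = if (length(asym)) min(asym) else NA_real_,
               asym_max_pct = if (length(asym)) max(asym) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
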