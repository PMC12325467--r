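#' Synthetic ontogenetic landmark growth series
#'
#' Generates per-species samples of 3D shell landmark configurations whose
#' shape deforms along a fixed direction in shape space by a Gompertz
#' function of carapace length, with isotropic landmark noise, optional
#' sexual size/shape dimorphism, uneven size sampling, and random digitising
#' frames (rotation, translation, scale). Every generated dataset carries an
#' analytic ground truth for the adult-size threshold, so the whole pipeline
#' can be validated end to end without external data.
#'
#' @name synthetic-data
NULL

#' Schematic shell base shape
#'
#' A half-ellipsoid "carapace" with K = 20 fixed landmarks: 12 margin points
#' (index 1 anteriormost, index 12 posteriormost, matching the landmarking
#' convention the I/O layer assumes) and 8 dome points, scaled to unit
#' centroid size.
#'
#' @param width,height transverse and dorsoventral semi-axes relative to the
#'   anteroposterior semi-axis.
#' @return 20 x 3 matrix, unit centroid size, centred.
#' @export
shell_base_shape <- function(width = 0.7, height = 0.4) {
  marg_deg <- c(90, 120, 150, 180, 210, 240, 300, 330, 0, 30, 60, 270)
  th <- marg_deg * pi / 180
  margin <- cbind(width * cos(th), sin(th), 0)
  ring1 <- t(vapply(c(45, 135, 225, 315) * pi / 180, function(a)
    c(width * cos(a) * cos(pi / 4), sin(a) * cos(pi / 4), height * sin(pi / 4)),
    numeric(3)))
  ring2 <- t(vapply(c(0, 90, 180, 270) * pi / 180, function(a)
    c(width * cos(a) * cos(7 * pi / 18), sin(a) * cos(7 * pi / 18),
      height * sin(7 * pi / 18)), numeric(3)))
  shape <- rbind(margin, ring1, ring2)
  shape <- centre_config(shape)
  shape / centroid_size(shape)
}

#' Default ontogenetic deformation axis
#'
#' "Elongate and narrow": stretch along the anteroposterior (y) axis, shrink
#' along the transverse (x) axis — the dominant ontogenetic trend in turtle
#' shells. The direction is orthogonalised against the base shape (so the
#' deformation is pure shape change, not size) and normalised to unit length
#' in flattened shape space.
#'
#' @param base_shape K x 3 base configuration.
#' @return unit vector of length 3K.
#' @export
elongation_axis <- function(base_shape = shell_base_shape()) {
  delta <- cbind(-0.5 * base_shape[, 1L], base_shape[, 2L], 0)
  v <- as.vector(t(delta))
  b <- as.vector(t(base_shape))
  b <- b / sqrt(sum(b^2))
  v <- v - sum(v * b) * b        # orthogonal to uniform scaling of the base
  v / sqrt(sum(v^2))
}

#' Define a synthetic species
#'
#' @param species species label.
#' @param n_specimens sample size (>= 2).
#' @param scl_range sampled carapace-length range (mm).
#' @param max_recorded_scl length-2 `(female, male)` maximum recorded SCL (mm).
#' @param gompertz named list/vector `(c, d, k, x0)` of the deformation
#'   magnitude (shape-space units) versus SCL (mm); needs `d > c`.
#' @param noise_sd isotropic per-coordinate noise in shape space.
#' @param base_shape K x 3 juvenile mean shape (unit centroid size).
#' @param deformation_axis unit vector (3K) of ontogenetic shape change.
#' @param sex_size_shift relative SCL increase of females over males
#'   (0 = no size dimorphism; negative = males larger).
#' @param sex_shape_shift vector (3K) added to male shapes (0 = none).
#' @param prop_unknown_sex fraction of unsexed specimens.
#' @param scl_sampling `"uniform"` or `"size_biased"` (museum-style excess
#'   of large specimens).
#' @return object of class `species_profile`.
#' @export
species_profile <- function(species, n_specimens = 20L,
                            scl_range = c(50, 280),
                            max_recorded_scl = c(300, 300),
                            gompertz = list(c = 0, d = 0.15, k = 0.03, x0 = 120),
                            noise_sd = 0.003,
                            base_shape = shell_base_shape(),
                            deformation_axis = elongation_axis(base_shape),
                            sex_size_shift = 0,
                            sex_shape_shift = 0,
                            prop_unknown_sex = 0.15,
                            scl_sampling = c("size_biased", "uniform")) {
  scl_sampling <- match.arg(scl_sampling)
  g <- as.list(gompertz)
  stopifnot(g$d > g$c, g$k > 0, n_specimens >= 2L,
            scl_range[1L] > 0, scl_range[2L] > scl_range[1L])
  v <- deformation_axis / sqrt(sum(deformation_axis^2))
  structure(list(species = species, n_specimens = as.integer(n_specimens),
                 scl_range = scl_range, max_recorded_scl = max_recorded_scl,
                 gompertz = g, noise_sd = noise_sd,
                 base_shape = base_shape, deformation_axis = v,
                 sex_size_shift = sex_size_shift,
                 sex_shape_shift = sex_shape_shift,
                 prop_unknown_sex = prop_unknown_sex,
                 scl_sampling = scl_sampling),
            class = "species_profile")
}

# analytic 85%-distance threshold of the planted trajectory
planted_threshold <- function(g, xmin, xmax, ratio = 0.85) {
  gx <- function(x) gompertz_fun(x, g$c, g$d, g$k, g$x0)
  t0 <- gx(xmin) + ratio * (gx(xmax) - gx(xmin))
  gompertz_inverse(t0, g$c, g$d, g$k, g$x0)
}

#' Generate one species' growth series
#'
#' Carapace lengths are drawn over `scl_range` (uniformly or size-biased);
#' each specimen's shape is the base shape plus the Gompertz deformation at
#' its SCL along the deformation axis, plus sex terms and isotropic Gaussian
#' noise — all in shape space, before a random similarity transform
#' (rotation, translation, and scaling such that the anterior–posterior
#' landmark distance equals the specimen's SCL) simulates the digitising
#' frame. Deterministic given `seed`.
#'
#' @param profile `species_profile`.
#' @param seed integer seed.
#' @return list with `dataset` (`shell_dataset`), `truth` (data.frame:
#'   species, true_distance85_mm, true_pct_of_max, true_has_sex_effect) and
#'   `profile`.
#' @export
generate_species <- function(profile, seed = 1L) {
  p <- profile
  n <- p$n_specimens
  if (n < 2L) stop("n_specimens must be >= 2")
  kdim <- nrow(p$base_shape)
  base_flat <- as.vector(t(p$base_shape))
  shift <- p$sex_shape_shift
  if (length(shift) == 1L) shift <- rep(shift, 3L * kdim)

  out <- with_seed(seed, {
    u <- stats::runif(n)
    if (p$scl_sampling == "size_biased") u <- sqrt(u)
    # anchor the series at its extremes: growth series enter this kind of
    # study only when they span the juvenile-to-adult range
    if (n >= 2L) u[1:2] <- c(0, 1)
    scl <- p$scl_range[1L] + u * diff(p$scl_range)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    sex[stats::runif(n) < p$prop_unknown_sex] <- "unknown"
    if (p$sex_size_shift != 0) {
      fem <- sex == "female"
      scl[fem] <- pmin(scl[fem] * (1 + p$sex_size_shift),
                       p$max_recorded_scl[1L])
    }
    g <- p$gompertz
    configs <- vector("list", n)
    for (i in seq_len(n)) {
      flat <- base_flat +
        gompertz_fun(scl[i], g$c, g$d, g$k, g$x0) * p$deformation_axis +
        (if (sex[i] == "male") shift else 0) +
        stats::rnorm(3L * kdim, sd = p$noise_sd)
      cfg <- unflatten_shapes(flat)
      cfg <- cfg * (scl[i] / scl_from_landmarks(cfg))   # digitised in mm
      cfg <- cfg %*% random_rotation()
      configs[[i]] <- sweep(cfg, 2L, stats::runif(3L, -50, 50), `+`)
    }
    names(configs) <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "_", p$species),
                              seq_len(n))
    list(scl = scl, sex = sex, configs = configs)
  })

  coords <- lm_array(out$configs)
  meta <- data.frame(specimen_id = names(configs), species = p$species,
                     sex = out$sex, scl_mm = out$scl,
                     stringsAsFactors = FALSE)
  xmax <- max(p$max_recorded_scl)
  thr <- planted_threshold(p$gompertz, min(out$scl), xmax)
  truth <- data.frame(species = p$species,
                      true_distance85_mm = thr,
                      true_pct_of_max = 100 * thr / xmax,
                      true_has_sex_effect = any(shift != 0),
                      stringsAsFactors = FALSE)
  list(dataset = shell_dataset(coords, meta), truth = truth, profile = p)
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Generate a multi-species panel
#'
#' @param profiles list of `species_profile`s with distinct species names.
#' @param seed integer seed; each species gets an independent derived seed,
#'   so adding a species does not perturb the others.
#' @return list with `dataset` (pooled `shell_dataset`), `truths`
#'   (data.frame), `max_table` (max-size table), `profiles`.
#' @export
generate_panel <- function(profiles, seed = 1L) {
  stopifnot(length(profiles) >= 1L)
  sp <- vapply(profiles, function(p) p$species, character(1))
  if (anyDuplicated(sp)) stop("duplicate species name: ", sp[duplicated(sp)][1L])
  gens <- lapply(seq_along(profiles), function(i) {
    generate_species(profiles[[i]], seed = (seed * 131L + i * 7919L) %% 2000000011L)
  })
  coords <- do.call(abind3, lapply(gens, function(g) g$dataset$coords))
  meta <- do.call(rbind, lapply(gens, function(g) g$dataset$meta))
  truths <- do.call(rbind, lapply(gens, function(g) g$truth))
  max_table <- data.frame(
    species = sp,
    max_scl_female_mm = vapply(profiles, function(p) p$max_recorded_scl[1L], numeric(1)),
    max_scl_male_mm = vapply(profiles, function(p) p$max_recorded_scl[2L], numeric(1)),
    stringsAsFactors = FALSE)
  list(dataset = shell_dataset(coords, meta), truths = truths,
       max_table = max_table, profiles = profiles)
}

abind3 <- function(...) {
  arrs <- list(...)
  k <- dim(arrs[[1L]])[1L]
  ids <- unlist(lapply(arrs, function(a) dimnames(a)[[3L]]))
  out <- array(NA_real_, dim = c(k, 3L, length(ids)),
               dimnames = list(NULL, c("x", "y", "z"), ids))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[3L]
    out[, , at + seq_len(n)] <- a
    at <- at + n
  }
  out
}

#' Write a generated panel to the pipeline's file formats
#'
#' Emits `landmarks.tps`, `metadata.tsv`, `max_sizes.tsv` and
#' `ground_truth.json` so the files can be consumed by [read_landmarks()],
#' [read_metadata()], [read_max_sizes()] and [run_pipeline()] unchanged.
#'
#' @param panel result of [generate_panel()].
#' @param dir output directory.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landmarks(panel$dataset$coords, file.path(dir, "landmarks.tps"), "tps")
  utils::write.table(panel$dataset$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(panel$max_table, file.path(dir, "max_sizes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(panel$truths, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Build a species profile hitting a planted adult-size threshold
#'
#' Solves for the Gompertz inflection x0 such that the analytic
#' 85%-distance threshold of the planted trajectory lands at
#' `target_pct` % of the species' maximum recorded SCL.
#'
#' @param species species label.
#' @param target_pct planted threshold, % of maximum SCL.
#' @param max_scl maximum recorded SCL (mm; both sexes unless overridden).
#' @param scl_min_frac,scl_max_frac sampled range as fractions of `max_scl`.
#' @param ... further arguments to [species_profile()].
#' @return `species_profile` whose analytic threshold is `target_pct`.
#' @export
profile_for_pct <- function(species, target_pct, max_scl = 300,
                            scl_min_frac = 0.15, scl_max_frac = 0.92, ...) {
  rng <- c(scl_min_frac, scl_max_frac) * max_scl
  g0 <- list(c = 0, d = 0.15, k = 8 / max_scl, x0 = NA)
  f <- function(x0) {
    g <- g0; g$x0 <- x0
    100 * planted_threshold(g, rng[1L], max_scl) / max_scl - target_pct
  }
  x0 <- stats::uniroot(f, interval = c(0.05 * max_scl, 0.95 * max_scl),
                       tol = 1e-8)$root
  g0$x0 <- x0
  species_profile(species, scl_range = rng,
                  max_recorded_scl = c(max_scl, max_scl),
                  gompertz = g0, ...)
}

#' Default synthetic study panel
#'
#' Ten species whose planted adult-shape thresholds span 55–75% of their
#' maximum recorded carapace lengths, with sample sizes and size ranges
#' emulating a museum growth-series compilation (14–29 specimens per
#' species, size-biased sampling). All species share the same juvenile base
#' shape — juveniles resemble each other across lineages — while each
#' species' ontogenetic deformation mixes the common elongate-and-narrow
#' trend with a species-specific direction, so adult shapes diverge and
#' morphological disparity grows through ontogeny. A few species carry
#' sexual size dimorphism without shape dimorphism.
#'
#' @param n_species number of species (default 10).
#' @param common_weight weight of the shared elongation trend in each
#'   species' deformation axis (the rest is species-specific, drawn from a
#'   fixed stream so profiles do not depend on the simulation seed).
#' @return list of `species_profile`s.
#' @export
default_panel_profiles <- function(n_species = 10L, common_weight = 0.7) {
  pcts <- seq(55, 75, length.out = n_species)
  maxes <- round(seq(180, 650, length.out = n_species))
  ns <- rep(c(14L, 22L, 29L, 17L, 25L), length.out = n_species)
  base <- shell_base_shape()
  common <- elongation_axis(base)
  b <- as.vector(t(base)); b <- b / sqrt(sum(b^2))
  lapply(seq_len(n_species), function(i) {
    own <- with_seed(7L + i, stats::rnorm(length(common)))
    own <- own - sum(own * b) * b          # keep it pure shape change
    own <- own - sum(own * common) * common
    own <- own / sqrt(sum(own^2))
    axis <- common_weight * common + (1 - common_weight) * own
    profile_for_pct(sprintf("Simulatus sp%02d", i), pcts[i],
                    max_scl = maxes[i], n_specimens = ns[i],
                    deformation_axis = axis / sqrt(sum(axis^2)),
                    sex_size_shift = if (i %% 4L == 0L) 0.15 else 0)
  })
}
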