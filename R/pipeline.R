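#' Full ontogenetic shell-shape analysis pipeline
#'
#' One call runs the whole study design: dataset filtering, pooled GPA and
#' PCA, per-species allometric regressions with CAC / PredLine shape
#' proxies, Gompertz shape-growth curves with both adult-size thresholds,
#' three-stage ontogenetic clustering, and pooled stage-wise disparity with
#' bootstrap, rarefaction and Zou's overlapping-CI tests. Species failing a
#' stage (non-convergent curve, flat trajectory) are recorded in the
#' manifest and excluded from summaries — they never abort the run.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param landmarks,metadata,max_sizes input file paths (TPS / TSV), or
#'   `NULL` when `dataset` / `max_table` objects are supplied directly.
#' @param dataset optional `shell_dataset` (overrides the file inputs).
#' @param max_table optional max-size data.frame.
#' @param fill_scl_specimens specimens whose missing SCL is computed from
#'   their landmarks.
#' @param min_n,min_fold,exclude_species,exclude_specimens filtering rules
#'   (see [filter_ontogenetic_series()]).
#' @param n_perm permutations for the allometric models.
#' @param seed global seed; per-species streams are derived from it so
#'   adding a species does not perturb another species' permutations.
#' @param n_grid,ratio distance-threshold grid size and fraction.
#' @param ci_level confidence level of the asymptote bound (default 0.90).
#' @param trajectory score-on-size model feeding the distance threshold
#'   (`"gompertz"` default, `"linear"` alternative).
#' @param cluster_k number of ontogenetic stages (default 3).
#' @param cluster_proxy proxy used for staging (`"cac"` or `"predline"`).
#' @param n_boot,boot_ci,rarefy disparity bootstrap settings (`rarefy =
#'   "min"` resamples every stage to the smallest stage's size for the sum
#'   of ranges).
#' @param dimorphic named character vector: species with strong sexual size
#'   dimorphism mapped to their larger sampled sex (`"female"`/`"male"`).
#' @param sex_model_species species for which the shape ~ size + sex model
#'   is run (`NULL` = every species with both sexes adequately sampled).
#' @param tangent tangent-space projection before PCA.
#' @param out_dir directory for TSV/JSON outputs (`NULL` = in-memory only).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(landmarks = NULL, metadata = NULL, max_sizes = NULL,
                            dataset = NULL, max_table = NULL,
                            fill_scl_specimens = character(),
                            min_n = 8L, min_fold = 3.0,
                            exclude_species = character(),
                            exclude_specimens = character(),
                            n_perm = 999L, seed = 1L,
                            n_grid = 1000L, ratio = 0.85, ci_level = 0.90,
                            trajectory = "gompertz",
                            cluster_k = 3L, cluster_proxy = "cac",
                            n_boot = 1000L, boot_ci = 0.95, rarefy = "min",
                            dimorphic = character(),
                            sex_model_species = NULL,
                            tangent = TRUE, out_dir = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$dataset)) {
    for (f in c("landmarks", "metadata", "max_sizes")) {
      if (is.null(cfg[[f]])) stop("config error: need either a dataset or the '",
                                  f, "' input path")
      if (!file.exists(cfg[[f]])) stop("config error: missing file ", cfg[[f]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

species_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 131 + i * 104729) %% 2147483629)
}

#' Run the full pipeline
#'
#' @param config `pipeline_config`.
#' @return list with `allometry`, `scores`, `thresholds`, `summary`,
#'   `stages`, `disparity`, `zou`, `filter_log`, `manifest`, `gpa`, `pca`.
#'   When the config names an `out_dir`, tables are also written there as
#'   TSV plus `summary.json` and `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config

  ds <- cfg$dataset
  max_table <- cfg$max_table
  if (is.null(ds)) {
    for (f in c("landmarks", "metadata", "max_sizes")) {
      if (is.null(cfg[[f]])) {
        stop("config error: need either a dataset or the '", f, "' input path")
      }
    }
    ds <- shell_dataset(read_landmarks(cfg$landmarks), read_metadata(cfg$metadata))
    max_table <- read_max_sizes(cfg$max_sizes)
  }
  if (is.null(max_table)) stop("config error: max_table required")
  n_input <- nrow(ds$meta)
  ds <- fill_scl_from_landmarks(ds, cfg$fill_scl_specimens)

  flt <- filter_ontogenetic_series(ds, min_n = cfg$min_n, min_fold = cfg$min_fold,
                                   exclude_species = cfg$exclude_species,
                                   max_table = max_table,
                                   exclude_specimens = cfg$exclude_specimens)
  ds <- flt$dataset
  if (nrow(ds$meta) == 0L) stop("pipeline error: no specimens survive filtering")

  fit <- gpa(ds$coords)
  pca <- shape_pca(fit, tangent = cfg$tangent)
  flat <- flatten_shapes(fit$aligned)
  log_cs <- log10(fit$centroid_sizes)

  species <- sort(unique(ds$meta$species))
  allom_rows <- list(); score_rows <- list(); thr_rows <- list()
  sex_rows <- list(); stage_rows <- list(); failures <- list()

  for (si in seq_along(species)) {
    sp <- species[si]
    idx <- which(ds$meta$species == sp)
    sp_seed <- species_seed(cfg$seed, si)
    y <- flat[idx, , drop = FALSE]
    scl <- ds$meta$scl_mm[idx]
    af <- tryCatch(fit_allometry(y, log_cs[idx], n_perm = cfg$n_perm,
                                 seed = sp_seed, species = sp),
                   error = function(e) e)
    if (inherits(af, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        species = sp, stage = "allometry", reason = conditionMessage(af))
      next
    }
    allom_rows[[sp]] <- data.frame(species = sp, n = af$n, r2 = af$r2,
                                   f = af$f_stat, z = af$z_score, p = af$p_value)
    score_rows[[sp]] <- data.frame(specimen_id = ds$meta$specimen_id[idx],
                                   species = sp, cac = af$cac_scores,
                                   predline = af$predline_scores,
                                   log_cs = log_cs[idx], scl_mm = scl)

    dim_flag <- sp %in% names(cfg$dimorphic)
    larger_sex <- if (dim_flag) unname(cfg$dimorphic[[sp]]) else NULL
    j <- match(sp, max_table$species)
    if (is.na(j)) {
      failures[[length(failures) + 1L]] <- data.frame(
        species = sp, stage = "thresholds", reason = "absent from max-size table")
      next
    }
    ref_max <- if (dim_flag && identical(larger_sex, "male")) {
      max_table$max_scl_male_mm[j]
    } else max_table$max_scl_female_mm[j]

    for (proxy in c("cac", "predline")) {
      scores <- if (proxy == "cac") af$cac_scores else af$predline_scores
      gf <- tryCatch(fit_gompertz(scl, scores, seed = sp_seed),
                     error = function(e) e)
      asym_mm <- NA_real_
      if (inherits(gf, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          species = sp, stage = paste0("gompertz_", proxy),
          reason = conditionMessage(gf))
      } else if (gf$converged) {
        asym_mm <- asymptote_threshold(gf, ci_level = cfg$ci_level)
      }
      d85 <- tryCatch(
        distance85_threshold(scl, scores, y, max_scl_mm = max(ref_max, max(scl)),
                             n_grid = cfg$n_grid, ratio = cfg$ratio,
                             trajectory = cfg$trajectory, seed = sp_seed),
        error = function(e) e)
      if (inherits(d85, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          species = sp, stage = paste0("distance85_", proxy),
          reason = conditionMessage(d85))
        next
      }
      pct <- pct_of_max(d85, sp, max_table, dimorphic = dim_flag,
                        larger_sex = larger_sex)
      asym_pct <- if (is.na(asym_mm)) NA_real_ else 100 * asym_mm / ref_max
      thr_rows[[paste(sp, proxy)]] <- data.frame(
        species = sp, proxy = proxy,
        asymptote_threshold_mm = asym_mm, distance85_mm = d85,
        pct_female = pct$pct_female, pct_male = pct$pct_male,
        sex_used = pct$sex_used, asymptote_pct = asym_pct,
        stringsAsFactors = FALSE)
    }

    sexes <- ds$meta$sex[idx]
    run_sex <- if (is.null(cfg$sex_model_species)) {
      all(table(factor(sexes[sexes != "unknown"],
                       levels = c("female", "male"))) >= 2L)
    } else sp %in% cfg$sex_model_species
    if (run_sex) {
      sm <- tryCatch(fit_allometry_with_sex(y, log_cs[idx], sexes,
                                            n_perm = cfg$n_perm, seed = sp_seed),
                     error = function(e) e)
      if (inherits(sm, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          species = sp, stage = "sex_model", reason = conditionMessage(sm))
      } else {
        sex_rows[[sp]] <- data.frame(species = sp, n = sm$n,
                                     z_size = sm$z_size, z_sex = sm$z_sex,
                                     p_size = sm$p_size, p_sex = sm$p_sex,
                                     delta_z = sm$delta_z)
      }
    }

    proxy_scores <- if (cfg$cluster_proxy == "cac") af$cac_scores else af$predline_scores
    if (length(idx) >= cfg$cluster_k) {
      st <- stage_clusters(proxy_scores, scl, k = cfg$cluster_k)
      stage_rows[[sp]] <- data.frame(specimen_id = ds$meta$specimen_id[idx],
                                     species = sp, stage = as.character(st),
                                     stringsAsFactors = FALSE)
    } else {
      failures[[length(failures) + 1L]] <- data.frame(
        species = sp, stage = "clustering",
        reason = sprintf("n = %d < k = %d", length(idx), cfg$cluster_k))
    }
  }

  allometry <- if (length(allom_rows)) do.call(rbind, allom_rows) else NULL
  scores <- if (length(score_rows)) do.call(rbind, score_rows) else NULL
  thresholds <- if (length(thr_rows)) do.call(rbind, thr_rows) else NULL
  sex_models <- if (length(sex_rows)) do.call(rbind, sex_rows) else NULL
  stages <- if (length(stage_rows)) do.call(rbind, stage_rows) else NULL
  summary_df <- if (!is.null(thresholds)) summarize_thresholds(thresholds) else NULL

  disparity <- NULL; zou <- NULL
  if (!is.null(stages)) {
    stage_of <- stages$stage[match(ds$meta$specimen_id, stages$specimen_id)]
    use <- !is.na(stage_of)
    lab <- factor(stage_of[use], levels = c("small", "intermediate", "large"))
    keep_axes <- pca$variances > 1e-12 * pca$variances[1L]
    sc <- pca$scores[use, keep_axes, drop = FALSE]
    sor <- bootstrap_disparity(sc, lab, metric = "sor", n_boot = cfg$n_boot,
                               rarefy_n = cfg$rarefy, ci = cfg$boot_ci,
                               seed = species_seed(cfg$seed, 900001L))
    pv <- bootstrap_disparity(flat[use, , drop = FALSE], lab, metric = "pv",
                              n_boot = cfg$n_boot, rarefy_n = NA,
                              ci = cfg$boot_ci,
                              seed = species_seed(cfg$seed, 900002L))
    disparity <- rbind(cbind(metric = "sor", sor), cbind(metric = "pv", pv))
    if (cfg$n_boot > 0L) {
      zou <- rbind(cbind(metric = "sor", pairwise_zou(sor, cfg$boot_ci)),
                   cbind(metric = "pv", pairwise_zou(pv, cfg$boot_ci)))
    }
  }

  used_ids <- ds$meta$specimen_id
  manifest <- list(
    seed = cfg$seed,
    n_input_specimens = n_input,
    n_used_specimens = length(used_ids),
    n_filtered_specimens = n_input - length(used_ids),
    n_species = length(species),
    failures = if (length(failures)) do.call(rbind, failures) else NULL)

  res <- list(allometry = allometry, scores = scores, thresholds = thresholds,
              sex_models = sex_models, summary = summary_df, stages = stages,
              disparity = disparity, zou = zou, filter_log = flt$log,
              manifest = manifest, gpa = fit, pca = pca, config = cfg)

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  res
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  wt(res$allometry, "allometry.tsv")
  wt(res$scores, "scores.tsv")
  wt(res$thresholds, "thresholds.tsv")
  wt(res$sex_models, "sex_models.tsv")
  wt(res$stages, "stages.tsv")
  wt(res$disparity, "disparity.tsv")
  wt(res$zou, "zou_tests.tsv")
  wt(res$filter_log, "filter_log.tsv")
  if (!is.null(res$summary)) {
    jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                         dataframe = "rows", digits = NA)
  }
  manifest <- res$manifest
  if (!is.null(manifest$failures)) {
    manifest$failures <- as.data.frame(manifest$failures)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
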