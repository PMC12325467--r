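#' Read 3D landmark configurations
#'
#' Two plain-text formats are supported:
#' \describe{
#'   \item{tps}{blocks starting `LM3=K`, followed by K lines of three
#'     whitespace-separated coordinates, then an `ID=<specimen>` line.}
#'   \item{csv-long}{columns `specimen_id, landmark_index, x, y, z`, one row
#'     per landmark, 1-based `landmark_index`.}
#' }
#' The landmark count must be uniform across specimens.
#'
#' @param path file path.
#' @param format `"tps"` or `"csv-long"`; default guessed from the extension.
#' @return K x 3 x N landmark array (see [lm_array()]).
#' @export
read_landmarks <- function(path, format = c("auto", "tps", "csv-long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv-long"
  }
  configs <- if (format == "tps") read_tps_file(path) else read_csvlong_file(path)
  lm_array(configs)
}

read_tps_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  configs <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    m <- regmatches(line, regexec("^LM3=([0-9]+)$", line))[[1L]]
    if (length(m) == 0L) {
      stop("TPS format error at line ", i, ": expected 'LM3=<count>', got '",
           line, "'")
    }
    k <- as.integer(m[2L])
    if (i + k > length(lines)) {
      stop("TPS format error at line ", i, ": block promises ", k,
           " landmarks but file ends early")
    }
    coords <- matrix(NA_real_, k, 3L)
    for (j in seq_len(k)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + j]),
                                                   "[[:space:]]+")[[1L]]))
      if (length(vals) != 3L || anyNA(vals)) {
        stop("TPS format error at line ", i + j,
             ": expected 3 numeric coordinates")
      }
      coords[j, ] <- vals
    }
    idline <- trimws(lines[i + k + 1L])
    m2 <- regmatches(idline, regexec("^ID=(.+)$", idline))[[1L]]
    if (length(m2) == 0L) {
      stop("TPS format error at line ", i + k + 1L, ": expected 'ID=<specimen>'")
    }
    configs[[m2[2L]]] <- coords
    i <- i + k + 2L
  }
  if (length(configs) == 0L) stop("no landmark blocks found in ", path)
  configs
}

read_csvlong_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "landmark_index", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("csv-long file must have columns ", paste(need, collapse = ", "))
  }
  ids <- unique(df$specimen_id)
  ks <- table(df$specimen_id)
  if (length(unique(as.integer(ks))) != 1L) {
    bad <- names(ks)[as.integer(ks) != as.integer(ks)[1L]][1L]
    stop("landmark count differs across specimens (specimen '", bad, "')")
  }
  lapply(stats::setNames(ids, ids), function(id) {
    sub <- df[df$specimen_id == id, ]
    sub <- sub[order(sub$landmark_index), ]
    if (!identical(as.integer(sub$landmark_index), seq_len(nrow(sub)))) {
      stop("specimen '", id, "': landmark_index must be 1..K without gaps")
    }
    as.matrix(sub[, c("x", "y", "z")])
  })
}

#' Write landmark configurations
#'
#' Inverse of [read_landmarks()]; full-precision round trip.
#'
#' @param arr K x 3 x N landmark array.
#' @param path output path.
#' @param format `"tps"` or `"csv-long"`.
#' @export
write_landmarks <- function(arr, path, format = c("tps", "csv-long")) {
  format <- match.arg(format)
  ids <- dimnames(arr)[[3L]]
  k <- dim(arr)[1L]
  if (format == "tps") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(ids)) {
      writeLines(sprintf("LM3=%d", k), con)
      writeLines(apply(arr[, , i], 1L, function(r)
        paste(sprintf("%.12g", r), collapse = " ")), con)
      writeLines(sprintf("ID=%s", ids[i]), con)
    }
  } else {
    rows <- do.call(rbind, lapply(seq_along(ids), function(i) {
      data.frame(specimen_id = ids[i], landmark_index = seq_len(k),
                 x = arr[, 1L, i], y = arr[, 2L, i], z = arr[, 3L, i])
    }))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# canonical sex vocabulary; anything unrecognized maps to "unknown"
SEX_LEVELS <- c("female", "male", "unknown")
SEX_MAP <- c(f = "female", female = "female", fem = "female",
             m = "male", male = "male")

normalize_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(SEX_MAP[key])
  out[is.na(out)] <- "unknown"
  out
}

#' Read specimen metadata
#'
#' Expects a delimited table with header columns `specimen_id, species, sex,
#' scl_mm`. Sex labels are normalised (`F`, `fem`, `male`, ... to
#' female/male; anything unrecognised or blank to `unknown`). Missing SCL is
#' kept as `NA`; it can later be filled from the landmarks for flagged
#' specimens (see [fill_scl_from_landmarks()]).
#'
#' @param path file path (TSV or CSV; delimiter guessed from extension).
#' @return data.frame with columns specimen_id, species, sex, scl_mm.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  need <- c("specimen_id", "species", "sex", "scl_mm")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (anyDuplicated(df$specimen_id)) {
    stop("duplicate specimen_id in metadata: ",
         df$specimen_id[duplicated(df$specimen_id)][1L])
  }
  df$sex <- normalize_sex(df$sex)
  df$scl_mm <- suppressWarnings(as.numeric(df$scl_mm))
  bad <- which(!is.na(df$scl_mm) & df$scl_mm <= 0)
  if (length(bad)) {
    stop("non-positive scl_mm for specimen ", df$specimen_id[bad[1L]])
  }
  df
}

#' Read the per-species maximum recorded carapace length table
#'
#' @param path TSV with columns `species, max_scl_female_mm, max_scl_male_mm`.
#' @return data.frame, one row per species.
#' @export
read_max_sizes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("species", "max_scl_female_mm", "max_scl_male_mm")
  if (!all(need %in% names(df))) {
    stop("max-size table must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$species)) stop("max-size table: one row per species required")
  if (any(df$max_scl_female_mm <= 0) || any(df$max_scl_male_mm <= 0)) {
    stop("max-size table: sizes must be positive")
  }
  df
}

#' Bundle landmarks and metadata into one dataset
#'
#' @param coords K x 3 x N landmark array.
#' @param meta metadata data.frame (see [read_metadata()]); must cover exactly
#'   the specimens in `coords`.
#' @return an object of class `shell_dataset`.
#' @export
shell_dataset <- function(coords, meta) {
  ids <- dimnames(coords)[[3L]]
  if (!setequal(ids, meta$specimen_id)) {
    stop("landmark specimens and metadata specimens do not match")
  }
  meta <- meta[match(ids, meta$specimen_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(coords = coords, meta = meta), class = "shell_dataset")
}

#' @export
print.shell_dataset <- function(x, ...) {
  cat("shell_dataset:", dim(x$coords)[3L], "specimens,",
      dim(x$coords)[1L], "landmarks,",
      length(unique(x$meta$species)), "species\n")
  invisible(x)
}

subset_dataset <- function(ds, keep) {
  idx <- match(keep, ds$meta$specimen_id)
  shell_dataset(ds$coords[, , idx, drop = FALSE],
                ds$meta[idx, , drop = FALSE])
}

#' Fill missing carapace lengths from the landmarks of flagged specimens
#'
#' Digitised inter-landmark distance can differ from a measured SCL, so the
#' fill is applied only to explicitly named specimens, never silently.
#'
#' @param ds `shell_dataset`.
#' @param specimen_ids specimens whose missing `scl_mm` should be computed as
#'   the distance between the anterior and posterior landmarks.
#' @inheritParams scl_from_landmarks
#' @return the dataset with `scl_mm` filled for the named specimens.
#' @export
fill_scl_from_landmarks <- function(ds, specimen_ids,
                                    anterior_idx = 1L, posterior_idx = 12L) {
  for (id in specimen_ids) {
    i <- match(id, ds$meta$specimen_id)
    if (is.na(i)) stop("unknown specimen: ", id)
    if (is.na(ds$meta$scl_mm[i])) {
      ds$meta$scl_mm[i] <- scl_from_landmarks(ds$coords[, , i],
                                              anterior_idx, posterior_idx)
    }
  }
  ds
}

#' Subset a dataset to usable ontogenetic series
#'
#' Applies the study's inclusion rules: a species is kept when it has at least
#' `min_n` specimens and at least a `min_fold`-fold SCL difference between its
#' smallest and largest individuals (inclusive comparisons). Named species are
#' excluded outright (e.g. those whose size spread is an artefact of extreme
#' sexual size dimorphism), and named specimens are dropped when their SCL
#' exceeds the species' maximum recorded SCL (possible misidentifications).
#'
#' @param ds `shell_dataset`; every specimen must have `scl_mm`
#'   (fill flagged ones with [fill_scl_from_landmarks()] first).
#' @param min_n minimum specimens per species (default 8).
#' @param min_fold minimum max/min SCL ratio (default 3).
#' @param exclude_species character vector of species to drop.
#' @param max_table max-size table ([read_max_sizes()]); required when
#'   `exclude_specimens` is non-empty.
#' @param exclude_specimens specimen ids to drop if oversized relative to the
#'   species maximum (larger sex's record).
#' @return list with elements `dataset` (filtered `shell_dataset`) and
#'   `log` (data.frame item, action, reason — one row per drop).
#' @export
filter_ontogenetic_series <- function(ds, min_n = 8L, min_fold = 3.0,
                                      exclude_species = character(),
                                      max_table = NULL,
                                      exclude_specimens = character()) {
  if (anyNA(ds$meta$scl_mm)) {
    stop("all specimens need scl_mm before filtering; missing for ",
         ds$meta$specimen_id[which(is.na(ds$meta$scl_mm))[1L]])
  }
  log <- data.frame(item = character(), action = character(),
                    reason = character(), stringsAsFactors = FALSE)
  add_log <- function(item, action, reason) {
    rbind(log, data.frame(item = item, action = action, reason = reason,
                          stringsAsFactors = FALSE))
  }
  meta <- ds$meta

  drop_sp <- intersect(exclude_species, meta$species)
  for (sp in drop_sp) {
    log <- add_log(sp, "drop_species", "excluded by name")
  }
  keep <- !(meta$species %in% exclude_species)

  for (id in exclude_specimens) {
    i <- match(id, meta$specimen_id)
    if (is.na(i) || !keep[i]) next
    if (is.null(max_table)) stop("max_table required to check oversized specimens")
    j <- match(meta$species[i], max_table$species)
    if (is.na(j)) {
      stop("species '", meta$species[i], "' absent from max-size table")
    }
    sp_max <- max(max_table$max_scl_female_mm[j], max_table$max_scl_male_mm[j])
    if (meta$scl_mm[i] > sp_max) {
      keep[i] <- FALSE
      log <- add_log(id, "drop_specimen",
                     sprintf("SCL %.1f mm exceeds species maximum %.1f mm",
                             meta$scl_mm[i], sp_max))
    }
  }

  for (sp in unique(meta$species[keep])) {
    idx <- keep & meta$species == sp
    n <- sum(idx)
    scl <- meta$scl_mm[idx]
    fold <- max(scl) / min(scl)
    if (n < min_n) {
      keep[idx] <- FALSE
      log <- add_log(sp, "drop_species", sprintf("n = %d < %d", n, min_n))
    } else if (fold < min_fold) {
      keep[idx] <- FALSE
      log <- add_log(sp, "drop_species",
                     sprintf("SCL fold change %.2f < %.2f", fold, min_fold))
    }
  }

  list(dataset = subset_dataset(ds, meta$specimen_id[keep]), log = log)
}
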