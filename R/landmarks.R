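#' Landmark array utilities
#'
#' Landmark data are held the way 3D geometric morphometrics usually holds
#' them: a single specimen is a K x 3 numeric matrix (rows = landmarks, in a
#' fixed, meaningful order; columns = x, y, z in the digitising space, mm),
#' and a sample is a K x 3 x N array whose third dimnames are the specimen
#' identifiers. Landmark indices are 1-based in every user-facing function;
#' by convention of the landmarking scheme index 1 is the anteriormost and
#' index 12 the posteriormost point of the shell.
#'
#' @name landmark-arrays
NULL

#' Assemble a landmark array from a list of configurations
#'
#' @param configs named list of K x 3 numeric matrices (names = specimen ids).
#' @return K x 3 x N array with specimen ids as third dimnames.
#' @export
lm_array <- function(configs) {
  stopifnot(is.list(configs), length(configs) >= 1L)
  ids <- names(configs)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("every configuration must carry a specimen id (list names)")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate specimen id: ", ids[duplicated(ids)][1L])
  }
  ks <- vapply(configs, nrow, integer(1))
  if (length(unique(ks)) != 1L) {
    bad <- ids[ks != ks[1L]][1L]
    stop("landmark count differs across specimens (specimen '", bad,
         "' has ", ks[names(ks) == bad][1L], ", expected ", ks[1L], ")")
  }
  k <- ks[1L]
  if (k < 3L) stop("need at least 3 landmarks, got ", k)
  for (i in seq_along(configs)) {
    m <- as.matrix(configs[[i]])
    if (ncol(m) != 3L) stop("specimen '", ids[i], "': expected 3 coordinate columns")
    if (!all(is.finite(m))) stop("specimen '", ids[i], "': non-finite coordinates")
  }
  arr <- array(NA_real_, dim = c(k, 3L, length(configs)),
               dimnames = list(NULL, c("x", "y", "z"), ids))
  for (i in seq_along(configs)) arr[, , i] <- as.matrix(configs[[i]])
  arr
}

#' Flatten a landmark array to an N x 3K matrix
#'
#' Row per specimen, coordinates interleaved as (x1, y1, z1, x2, ...), the
#' ordering assumed by every shape-space operation in the package.
#'
#' @param arr K x 3 x N landmark array (or a single K x 3 matrix).
#' @return N x 3K numeric matrix with specimen ids as rownames.
#' @export
flatten_shapes <- function(arr) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  k <- dim(arr)[1L]
  n <- dim(arr)[3L]
  out <- matrix(NA_real_, n, 3L * k)
  for (i in seq_len(n)) out[i, ] <- as.vector(t(arr[, , i]))
  rownames(out) <- dimnames(arr)[[3L]]
  out
}

#' Rebuild K x 3 configurations from flattened shape rows
#'
#' @param mat N x 3K matrix (or a length-3K vector).
#' @return K x 3 x N array (K x 3 matrix when a single row is given).
#' @export
unflatten_shapes <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  k <- ncol(mat) / 3L
  stopifnot(k == round(k))
  n <- nrow(mat)
  arr <- array(NA_real_, dim = c(k, 3L, n),
               dimnames = list(NULL, c("x", "y", "z"), rownames(mat)))
  for (i in seq_len(n)) arr[, , i] <- matrix(mat[i, ], ncol = 3L, byrow = TRUE)
  if (n == 1L) arr[, , 1L] else arr
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all landmarks to their
#' centroid -- the standard geometric-morphometric size measure.
#'
#' @param config K x 3 numeric matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2L) stop("need at least 2 landmarks")
  centred <- sweep(config, 2L, colMeans(config))
  cs <- sqrt(sum(centred^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide")
  cs
}

centre_config <- function(config) {
  sweep(config, 2L, colMeans(config))
}

#' Inter-landmark Euclidean distance (straight carapace length)
#'
#' The straight carapace length (SCL) of a digitised shell is the distance
#' between the anteriormost and posteriormost landmarks, in the input units.
#'
#' @param config K x 3 matrix.
#' @param anterior_idx,posterior_idx 1-based landmark indices
#'   (defaults 1 and 12, the scheme's anterior/posterior shell points).
#' @return distance in input units (mm for digitised shells).
#' @export
scl_from_landmarks <- function(config, anterior_idx = 1L, posterior_idx = 12L) {
  config <- as.matrix(config)
  k <- nrow(config)
  if (anterior_idx < 1L || posterior_idx < 1L ||
      anterior_idx > k || posterior_idx > k) {
    stop("landmark index out of range: config has ", k, " landmarks")
  }
  d <- sqrt(sum((config[anterior_idx, ] - config[posterior_idx, ])^2))
  if (d == 0) warning("anterior and posterior landmarks coincide; SCL is 0")
  d
}
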