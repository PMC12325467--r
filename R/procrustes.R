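#' Procrustes superimposition, distances and ordination
#'
#' Classic landmark superimposition: ordinary Procrustes alignment of one
#' configuration onto another (rotation + translation, optional scaling,
#' reflections never allowed — shell landmarks have left/right anatomical
#' identity), generalized Procrustes analysis of a sample, Procrustes
#' distances, tangent-space projection and PCA of the aligned shapes.
#'
#' @name procrustes
NULL

# optimal rotation of centred X onto centred Y, reflection excluded.
# Kabsch: C = X'Y, C = U D V', R = U diag(1,1,s) V' with s = sign(det(UV'))
optimal_rotation <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Ordinary Procrustes alignment of one configuration onto a reference
#'
#' Finds the rigid motion (translation + proper rotation, optionally uniform
#' scaling) of `mobile` minimising the summed squared differences to
#' `reference`. The rotation comes from the SVD of the cross-covariance
#' matrix with the determinant forced to +1, so mirrored configurations are
#' never "fixed" by a reflection.
#'
#' @param mobile,reference K x 3 matrices with equal K.
#' @param scale also estimate a uniform scale factor? (default FALSE).
#' @return list with `aligned` (K x 3), `rotation`, `scale`, and `residual`
#'   (root summed squared difference to the centred reference).
#' @export
opa_align <- function(mobile, reference, scale = FALSE) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference))) {
    stop("dimension mismatch: mobile is ", nrow(mobile), " x ", ncol(mobile),
         ", reference is ", nrow(reference), " x ", ncol(reference))
  }
  xc <- centre_config(mobile)
  yc <- centre_config(reference)
  r <- optimal_rotation(xc, yc)
  beta <- 1
  if (scale) {
    # optimal uniform scale for rotation r: trace(Y' X R) / trace(X' X)
    beta <- sum(yc * (xc %*% r)) / sum(xc^2)
  }
  aligned <- beta * xc %*% r
  list(aligned = aligned, rotation = r, scale = beta,
       residual = sqrt(sum((aligned - yc)^2)))
}

#' Generalized Procrustes Analysis
#'
#' Gower-style iterative superimposition: every configuration is centred and
#' scaled to unit centroid size, then repeatedly rotated onto the current
#' consensus (the coordinate-wise mean, itself rescaled to unit centroid
#' size) until the root-mean-squared change of the consensus falls below
#' `tol`. The landmark scheme has fixed points only, so no semilandmark
#' sliding is involved.
#'
#' @param coords K x 3 x N landmark array, N >= 2.
#' @param tol convergence tolerance on the consensus RMS change.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return object of class `gpa_fit`: `consensus` (K x 3, unit centroid
#'   size), `aligned` (K x 3 x N, unit centroid size, centred), the original
#'   `centroid_sizes`, and `n_iterations`.
#' @export
gpa <- function(coords, tol = 1e-8, max_iter = 100L) {
  n <- dim(coords)[3L]
  if (is.na(n) || n < 2L) stop("GPA needs at least 2 configurations")
  cs <- apply(coords, 3L, centroid_size)
  aligned <- coords
  for (i in seq_len(n)) {
    aligned[, , i] <- centre_config(coords[, , i]) / cs[i]
  }
  consensus <- aligned[, , 1L]
  consensus <- consensus / sqrt(sum(consensus^2))
  it <- 0L
  repeat {
    it <- it + 1L
    for (i in seq_len(n)) {
      r <- optimal_rotation(aligned[, , i], consensus)
      aligned[, , i] <- aligned[, , i] %*% r
    }
    new_cons <- apply(aligned, c(1L, 2L), mean)
    new_cons <- centre_config(new_cons)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
    if (it >= max_iter) {
      stop("GPA did not converge in ", max_iter,
           " iterations (last consensus RMS change ", format(delta), ")")
    }
  }
  structure(list(consensus = consensus, aligned = aligned,
                 centroid_sizes = cs, n_iterations = it),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("GPA fit:", dim(x$aligned)[3L], "specimens,", dim(x$aligned)[1L],
      "landmarks,", x$n_iterations, "iterations\n")
  invisible(x)
}

#' Procrustes distance between two shapes
#'
#' Euclidean norm of the coordinate difference between two superimposed
#' configurations. With `pre_aligned = TRUE` the shapes are taken as already
#' lying in a common shape space (e.g. both from one GPA) and the norm is
#' computed directly; otherwise both are scaled to unit centroid size and
#' optimally rotated first.
#'
#' @param a,b K x 3 matrices.
#' @param pre_aligned skip superimposition?
#' @return non-negative scalar; 0 iff the shapes are identical up to the
#'   allowed transforms.
#' @export
procrustes_distance <- function(a, b, pre_aligned = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("dimension mismatch between shapes")
  if (pre_aligned) return(sqrt(sum((a - b)^2)))
  ac <- centre_config(a); ac <- ac / sqrt(sum(ac^2))
  bc <- centre_config(b); bc <- bc / sqrt(sum(bc^2))
  opa_align(ac, bc)$residual
}

#' Project aligned shapes onto the tangent space at the consensus
#'
#' Orthogonal projection: the component of each centred shape along the
#' (unit) consensus direction is removed, linearising shape space around the
#' consensus before PCA.
#'
#' @param flat N x 3K matrix of flattened aligned shapes.
#' @param consensus K x 3 consensus configuration.
#' @return N x 3K matrix.
#' @export
tangent_project <- function(flat, consensus) {
  f <- as.vector(t(consensus))
  f <- f / sqrt(sum(f^2))
  proj <- flat %*% f
  flat - tcrossprod(proj, f)
}

#' Principal component analysis of an aligned sample
#'
#' Ordination of the GPA-aligned shapes in their major axes of variation.
#' Shapes are flattened, optionally projected to the tangent space at the
#' consensus (the default, matching common geometric-morphometric practice),
#' centred, and decomposed.
#'
#' @param fit `gpa_fit` from [gpa()] (needs N >= 3).
#' @param tangent project to tangent space first? (default TRUE).
#' @return object of class `shape_pca`: `scores` (N x D), `axes`
#'   (orthonormal columns, 3K x D), `variances` (non-increasing), `center`
#'   (mean flattened shape), `tangent` flag, `consensus`.
#' @export
shape_pca <- function(fit, tangent = TRUE) {
  stopifnot(inherits(fit, "gpa_fit"))
  n <- dim(fit$aligned)[3L]
  if (n < 3L) stop("PCA needs at least 3 specimens")
  flat <- flatten_shapes(fit$aligned)
  if (tangent) flat <- tangent_project(flat, fit$consensus)
  ctr <- colMeans(flat)
  x <- sweep(flat, 2L, ctr)
  sv <- svd(x)
  d <- min(n - 1L, ncol(x))
  variances <- sv$d[seq_len(d)]^2 / (n - 1L)
  structure(list(scores = x %*% sv$v[, seq_len(d), drop = FALSE],
                 axes = sv$v[, seq_len(d), drop = FALSE],
                 variances = variances,
                 center = ctr, tangent = tangent,
                 consensus = fit$consensus),
            class = "shape_pca")
}

#' Per-landmark normalised displacement between two shapes
#'
#' Euclidean displacement of each landmark between two configurations,
#' divided by the largest displacement so values span 0–1 (0/0 defined as
#' 0 when the shapes are identical). Used to map where on the shell the
#' ontogenetic change concentrates.
#'
#' @param a,b K x 3 matrices in a common space.
#' @return numeric vector of K values in \[0, 1\].
#' @export
landmark_displacement_map <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("dimension mismatch between shapes")
  d <- sqrt(rowSums((a - b)^2))
  m <- max(d)
  if (m == 0) return(rep(0, nrow(a)))
  d / m
}

#' Serialise a GPA result to plain-text files
#'
#' Writes `consensus.csv`, `aligned.csv` (long format) and
#' `centroid_sizes.tsv` into a directory.
#'
#' @param fit `gpa_fit`.
#' @param dir output directory (created if needed).
#' @export
write_gpa <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(landmark_index = seq_len(nrow(fit$consensus)),
                              x = fit$consensus[, 1L],
                              y = fit$consensus[, 2L],
                              z = fit$consensus[, 3L]),
                   file.path(dir, "consensus.csv"), row.names = FALSE)
  write_landmarks(fit$aligned, file.path(dir, "aligned.csv"), "csv-long")
  utils::write.table(data.frame(specimen_id = dimnames(fit$aligned)[[3L]],
                                centroid_size = fit$centroid_sizes),
                     file.path(dir, "centroid_sizes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
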