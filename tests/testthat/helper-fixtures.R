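# fixture builders shared across test files; everything generated in code

# small random K x 3 configuration
rand_config <- function(k = 12L, seed = NULL, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(3L * k, sd = sd), k, 3L)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3L, 3L)
}

# random proper rotation
rand_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# aligned-sample fixture: base shape plus planted size signal and noise,
# run through GPA; returns flat shapes, log sizes, and the gpa fit
allometric_fixture <- function(n = 20L, slope = 0.1, noise = 0.003,
                               seed = 1L, axis = NULL) {
  set.seed(seed)
  base <- shell_base_shape()
  if (is.null(axis)) axis <- elongation_axis(base)
  base_flat <- as.vector(t(base))
  sizes <- runif(n, 50, 250)
  configs <- lapply(seq_len(n), function(i) {
    flat <- base_flat + slope * (log10(sizes[i]) - 2) * axis +
      rnorm(length(base_flat), sd = noise)
    cfg <- unflatten_shapes(flat) * sizes[i]
    cfg %*% rand_rotation() + 10
  })
  names(configs) <- sprintf("spec%03d", seq_len(n))
  fit <- gpa(lm_array(configs))
  list(flat = flatten_shapes(fit$aligned),
       log_size = log10(fit$centroid_sizes),
       sizes = sizes, fit = fit, axis = axis)
}

# toy metadata table
toy_meta <- function() {
  data.frame(
    specimen_id = c("a1", "a2", "a3"),
    species = c("Sp a", "Sp a", "Sp b"),
    sex = c("F", "male", ""),
    scl_mm = c(100, 200, NA),
    stringsAsFactors = FALSE)
}
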