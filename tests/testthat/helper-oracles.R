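# Independent oracles and small fixture builders shared across the suite.
# These deliberately avoid the package's own computational paths.

# Octahedral shear strain of one voxel via explicit eigenvalues of the real
# part at each sampled phase: the route stated in terms of principal strains.
oss_eigen_oracle <- function(m6, phase_samples = 16L) {
  phases <- seq(0, pi, length.out = phase_samples + 1L)[seq_len(phase_samples)]
  best <- 0
  for (phi in phases) {
    e <- Re(m6 * exp(1i * phi))
    M <- matrix(c(
      e[1], e[4], e[5],
      e[4], e[2], e[6],
      e[5], e[6], e[3]
    ), 3, 3)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    ss <- (ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 + (ev[3] - ev[1])^2
    best <- max(best, ss)
  }
  (2 / 3) * sqrt(best)
}

# Brute-force Benjamini-Hochberg step-up, straight from its definition.
bh_brute_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0L) {
    list(rejected = rep(FALSE, m), p_threshold = 0)
  } else {
    thr <- ps[max(ok)]
    list(rejected = p <= thr, p_threshold = thr)
  }
}

# Exact two-sided signed-rank p-value by full 2^n enumeration of sign
# assignments (no ties in |d| assumed), matching the exact test's convention.
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Random symmetric (packed) voxel tensors, real or complex.
random_packed_tensor <- function(n, complex = TRUE) {
  m <- matrix(rnorm(n * 6, sd = 0.01), n, 6)
  if (complex) m <- m + 1i * matrix(rnorm(n * 6, sd = 0.01), n, 6)
  array(m, c(n, 1, 1, 6))
}

# Apply a rotation R to packed tensors: eps' = R eps R^T per voxel.
rotate_packed <- function(packed, R) {
  d <- dim(packed)
  out <- packed
  idx <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  n <- prod(d[1:3])
  m <- matrix(packed, n, 6)
  for (v in seq_len(n)) {
    E <- matrix(c(
      m[v, 1], m[v, 4], m[v, 5],
      m[v, 4], m[v, 2], m[v, 6],
      m[v, 5], m[v, 6], m[v, 3]
    ), 3, 3)
    Er <- R %*% E %*% t(R)
    for (k in seq_along(idx)) out[cbind(v, 1, 1, k)] <- Er[idx[[k]][1], idx[[k]][2]]
  }
  out
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Phantom overrides that switch off all stochastic components, for analytic
# single-subject oracles.
noiseless_overrides <- function(...) {
  strainmap:::merge_overrides(
    list(
      noise_sd = list(displacement = 0, moduli = 0, afd = 0),
      subject_sigma = 0,
      wave = list(direction_sd_deg = 0, amp_field_sd = 0, reflection = 0)
    ),
    list(...)
  )
}

# z-OSS maps for a displacement cohort.
zmaps_of <- function(cohort, spec) {
  lapply(cohort, function(u) {
    oss <- octahedral_shear_strain(
      strain_from_displacement(u, spec$voxel_size, mask = spec$brain_mask)
    )
    znormalize(oss, spec$brain_mask)
  })
}

# A region_mask built from the phantom's ground truth (used where regions
# must be fixed a priori, e.g. null calibration).
truth_regions <- function(spec, which = "true") {
  hs <- switch(which,
    true = spec$hs_true, occipital = spec$hs_occipital, lateral = spec$hs_lateral
  )
  structure(
    list(
      hs = hs, ls = spec$brain_mask & !hs, t_threshold = 4, fdr_q = 0.05,
      provenance = list(list(source = "phantom_truth"))
    ),
    class = "region_mask"
  )
}
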