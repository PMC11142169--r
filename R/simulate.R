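#' @importFrom withr with_seed
NULL

# Stationary smooth Gaussian random field with unit pointwise variance:
# white noise is generated on a grid padded by the kernel radius, smoothed,
# cropped back, and scaled by the closed-form sd of the separable
# convolution, so face voxels are statistically identical to the interior.
smooth_noise_field <- function(grid_shape, scale, mask) {
  r <- max(1L, as.integer(ceiling(3 * scale)))
  k <- stats::dnorm(seq(-r, r), sd = scale)
  k <- k / sum(k)
  big <- grid_shape + 2L * r
  f <- gaussian_smooth(array(rnorm(prod(big)), big), scale)
  f <- f[(r + 1):(r + grid_shape[1]), (r + 1):(r + grid_shape[2]),
    (r + 1):(r + grid_shape[3])]
  f <- f / sum(k^2)^1.5
  f - mean(f[mask])
}

actuation_geometry <- function(actuation) {
  switch(actuation,
    # occipital actuation: shear wave travelling posterior->anterior (+y),
    # polarised along z; lateral: travelling left->right (+x), polarised along y
    occipital = list(k_hat = c(0, 1, 0), pol = c(0, 0, 1)),
    lateral = list(k_hat = c(1, 0, 0), pol = c(0, 1, 0))
  )
}

#' Simulate a cohort of complex harmonic displacement fields
#'
#' Each subject's field is a smooth propagating shear plane wave
#' `u(r) = A * env(r) * m_s(r) * pol * exp(i (k . r + phi_s))` plus complex
#' voxel noise, where `env` multiplies the amplitude by
#' `spec$oss_amplification` inside the actuation-matched high-strain blob
#' (with a smoothed edge), and `m_s` is a per-subject smooth multiplicative
#' amplitude field providing between-subject variability. The propagation
#' direction is jittered per subject around the actuation axis. Displacement
#' is zero outside the brain mask. Deterministic under the seed.
#'
#' @param spec A [make_phantom()] specification.
#' @param actuation `"occipital"` or `"lateral"`.
#' @param frequency Actuation frequency in Hz (> 0). The wavelength scales as
#'   `ref_frequency / frequency` around the spec's wavelength, floored at 6
#'   voxels.
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; defaults to the spec's.
#' @return List of `displacement_vol` arrays (`nx x ny x nz x 3`, complex, mm)
#'   with `frequency`, `actuation`, `voxel_size` and `mask` attributes.
#' @export
simulate_displacement_cohort <- function(spec, actuation = c("occipital", "lateral"),
                                         frequency = 50, n_subjects = 2L,
                                         seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.character(actuation) || !all(actuation %in% c("occipital", "lateral")))
    stop("actuation must be \"occipital\" or \"lateral\"", call. = FALSE)
  actuation <- match.arg(actuation)
  if (!is.numeric(frequency) || frequency <= 0)
    stop("frequency must be positive (Hz)", call. = FALSE)
  if (n_subjects < 1L) stop("n_subjects must be at least 1", call. = FALSE)

  g <- spec$grid_shape
  mask <- spec$brain_mask
  geo <- actuation_geometry(actuation)
  blob <- if (actuation == "occipital") spec$hs_occipital else spec$hs_lateral
  # amplification envelope: exactly `oss_amplification` on the blob, decaying
  # smoothly just outside it so the analytic in-blob strain ratio is preserved
  soft <- gaussian_smooth(blob * 1, spec$wave$edge_sigma)
  soft[blob] <- 1
  env <- 1 + (spec$oss_amplification - 1) * soft

  lambda_vox <- max(6, spec$wave$wavelength_voxels * spec$ref_frequency / frequency)
  lambda_mm <- lambda_vox * spec$voxel_size
  kmag <- 2 * pi / lambda_mm
  coords <- list(
    (seq_len(g[1]) - 1) * spec$voxel_size,
    (seq_len(g[2]) - 1) * spec$voxel_size,
    (seq_len(g[3]) - 1) * spec$voxel_size
  )

  lapply(seq_len(n_subjects), function(s) {
    with_seed(derive_seed(seed, stage = match(actuation, c("occipital", "lateral")), k = s), {
      ang <- spec$wave$direction_sd_deg * pi / 180
      if (ang > 0) {
        axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
        theta <- rnorm(1, sd = ang)
        ct <- cos(theta); st <- sin(theta)
        # rotate k_hat by theta about a random axis; carry the polarisation along
        rot <- function(v) {
          v * ct + c(
            axis[2] * v[3] - axis[3] * v[2],
            axis[3] * v[1] - axis[1] * v[3],
            axis[1] * v[2] - axis[2] * v[1]
          ) * st + axis * sum(axis * v) * (1 - ct)
        }
        k_hat <- rot(geo$k_hat); pol <- rot(geo$pol)
      } else {
        k_hat <- geo$k_hat; pol <- geo$pol
      }
      phi <- runif(1, 0, 2 * pi)
      if (spec$wave$amp_field_sd > 0) {
        m_s <- exp(spec$wave$amp_field_sd *
          smooth_noise_field(g, spec$wave$amp_field_scale, mask))
      } else {
        m_s <- array(1, g)
      }
      travel <- outer(outer(coords[[1]] * k_hat[1], coords[[2]] * k_hat[2], `+`),
        coords[[3]] * k_hat[3], `+`)
      # forward wave plus a weaker counter-propagating reflection with random
      # relative phase: gives each subject a standing-wave interference
      # pattern at a random position, as reflections off the skull do
      psi <- runif(1, 0, 2 * pi)
      wavefield <- exp(1i * (kmag * travel + phi)) +
        spec$wave$reflection * exp(1i * (-kmag * travel + phi + psi))
      carrier <- spec$wave$amplitude * env * m_s * wavefield
      u <- array(0 + 0i, c(g, 3L))
      nsd <- spec$noise_sd$displacement
      for (comp in 1:3) {
        plane <- carrier * pol[comp]
        if (nsd > 0) {
          plane <- plane + nsd * (array(rnorm(prod(g)), g) + 1i * array(rnorm(prod(g)), g))
        }
        plane[!mask] <- 0 + 0i
        u[, , , comp] <- plane
      }
      structure(u,
        class = "displacement_vol", frequency = frequency, actuation = actuation,
        voxel_size = spec$voxel_size, mask = mask, subject = s
      )
    })
  })
}

#' Simulate a cohort of multi-frequency storage/loss modulus sets
#'
#' At every voxel the moduli are linear in frequency:
#' `G(f) = off_s * (baseline + slope_region * (f - ref_frequency)) + noise`,
#' with separate storage and loss slopes inside the ground-truth high-strain
#' region (`spec$hs_true`) and in the rest of the brain, and a lognormal
#' per-subject multiplier `off_s`. Storage stays positive and loss
#' non-negative in the mask; voxels outside the mask are `NA`.
#'
#' @param spec A [make_phantom()] specification.
#' @param frequencies At least two distinct frequencies in Hz.
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; defaults to the spec's.
#' @return List of [moduli_set()] objects, one per subject.
#' @export
simulate_moduli_cohort <- function(spec, frequencies = c(30, 50, 70),
                                   n_subjects = 2L, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(unique(frequencies)) < 2L)
    stop("at least 2 distinct frequencies are needed (slope undefined otherwise)",
      call. = FALSE
    )
  if (n_subjects < 1L) stop("n_subjects must be at least 1", call. = FALSE)
  g <- spec$grid_shape
  mask <- spec$brain_mask
  sl <- spec$dispersion_slopes
  s_slope <- array(sl[["storage_ls"]], g); s_slope[spec$hs_true] <- sl[["storage_hs"]]
  l_slope <- array(sl[["loss_ls"]], g); l_slope[spec$hs_true] <- sl[["loss_hs"]]

  lapply(seq_len(n_subjects), function(s) {
    with_seed(derive_seed(seed, stage = 3L, k = s), {
      off <- if (spec$subject_sigma > 0) exp(rnorm(1, 0, spec$subject_sigma)) else 1
      storage <- vector("list", length(frequencies))
      loss <- vector("list", length(frequencies))
      for (i in seq_along(frequencies)) {
        df <- frequencies[i] - spec$ref_frequency
        gp <- off * (spec$moduli_baseline[["storage"]] + s_slope * df)
        gpp <- off * (spec$moduli_baseline[["loss"]] + l_slope * df)
        if (spec$noise_sd$moduli > 0) {
          gp <- gp + spec$noise_sd$moduli * array(rnorm(prod(g)), g)
          gpp <- gpp + spec$noise_sd$moduli * array(rnorm(prod(g)), g)
          gp <- pmax(gp, 1e-3)
          gpp <- pmax(gpp, 0)
        }
        gp[!mask] <- NA_real_; gpp[!mask] <- NA_real_
        storage[[i]] <- gp; loss[[i]] <- gpp
      }
      ms <- moduli_set(frequencies, storage, loss)
      ms$subject <- s
      ms
    })
  })
}

#' Simulate control and mTBI apparent fiber density cohorts
#'
#' Control AFD is `baseline * off_s + voxel noise`; mTBI subjects are
#' identical except multiplied by `(1 - afd_deficit)` inside the ground-truth
#' high-strain voxels (`spec$hs_true`). The lognormal per-subject multipliers
#' `off_s` give raw between-subject variance exceeding the deficit, which is
#' what makes ratio normalisation to low-strain tissue necessary downstream.
#'
#' @param spec A [make_phantom()] specification.
#' @param n_control,n_mtbi Subjects per group (each >= 2).
#' @param seed Integer seed; defaults to the spec's.
#' @return An `afd_cohort`: list with `volumes` (3D arrays, `NA` outside the
#'   mask) and a tibble `manifest` (`subject_id`, `group`).
#' @export
simulate_afd_cohort <- function(spec, n_control = 20L, n_mtbi = 20L, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_control < 2L || n_mtbi < 2L)
    stop("each group needs at least 2 subjects", call. = FALSE)
  g <- spec$grid_shape
  mask <- spec$brain_mask
  groups <- c(rep("control", n_control), rep("mtbi", n_mtbi))
  deficit_map <- 1 - spec$afd_deficit * spec$hs_true

  volumes <- lapply(seq_along(groups), function(s) {
    with_seed(derive_seed(seed, stage = 4L, k = s), {
      off <- if (spec$subject_sigma > 0) exp(rnorm(1, 0, spec$subject_sigma)) else 1
      v <- array(spec$afd_baseline * off, g)
      if (groups[s] == "mtbi") v <- v * deficit_map
      if (spec$noise_sd$afd > 0) v <- v + spec$noise_sd$afd * array(rnorm(prod(g)), g)
      v[!mask] <- NA_real_
      v
    })
  })
  structure(
    list(
      volumes = volumes,
      manifest = tibble::tibble(
        subject_id = sprintf("%s%02d", ifelse(groups == "control", "c", "m"),
          c(seq_len(n_control), seq_len(n_mtbi))),
        group = groups
      )
    ),
    class = "afd_cohort"
  )
}
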