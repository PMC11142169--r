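#' @importFrom stats median rnorm runif sd setNames
NULL

# Ellipsoid indicator on a voxel grid: centre and semi-axes in voxel units.
ellipsoid_mask <- function(grid_shape, centre, semi_axes) {
  x <- seq_len(grid_shape[1]); y <- seq_len(grid_shape[2]); z <- seq_len(grid_shape[3])
  dx2 <- ((x - centre[1]) / semi_axes[1])^2
  dy2 <- ((y - centre[2]) / semi_axes[2])^2
  dz2 <- ((z - centre[3]) / semi_axes[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

phantom_defaults <- function() {
  list(
    voxel_size = 2, # mm
    oss_amplification = 2, # displacement-amplitude factor inside HS blobs
    moduli_baseline = c(storage = 2.2, loss = 1.0), # kPa at the reference frequency
    ref_frequency = 50, # Hz
    # kPa/Hz; high-strain tissue stiffens twice as fast with frequency as it
    # gains loss, low-strain tissue keeps the two rates equal
    dispersion_slopes = c(
      storage_hs = 0.02, storage_ls = 0.01,
      loss_hs = 0.01, loss_ls = 0.01
    ),
    afd_baseline = 0.5,
    afd_deficit = 0.1, # fractional AFD reduction in mTBI inside true-HS voxels
    subject_sigma = 0.05, # lognormal sd of per-subject global multipliers
    noise_sd = list(displacement = 0.0005, moduli = 0.05, afd = 0.02),
    wave = list(
      amplitude = 0.02, # mm, harmonic displacement amplitude
      wavelength_voxels = 12, # at the reference frequency
      reflection = 0, # optional counter-propagating wave (relative amplitude)
      direction_sd_deg = 10, # per-subject propagation-direction jitter
      amp_field_sd = 0.25, # sd of the per-subject log-amplitude field
      amp_field_scale = 3, # correlation length (voxels) of that field
      edge_sigma = 0.5 # smoothing (voxels) of the blob amplification edge
    )
  )
}

merge_overrides <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- merge_overrides(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Build a seeded voxel phantom specification
#'
#' Constructs the geometry and ground-truth parameters shared by the cohort
#' simulators: an ellipsoidal brain mask, two smooth ellipsoidal high-strain
#' blobs (one matched to occipital, one to lateral skull actuation) that
#' overlap partially, and the mechanical/diffusion parameters of the tissue.
#' The blob intersection (`hs_true`) is the ground-truth actuation-invariant
#' vulnerable region used by the moduli and AFD simulators.
#'
#' @param grid_shape Integer triple of grid dimensions; each must be >= 16.
#' @param seed Integer seed stored in the spec and consumed by the simulators.
#' @param overrides Named list overriding any default parameter (nested lists
#'   such as `wave` and `noise_sd` are merged element-wise).
#' @return A `phantom_spec` object: grid and masks plus all generator
#'   parameters (see [phantom_defaults] values in the source for units).
#' @examples
#' spec <- make_phantom(c(32, 32, 32), seed = 1)
#' sum(spec$hs_occipital & spec$hs_lateral) > 0
#' @export
make_phantom <- function(grid_shape = c(32L, 32L, 32L), seed = 1L, overrides = list()) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(is.na(grid_shape)))
    stop("grid_shape must be an integer triple", call. = FALSE)
  if (any(grid_shape < 16L))
    stop(sprintf(
      "grid %s is too small to host the brain mask plus two high-strain blobs; each dimension must be at least 16",
      paste(grid_shape, collapse = "x")
    ), call. = FALSE)
  p <- merge_overrides(phantom_defaults(), overrides)
  if (p$oss_amplification < 1)
    stop("oss_amplification must be >= 1", call. = FALSE)
  if (p$afd_deficit < 0 || p$afd_deficit >= 1)
    stop("afd_deficit must be in [0, 1)", call. = FALSE)

  centre <- (grid_shape + 1) / 2
  brain_mask <- ellipsoid_mask(grid_shape, centre, 0.44 * grid_shape)
  # axis convention: x = left-right, y = posterior-anterior, z = inferior-superior
  occ_centre <- centre + c(0, -0.18, 0) * grid_shape
  lat_centre <- centre + c(0.09, -0.12, 0) * grid_shape
  blob_axes <- c(0.18, 0.16, 0.16) * grid_shape
  hs_occipital <- ellipsoid_mask(grid_shape, occ_centre, blob_axes)
  hs_lateral <- ellipsoid_mask(grid_shape, lat_centre, blob_axes)

  if (any(hs_occipital & !brain_mask) || any(hs_lateral & !brain_mask))
    stop("high-strain blobs extend outside the brain mask; enlarge the grid", call. = FALSE)
  hs_true <- hs_occipital & hs_lateral
  overlap <- sum(hs_true) / min(sum(hs_occipital), sum(hs_lateral))
  if (sum(hs_true) == 0L)
    stop("occipital and lateral blobs do not intersect; enlarge the grid", call. = FALSE)

  structure(
    c(
      list(
        grid_shape = grid_shape, seed = as.integer(seed),
        brain_mask = brain_mask, hs_occipital = hs_occipital,
        hs_lateral = hs_lateral, hs_true = hs_true, overlap_fraction = overlap
      ),
      p
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> grid %s at %g mm, %d brain voxels\n",
    paste(x$grid_shape, collapse = "x"), x$voxel_size, sum(x$brain_mask)
  ))
  cat(sprintf(
    "  HS blobs: occipital %d, lateral %d, intersection %d voxels (overlap %.0f%% of smaller)\n",
    sum(x$hs_occipital), sum(x$hs_lateral), sum(x$hs_true), 100 * x$overlap_fraction
  ))
  cat(sprintf(
    "  amplification %g, AFD deficit %g, seed %d\n",
    x$oss_amplification, x$afd_deficit, x$seed
  ))
  invisible(x)
}

# Deterministic per-stage, per-subject seed derivation (kept below 2^31).
derive_seed <- function(seed, stage, k = 0L) {
  (as.numeric(seed) * 48271 + stage * 7919 + k * 104729) %% 2147483647 + 1
}
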