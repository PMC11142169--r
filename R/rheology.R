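#' Masked finite-difference gradient along one axis
#'
#' Differentiates a (possibly complex) 3D field using only in-mask voxels in
#' the stencil: 4th-order central differences where two in-mask neighbours
#' exist on each side, 2nd-order central with one neighbour per side,
#' one-sided differences at mask edges, and 0 for voxels isolated along the
#' axis. Out-of-mask voxels are `NA`.
#'
#' @param field 3D numeric or complex array.
#' @param mask Logical 3D array; voxels outside it never enter a stencil.
#' @param axis Axis (1, 2 or 3) along which to differentiate.
#' @param h Voxel spacing in mm along that axis.
#' @return Array of the same shape as `field`.
#' @keywords internal
masked_gradient <- function(field, mask, axis, h) {
  check_mask(mask)
  check_same_grid(field, mask, "field", "mask")
  vp1 <- neighbour(field, axis, 1L); vm1 <- neighbour(field, axis, -1L)
  vp2 <- neighbour(field, axis, 2L); vm2 <- neighbour(field, axis, -2L)
  mp1 <- neighbour(mask, axis, 1L, fill = FALSE)
  mm1 <- neighbour(mask, axis, -1L, fill = FALSE)
  mp2 <- neighbour(mask, axis, 2L, fill = FALSE)
  mm2 <- neighbour(mask, axis, -2L, fill = FALSE)

  g <- array(if (is.complex(field)) NA_complex_ else NA_real_, dim(field))
  use4 <- mask & mp1 & mm1 & mp2 & mm2 # 4th-order central
  use3f <- mask & mp1 & mm1 & mp2 & !mm2 # 3rd-order, biased forward
  use3b <- mask & mp1 & mm1 & mm2 & !mp2 # 3rd-order, biased backward
  use2 <- mask & mp1 & mm1 & !mp2 & !mm2 # plain central
  usef2 <- mask & mp1 & !mm1 & mp2 # 2nd-order one-sided forward
  usef1 <- mask & mp1 & !mm1 & !mp2 # 1st-order forward
  useb2 <- mask & mm1 & !mp1 & mm2
  useb1 <- mask & mm1 & !mp1 & !mm2
  use0 <- mask & !mp1 & !mm1

  g[use4] <- (-vp2[use4] + 8 * vp1[use4] - 8 * vm1[use4] + vm2[use4]) / (12 * h)
  g[use3f] <- (-2 * vm1[use3f] - 3 * field[use3f] + 6 * vp1[use3f] - vp2[use3f]) / (6 * h)
  g[use3b] <- (2 * vp1[use3b] + 3 * field[use3b] - 6 * vm1[use3b] + vm2[use3b]) / (6 * h)
  g[use2] <- (vp1[use2] - vm1[use2]) / (2 * h)
  g[usef2] <- (-3 * field[usef2] + 4 * vp1[usef2] - vp2[usef2]) / (2 * h)
  g[usef1] <- (vp1[usef1] - field[usef1]) / h
  g[useb2] <- (3 * field[useb2] - 4 * vm1[useb2] + vm2[useb2]) / (2 * h)
  g[useb1] <- (field[useb1] - vm1[useb1]) / h
  g[use0] <- 0
  g
}

# Component ordering used throughout for symmetric tensors stored as 6-planes.
TENSOR_COMPONENTS <- c("xx", "yy", "zz", "xy", "xz", "yz")

#' Strain tensor from a complex harmonic displacement field
#'
#' Computes the infinitesimal strain tensor `eps = (grad u + grad u^T) / 2`
#' voxelwise by finite differences in voxel space scaled by the voxel size.
#' Central differences are used in the mask interior and one-sided differences
#' at mask edges; voxels outside the mask never enter a stencil.
#'
#' @param u Complex (or numeric) 4D array `nx x ny x nz x 3`, the three
#'   displacement components in mm.
#' @param voxel_size Isotropic voxel edge length in mm; must be positive.
#' @param mask Logical 3D array. Defaults to the `mask` attribute of `u`, or
#'   everywhere `TRUE`.
#' @return A 4D complex array `nx x ny x nz x 6` of class `strain_tensor`,
#'   with the symmetric components ordered `xx, yy, zz, xy, xz, yz`.
#' @examples
#' u <- array(0+0i, c(8, 8, 8, 3))
#' eps <- strain_from_displacement(u, voxel_size = 2)
#' max(abs(eps)) # uniform field has zero strain
#' @export
strain_from_displacement <- function(u, voxel_size, mask = NULL) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number (mm)", call. = FALSE)
  if (length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("u must be an nx x ny x nz x 3 array of displacement components", call. = FALSE)
  if (is.null(mask)) mask <- attr(u, "mask")
  if (is.null(mask)) mask <- array(TRUE, dim(u)[1:3])
  check_mask(mask)
  ext <- vapply(1:3, function(ax) {
    idx <- which(apply(mask, ax, any))
    if (length(idx)) diff(range(idx)) + 1L else 0L
  }, integer(1))
  if (any(ext < 3L))
    stop("mask must span at least 3 voxels along every axis", call. = FALSE)

  u <- u * (1 + 0i) # promote numeric input
  grad <- vector("list", 9L) # grad[[(i-1)*3 + j]] = d u_i / d x_j
  for (i in 1:3) {
    ui <- array(u[, , , i], dim(u)[1:3])
    for (j in 1:3) grad[[(i - 1L) * 3L + j]] <- masked_gradient(ui, mask, j, voxel_size)
  }
  d <- dim(u)[1:3]
  eps <- array(NA_complex_, c(d, 6L))
  pair <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (k in seq_along(pair)) {
    i <- pair[[k]][1]; j <- pair[[k]][2]
    eps[, , , k] <- (grad[[(i - 1L) * 3L + j]] + grad[[(j - 1L) * 3L + i]]) / 2
  }
  structure(eps,
    class = "strain_tensor", components = TENSOR_COMPONENTS,
    voxel_size = voxel_size, mask = mask
  )
}

# Accept either the packed 6-component form or a full 3x3 tensor field;
# a full tensor is validated for symmetry before packing.
as_packed_tensor <- function(eps, tol = 1e-12) {
  d <- dim(eps)
  if (length(d) == 5L && all(d[4:5] == 3L)) {
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      delta <- max(abs(eps[, , , p[1], p[2]] - eps[, , , p[2], p[1]]), na.rm = TRUE)
      if (is.finite(delta) && delta > tol)
        stop(sprintf(
          "strain tensor is asymmetric: max |eps_ij - eps_ji| = %.3g exceeds %.3g",
          delta, tol
        ), call. = FALSE)
    }
    packed <- array(NA_complex_, c(d[1:3], 6L))
    idx <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
    for (k in seq_along(idx))
      packed[, , , k] <- eps[, , , idx[[k]][1], idx[[k]][2]]
    return(packed)
  }
  if (length(d) == 4L && d[4] == 6L) return(eps * (1 + 0i))
  stop("eps must be nx x ny x nz x 6 (xx,yy,zz,xy,xz,yz) or nx x ny x nz x 3 x 3",
    call. = FALSE
  )
}

#' Octahedral shear strain of a harmonic strain field
#'
#' For each voxel, the octahedral shear strain (OSS) is the maximum over the
#' oscillation cycle of
#' `(2/3) * sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)`, where `e_i` are the
#' eigenvalues of the real tensor `Re(eps * exp(i*phi))`. It summarises the
#' maximum shear strain at a voxel regardless of direction, and is computed
#' here through the equivalent deviatoric invariant
#' `(2/sqrt(3)) * sqrt(tr(dev(E)^2))`, maximised over `phase_samples`
#' uniformly spaced phases in `[0, pi)`.
#'
#' @param eps Strain field: `nx x ny x nz x 6` packed symmetric components or
#'   a full `nx x ny x nz x 3 x 3` array (validated for symmetry).
#' @param phase_samples Number of phases sampled over `[0, pi)`; at least 8.
#' @return 3D numeric array of OSS values (`NA` where the tensor is `NA`).
#' @export
octahedral_shear_strain <- function(eps, phase_samples = 16L) {
  if (!is.numeric(phase_samples) || phase_samples < 8L)
    stop("phase_samples must be at least 8", call. = FALSE)
  packed <- as_packed_tensor(eps)
  d <- dim(packed)[1:3]
  m <- matrix(packed, nrow = prod(d), ncol = 6L)
  # deviatoric part: subtract mean of the diagonal from diagonal components
  trc <- (m[, 1] + m[, 2] + m[, 3]) / 3
  m[, 1] <- m[, 1] - trc; m[, 2] <- m[, 2] - trc; m[, 3] <- m[, 3] - trc
  phases <- seq(0, pi, length.out = phase_samples + 1L)[seq_len(phase_samples)]
  best <- rep(0, nrow(m))
  for (phi in phases) {
    e <- Re(m * exp(1i * phi))
    ss <- e[, 1]^2 + e[, 2]^2 + e[, 3]^2 + 2 * (e[, 4]^2 + e[, 5]^2 + e[, 6]^2)
    best <- pmax(best, ss)
  }
  oss <- (2 / sqrt(3)) * sqrt(best)
  oss[is.na(m[, 1])] <- NA_real_
  array(oss, d)
}

#' Shear stiffness from storage and loss moduli
#'
#' Voxelwise scalar stiffness derived from the complex shear modulus
#' `G = G' + iG''`. The default is the inversion-literature convention
#' `mu = 2|G|^2 / (G' + |G|)`, which reduces to `G'` in the lossless limit;
#' `method = "magnitude"` returns `|G|` instead.
#'
#' @param storage,loss 3D arrays of storage modulus G' (must be positive where
#'   finite) and loss modulus G'' (non-negative), in kPa.
#' @param method Stiffness convention, `"inversion"` (default) or `"magnitude"`.
#' @return 3D array of stiffness in kPa.
#' @examples
#' shear_stiffness(array(3, c(2, 2, 2)), array(4, c(2, 2, 2)))[1] # 6.25 kPa
#' @export
shear_stiffness <- function(storage, loss, method = c("inversion", "magnitude")) {
  method <- match.arg(method)
  check_same_grid(storage, loss, "storage modulus", "loss modulus")
  if (any(storage <= 0, na.rm = TRUE))
    stop("storage modulus must be positive wherever defined", call. = FALSE)
  if (any(loss < 0, na.rm = TRUE))
    stop("loss modulus must be non-negative wherever defined", call. = FALSE)
  gmag <- sqrt(storage^2 + loss^2)
  out <- switch(method,
    inversion = 2 * gmag^2 / (storage + gmag),
    magnitude = gmag
  )
  structure(out, quantity = "stiffness_kpa")
}

#' Shear strain energy density
#'
#' `U = k * eps^2 / 2` voxelwise, with the stiffness `k` converted from kPa to
#' Pa so that `U` is in J/m^3.
#'
#' @param stiffness 3D array, kPa.
#' @param oss 3D array of octahedral shear strain (dimensionless, >= 0).
#' @return 3D array of energy density in J/m^3.
#' @examples
#' strain_energy(array(2, c(2, 2, 2)), array(0.01, c(2, 2, 2)))[1] # 0.1 J/m^3
#' @export
strain_energy <- function(stiffness, oss) {
  check_same_grid(stiffness, oss, "stiffness", "OSS")
  if (any(oss < 0, na.rm = TRUE))
    stop("OSS must be non-negative", call. = FALSE)
  structure(0.5 * (stiffness * 1000) * oss^2, quantity = "energy_j_per_m3")
}

#' Bundle per-frequency storage and loss modulus volumes
#'
#' @param frequencies Numeric vector of actuation frequencies in Hz.
#' @param storage,loss Lists of 3D arrays (kPa), one per frequency.
#' @return A `moduli_set` object.
#' @export
moduli_set <- function(frequencies, storage, loss) {
  if (length(frequencies) != length(storage) || length(frequencies) != length(loss))
    stop("frequencies, storage and loss must have equal length", call. = FALSE)
  for (i in seq_along(storage)[-1]) {
    check_same_grid(storage[[1]], storage[[i]], "storage[[1]]", sprintf("storage[[%d]]", i))
    check_same_grid(storage[[1]], loss[[i]], "storage[[1]]", sprintf("loss[[%d]]", i))
  }
  structure(
    list(frequencies = as.numeric(frequencies), storage = storage, loss = loss),
    class = "moduli_set"
  )
}

#' Frequency-dispersion slopes and dispersion index
#'
#' Fits, at every voxel, ordinary least-squares lines to the storage and loss
#' moduli as a function of actuation frequency. The dispersion index is the
#' ratio of the storage slope to the loss slope; values above 1 indicate a
#' region absorbing energy at a greater rate than it dissipates it. Voxels
#' with a non-positive loss slope get a missing index rather than an error.
#'
#' @param moduli A [moduli_set()] with at least two distinct frequencies.
#' @param log_frequency Fit against `log(f)` instead of `f` (default `FALSE`).
#' @return A list with 3D arrays `storage_slope`, `loss_slope` (kPa/Hz) and
#'   `index` (dimensionless, `NA` where the loss slope is not positive).
#' @export
dispersion_index <- function(moduli, log_frequency = FALSE) {
  if (!inherits(moduli, "moduli_set"))
    stop("moduli must be a moduli_set object", call. = FALSE)
  f <- moduli$frequencies
  if (length(unique(f)) < 2L)
    stop("dispersion slopes need at least 2 distinct frequencies", call. = FALSE)
  x <- if (log_frequency) log(f) else f
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  d <- dim(moduli$storage[[1]])
  s_slope <- array(0, d); l_slope <- array(0, d)
  for (i in seq_along(x)) {
    s_slope <- s_slope + xc[i] * moduli$storage[[i]]
    l_slope <- l_slope + xc[i] * moduli$loss[[i]]
  }
  s_slope <- s_slope / sxx
  l_slope <- l_slope / sxx
  index <- s_slope / l_slope
  index[!is.na(l_slope) & l_slope <= 0] <- NA_real_
  list(storage_slope = s_slope, loss_slope = l_slope, index = index)
}
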