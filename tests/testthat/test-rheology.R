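make_grid_u <- function(g = c(16, 16, 16)) array(0 + 0i, c(g, 3L))

test_that("a spatially uniform displacement field has zero strain", {
  u <- make_grid_u()
  u[, , , 1] <- 0.3 + 0.1i
  eps <- strain_from_displacement(u, voxel_size = 2)
  expect_equal(max(abs(eps)), 0)
})

test_that("a linear field gives the exact constant shear everywhere", {
  g <- c(16, 16, 16)
  u <- make_grid_u(g)
  ymm <- (seq_len(g[2]) - 1) * 2
  for (j in seq_len(g[2])) u[, j, , 1] <- 0.01 * ymm[j]
  eps <- strain_from_displacement(u, voxel_size = 2)
  exy <- Re(eps[, , , 4])
  expect_equal(range(exy), c(0.005, 0.005), tolerance = 1e-13)
  expect_equal(max(abs(Im(eps))), 0)
})

test_that("plane-wave strain matches the analytic amplitude within 1%", {
  g <- c(24, 24, 24)
  A <- 0.1; lam <- 16 * 2
  u <- make_grid_u(g)
  zmm <- (seq_len(g[3]) - 1) * 2
  for (k in seq_len(g[3])) u[, , k, 1] <- A * sin(2 * pi * zmm[k] / lam)
  eps <- strain_from_displacement(u, voxel_size = 2)
  expect_equal(max(abs(Re(eps[, , , 5]))), pi * A / lam, tolerance = 0.01)
})

test_that("strain is linear in the displacement field", {
  set.seed(1)
  g <- c(10, 10, 10)
  u1 <- array(rnorm(prod(g) * 3) + 1i * rnorm(prod(g) * 3), c(g, 3))
  u2 <- array(rnorm(prod(g) * 3) + 1i * rnorm(prod(g) * 3), c(g, 3))
  e1 <- strain_from_displacement(u1, 2)
  e2 <- strain_from_displacement(u2, 2)
  e12 <- strain_from_displacement(3 * u1 - 2i * u2, 2)
  expect_equal(as.vector(e12), as.vector(3 * e1 - 2i * e2), tolerance = 1e-12)
})

test_that("strain input validation catches bad voxel size and thin masks", {
  u <- make_grid_u()
  expect_error(strain_from_displacement(u, 0), "positive")
  thin <- array(FALSE, c(16, 16, 16)); thin[, , 8] <- TRUE
  expect_error(strain_from_displacement(u, 2, mask = thin), "3 voxels")
})

test_that("octahedral shear strain reproduces closed-form values", {
  t0 <- array(0 + 0i, c(1, 1, 1, 6))
  expect_equal(octahedral_shear_strain(t0)[1], 0)
  t1 <- t0; t1[1, 1, 1, 1] <- 0.01
  expect_equal(octahedral_shear_strain(t1)[1], (2 / 3) * sqrt(2) * 0.01, tolerance = 1e-12)
  t2 <- t0; t2[1, 1, 1, 4] <- 0.005
  expect_equal(octahedral_shear_strain(t2)[1], (2 / 3) * sqrt(1.5e-4), tolerance = 1e-12)
})

test_that("OSS is rotation invariant and matches the eigenvalue route", {
  set.seed(42)
  n <- 200
  packed <- random_packed_tensor(n, complex = TRUE)
  oss <- octahedral_shear_strain(packed)
  m <- matrix(packed, n, 6)
  for (v in seq_len(n)) {
    expect_equal(oss[v], oss_eigen_oracle(m[v, ]), tolerance = 1e-10)
  }
  R <- random_rotation()
  oss_rot <- octahedral_shear_strain(rotate_packed(packed, R))
  expect_equal(as.vector(oss_rot), as.vector(oss), tolerance = 1e-10)
})

test_that("OSS is invariant to a global phase of the harmonic tensor", {
  set.seed(7)
  packed <- random_packed_tensor(50, complex = TRUE)
  oss <- octahedral_shear_strain(packed, phase_samples = 64)
  # a shift by an exact multiple of the sampling step permutes the sampled
  # phases (modulo pi), so the maximum is reproduced exactly
  shifted <- packed * exp(1i * pi / 64 * 7)
  expect_equal(
    as.vector(octahedral_shear_strain(shifted, phase_samples = 64)),
    as.vector(oss),
    tolerance = 1e-10
  )
  # for a purely real tensor the phase sweep changes nothing
  re <- random_packed_tensor(50, complex = FALSE)
  expect_equal(
    as.vector(octahedral_shear_strain(re, phase_samples = 8)),
    as.vector(octahedral_shear_strain(re, phase_samples = 64)),
    tolerance = 1e-12
  )
})

test_that("asymmetric full tensors and bad phase counts are rejected", {
  full <- array(0 + 0i, c(2, 2, 2, 3, 3))
  full[, , , 1, 2] <- 0.01 # eps_xy != eps_yx
  expect_error(octahedral_shear_strain(full), "asymmetric")
  sym <- array(0 + 0i, c(2, 2, 2, 3, 3))
  sym[, , , 1, 2] <- sym[, , , 2, 1] <- 0.005
  expect_equal(octahedral_shear_strain(sym)[1], (2 / 3) * sqrt(1.5e-4), tolerance = 1e-12)
  expect_error(octahedral_shear_strain(sym, phase_samples = 4), "at least 8")
})

test_that("shear stiffness follows the inversion convention", {
  one <- function(x) array(x, c(1, 1, 1))
  expect_equal(shear_stiffness(one(2), one(0))[1], 2)
  expect_equal(shear_stiffness(one(3), one(4))[1], 6.25)
  expect_equal(shear_stiffness(one(1), one(1))[1], 4 / (1 + sqrt(2)), tolerance = 1e-12)
  expect_equal(shear_stiffness(one(3), one(4), method = "magnitude")[1], 5)
  expect_error(shear_stiffness(one(-1), one(0)), "positive")
  expect_error(shear_stiffness(one(1), one(-1)), "non-negative")
})

test_that("strain energy evaluates and scales as U = k eps^2 / 2", {
  one <- function(x) array(x, c(2, 2, 2))
  expect_equal(strain_energy(one(0), one(0.5))[1], 0)
  expect_equal(strain_energy(one(2), one(0.01))[1], 0.1)
  U1 <- strain_energy(one(2), one(0.01))
  expect_equal(strain_energy(one(6), one(0.01))[1], 3 * U1[1])
  expect_equal(strain_energy(one(2), one(0.02))[1], 4 * U1[1])
  expect_error(strain_energy(one(2), array(0.01, c(3, 3, 3))), "mismatch")
  expect_error(strain_energy(one(2), one(-0.1)), "non-negative")
})

test_that("dispersion slopes are exact on constructed linear moduli", {
  g <- c(4, 4, 4)
  f <- c(30, 50, 70)
  ms <- moduli_set(f,
    storage = lapply(f, function(x) array(1000 + 10 * x, g)),
    loss = lapply(f, function(x) array(200 + 5 * x, g))
  )
  di <- dispersion_index(ms)
  expect_equal(unique(as.vector(di$storage_slope)), 10, tolerance = 1e-10)
  expect_equal(unique(as.vector(di$loss_slope)), 5, tolerance = 1e-10)
  expect_equal(unique(as.vector(di$index)), 2, tolerance = 1e-10)
})

test_that("equal slopes give index 1 and zero loss slope flags missing", {
  g <- c(3, 3, 3)
  f <- c(30, 50, 70)
  ms <- moduli_set(f,
    storage = lapply(f, function(x) array(1 + 0.01 * x, g)),
    loss = lapply(f, function(x) array(0.5 + 0.01 * x, g))
  )
  expect_equal(unique(as.vector(dispersion_index(ms)$index)), 1, tolerance = 1e-12)
  flat <- moduli_set(f,
    storage = lapply(f, function(x) array(1 + 0.01 * x, g)),
    loss = lapply(f, function(x) array(0.5, g))
  )
  di <- dispersion_index(flat)
  expect_true(all(is.na(di$index)))
  expect_error(dispersion_index(moduli_set(c(50, 50),
    storage = list(array(1, g), array(1, g)),
    loss = list(array(1, g), array(1, g))
  )), "distinct")
})
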