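mask3 <- function(g = c(4, 4, 4)) array(TRUE, g)

test_that("z-normalisation matches the hand-computed n-1 standardisation", {
  m <- array(FALSE, c(3, 1, 1)); m[] <- TRUE
  v <- array(c(1, 2, 3), c(3, 1, 1))
  z <- znormalize(v, m)
  expect_equal(as.vector(z), c(-1, 0, 1))
  expect_equal(as.vector(znormalize(z, m)), c(-1, 0, 1), tolerance = 1e-12)
  expect_error(znormalize(array(5, c(3, 1, 1)), m), "constant")
})

test_that("out-of-mask voxels become missing after z-normalisation", {
  g <- c(4, 4, 4)
  m <- array(FALSE, g); m[2:3, 2:3, 2:3] <- TRUE
  set.seed(1)
  z <- znormalize(array(rnorm(prod(g)), g), m)
  expect_true(all(is.na(z[!m])))
  expect_equal(mean(z[m]), 0, tolerance = 1e-12)
  expect_equal(sd(z[m]), 1, tolerance = 1e-12)
})

test_that("the group t-map matches the closed-form one-sample t", {
  g <- c(1, 1, 1)
  zm <- lapply(c(1, 2, 3, 4), function(x) array(x, g))
  tm <- group_tmap(zm, mask3(g))
  expect_equal(tm$t[1], 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(tm$p[1], 2 * pt(-tm$t[1], df = 3), tolerance = 1e-12)
  expect_equal(tm$df, 3)
})

test_that("zero-variance voxels are flagged, sign flips negate t", {
  g <- c(2, 1, 1)
  zm <- lapply(c(1, 2, 3), function(x) {
    a <- array(0, g); a[1] <- x; a # voxel 2 constant zero
  })
  tm <- group_tmap(zm, mask3(g))
  expect_true(tm$zero_variance[2])
  expect_true(is.na(tm$t[2]))
  tneg <- group_tmap(lapply(zm, function(z) -z), mask3(g))
  expect_equal(tneg$t[1], -tm$t[1])
  expect_error(group_tmap(zm[1:2], mask3(g)), "3 subjects")
})

test_that("BH step-up matches its textbook evaluation", {
  r <- bh_fdr(c(0.001, 0.02, 0.03, 0.9), q = 0.05)
  expect_equal(r$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$p_threshold, 0.03)
  expect_equal(bh_fdr(rep(1, 5), 0.05)$p_threshold, 0)
  expect_true(bh_fdr(0.04, 0.05)$rejected)
  expect_false(bh_fdr(0.06, 0.05)$rejected)
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
  expect_error(bh_fdr(0.5, 1.5), "\\(0, 1\\)")
})

test_that("BH agrees with brute-force enumeration on random vectors", {
  set.seed(11)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- round(runif(m), 3)
    q <- runif(1, 0.01, 0.2)
    got <- bh_fdr(p, q)
    want <- bh_brute_oracle(p, q)
    expect_identical(got$rejected, want$rejected)
    expect_equal(got$p_threshold, want$p_threshold)
  }
})

test_that("region definition applies the t-and-FDR rule literally", {
  # 10-voxel map: one strong voxel among nulls
  g <- c(10, 1, 1)
  m <- mask3(g)
  set.seed(2)
  zm <- lapply(1:6, function(s) {
    a <- array(rnorm(10, 0, 1), g)
    a[1] <- 2 + rnorm(1, 0, 0.1) # consistent strong voxel
    a
  })
  tm <- group_tmap(zm, m)
  reg <- define_regions(tm, t_threshold = 4, q = 0.05)
  expect_true(reg$hs[1])
  expect_equal(sum(reg$hs), 1)
  expect_equal(reg$t_threshold, 4.0)
  expect_equal(reg$fdr_q, 0.05)
  expect_equal(reg$provenance[[1]]$t_threshold, 4.0)
  expect_equal(reg$provenance[[1]]$fdr_q, 0.05)
  expect_true(all(xor(reg$hs[m], reg$ls[m])))
})

test_that("an all-zero t-map yields an empty HS recorded as provenance warning", {
  g <- c(5, 1, 1)
  set.seed(3)
  zm <- lapply(1:4, function(s) array(rnorm(5, 0, 1e-6), g))
  tm <- group_tmap(zm, mask3(g))
  tm$t[] <- 0; tm$p[] <- 1
  reg <- define_regions(tm)
  expect_equal(sum(reg$hs), 0)
  expect_equal(sum(reg$ls), 5)
  expect_match(reg$provenance[[1]]$warning, "empty")
})

test_that("region intersection is idempotent and warns when disjoint", {
  g <- c(6, 1, 1)
  mk <- function(idx) {
    hs <- array(FALSE, g); hs[idx] <- TRUE
    structure(list(
      hs = hs, ls = array(TRUE, g) & !hs, t_threshold = 4, fdr_q = 0.05,
      provenance = list(list(source = "test"))
    ), class = "region_mask")
  }
  a <- mk(1:3)
  expect_equal(intersect_regions(a, a)$hs, a$hs)
  ab <- intersect_regions(a, mk(5:6))
  expect_equal(sum(ab$hs), 0)
  expect_match(ab$provenance[[3]]$warning, "empty")
  big <- structure(list(
    hs = array(FALSE, c(7, 1, 1)), ls = array(TRUE, c(7, 1, 1)),
    t_threshold = 4, fdr_q = 0.05, provenance = list()
  ), class = "region_mask")
  expect_error(intersect_regions(a, big), "mismatch")
})

test_that("LOO folds depend only on the training subjects (no leakage)", {
  spec <- make_phantom(c(20, 20, 20), seed = 6)
  co <- simulate_displacement_cohort(spec, "occipital", 50, 6, seed = 6)
  zm <- zmaps_of(co, spec)
  loo <- loo_crossvalidate(zm, spec$brain_mask)
  # recompute fold 3's regions from scratch with subject 3 absent entirely
  tm <- group_tmap(zm[-3], spec$brain_mask)
  reg <- define_regions(tm, 4, 0.05)
  hs_mean <- mean(zm[[3]][reg$hs], na.rm = TRUE)
  ls_mean <- mean(zm[[3]][reg$ls], na.rm = TRUE)
  expect_equal(loo$table$hs_mean[3], hs_mean, tolerance = 1e-10)
  expect_equal(loo$table$ls_mean[3], ls_mean, tolerance = 1e-10)
  expect_error(loo_crossvalidate(zm[1:3], spec$brain_mask), "4 subjects")
})

test_that("LOO recovers the phantom effect and reports tidy summaries", {
  spec <- make_phantom(c(20, 20, 20), seed = 13)
  co <- simulate_displacement_cohort(spec, "occipital", 50, 8, seed = 13)
  zm <- zmaps_of(co, spec)
  loo <- loo_crossvalidate(zm, spec$brain_mask)
  inc <- loo$table[!loo$table$excluded, ]
  expect_true(all(inc$hs_mean > inc$ls_mean))
  g <- glance(loo)
  expect_equal(g$n_folds, 8)
  expect_equal(g$frac_hs_gt_ls, 1)
  expect_lt(g$p_t_two, 0.01)
  expect_equal(nrow(tidy(loo)), 8)
})
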