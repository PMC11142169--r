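region_fixture <- function(g = c(6, 1, 1), hs_idx = 1:2) {
  hs <- array(FALSE, g); hs[hs_idx] <- TRUE
  structure(list(
    hs = hs, ls = array(TRUE, g) & !hs, t_threshold = 4, fdr_q = 0.05,
    provenance = list(list(source = "fixture"))
  ), class = "region_mask")
}

test_that("ROI AFD summaries compute means and the HS/LS ratio", {
  reg <- region_fixture()
  uni <- array(0.5, c(6, 1, 1))
  expect_equal(roi_afd_summary(uni, reg)$ratio, 1)
  v <- array(0.5, c(6, 1, 1)); v[1:2] <- 0.4
  s <- roi_afd_summary(v, reg)
  expect_equal(s$afd_hs, 0.4)
  expect_equal(s$afd_ls, 0.5)
  expect_equal(s$ratio, 0.8)
  empty <- region_fixture(hs_idx = integer(0))
  expect_error(roi_afd_summary(uni, empty), "empty")
})

cohort_fixture <- function(ctrl_d = c(0.1, -0.1, 0), mtbi_d = c(-0.5, -0.6, -0.4),
                           base = 1) {
  tibble::tibble(
    subject_id = sprintf("s%d", seq_len(length(ctrl_d) + length(mtbi_d))),
    group = rep(c("control", "mtbi"), c(length(ctrl_d), length(mtbi_d))),
    afd_ls = base,
    afd_hs = base + c(ctrl_d, mtbi_d)
  ) |>
    dplyr::mutate(ratio = .data$afd_hs / .data$afd_ls)
}

test_that("interaction ANOVA matches the hand-computed pooled t and F = t^2", {
  res <- interaction_anova(cohort_fixture())
  expect_equal(res$t_diff, 6.123724, tolerance = 1e-6)
  expect_equal(res$F, 37.5, tolerance = 1e-8)
  expect_equal(res$F, res$t_diff^2, tolerance = 1e-8)
  expect_equal(unname(res$cell_means["mtbi", "hs"]), 0.5)
  expect_lt(res$p, 0.01)
})

test_that("identical groups give a null interaction; relabeling is symmetric", {
  null_tab <- cohort_fixture(ctrl_d = c(0.1, -0.1, 0), mtbi_d = c(0.1, -0.1, 0))
  expect_lt(interaction_anova(null_tab)$F, 1e-20)
  tab <- cohort_fixture()
  flipped <- tab
  flipped$group <- ifelse(tab$group == "control", "mtbi", "control")
  expect_equal(interaction_anova(flipped)$F, interaction_anova(tab)$F, tolerance = 1e-10)
  too_small <- tab[tab$group == "mtbi" | tab$subject_id == "s1", ]
  expect_error(interaction_anova(too_small), "at least 2")
})

test_that("ANOVA F equals the squared two-sample t on random cohorts", {
  set.seed(99)
  for (i in 1:30) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    tab <- tibble::tibble(
      subject_id = sprintf("s%d", seq_len(n1 + n2)),
      group = rep(c("control", "mtbi"), c(n1, n2)),
      afd_hs = rnorm(n1 + n2, 0.5, 0.05),
      afd_ls = rnorm(n1 + n2, 0.5, 0.05)
    )
    res <- interaction_anova(tab)
    expect_equal(res$F, res$t_diff^2, tolerance = 1e-8)
  }
})

test_that("the directed contrast is one-tailed with the deficit-positive sign", {
  d <- directed_contrast(cohort_fixture())
  expect_equal(d$t, 6.123724, tolerance = 1e-6)
  expect_equal(d$p_one_tailed, pt(d$t, df = 4, lower.tail = FALSE), tolerance = 1e-12)
  # effect in the wrong direction: mTBI higher in HS
  wrong <- directed_contrast(cohort_fixture(mtbi_d = c(0.5, 0.6, 0.4)))
  expect_gt(wrong$p_one_tailed, 0.5)
})

test_that("directed-contrast p-values are uniform under the null", {
  spec <- make_phantom(c(16, 16, 16), seed = 21, overrides = list(afd_deficit = 0))
  reg <- truth_regions(spec)
  pvals <- vapply(1:100, function(r) {
    co <- simulate_afd_cohort(spec, 6, 6, seed = 5000 + r)
    directed_contrast(cohort_afd_table(co, reg))$p_one_tailed
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("ratio normalisation removes global per-subject scaling", {
  spec <- make_phantom(c(16, 16, 16), seed = 31)
  co <- simulate_afd_cohort(spec, 4, 4, seed = 31)
  reg <- truth_regions(spec)
  tab <- cohort_afd_table(co, reg)
  co2 <- co
  co2$volumes[[2]] <- co2$volumes[[2]] * 3.7 # rescale one subject globally
  tab2 <- cohort_afd_table(co2, reg)
  expect_equal(tab2$ratio, tab$ratio, tolerance = 1e-12)
  a1 <- interaction_anova(tab); a2 <- interaction_anova(tab2)
  expect_equal(a2$F_ratio, a1$F_ratio, tolerance = 1e-10)
  # the directed contrast on the ratio scale is unchanged too
  r1 <- tab; r1$afd_hs <- r1$ratio; r1$afd_ls <- 1
  r2 <- tab2; r2$afd_hs <- r2$ratio; r2$afd_ls <- 1
  expect_equal(directed_contrast(r2)$t, directed_contrast(r1)$t, tolerance = 1e-10)
})

test_that("binned analysis conserves voxels and keeps empty bins", {
  g <- c(8, 8, 8)
  set.seed(4)
  z <- array(rnorm(prod(g)), g)
  z[1:3] <- 6 # isolated extreme voxels leave interior bins empty
  mask <- array(TRUE, g)
  ctrl <- list(array(0.5, g)); mtbi <- list(array(0.45, g))
  bt <- binned_strain_injury(z, ctrl, mtbi, bin_width = 0.25, mask = mask)
  expect_equal(sum(bt$n_voxels), prod(g))
  expect_true(any(bt$n_voxels == 0))
  expect_true(all(is.na(bt$median_delta_afd[bt$n_voxels == 0])))
  expect_equal(unique(bt$bin_halfwidth), 0.125)
  expect_error(binned_strain_injury(z, ctrl, mtbi, bin_width = 0), "positive")
})

test_that("a deficit linear in strain gives a perfect rank-correlation trend", {
  g <- c(10, 10, 10)
  set.seed(5)
  z <- array(rnorm(prod(g)), g)
  mask <- array(TRUE, g)
  ctrl <- list(array(0.5, g))
  mtbi <- list(array(0.5 - 0.02 * (z - min(z)), g)) # delta rises linearly with z
  bt <- binned_strain_injury(z, ctrl, mtbi, bin_width = 0.25, mask = mask)
  expect_equal(attr(bt, "trend_rho"), 1, tolerance = 1e-12)
  g2 <- glance(bt)
  expect_equal(g2$trend_rho, 1, tolerance = 1e-12)
  expect_equal(g2$n_bins, nrow(bt))
})

test_that("paired HS/LS contrast reproduces the exact signed-rank p-value", {
  set.seed(8)
  vals <- tibble::tibble(ls_mean = rnorm(10), hs_mean = NA_real_)
  vals$hs_mean <- vals$ls_mean + runif(10, 0.1, 1) # all positive differences
  pc <- hs_ls_paired_contrast(vals, label = "energy")
  expect_equal(pc$p_w_two, 2 / 2^10, tolerance = 1e-12)
  expect_true(pc$wilcoxon_exact)
  expect_equal(pc$label, "energy")
  td <- tidy(pc)
  expect_equal(nrow(td), 2)
})

test_that("antisymmetric differences sit at the Wilcoxon null centre", {
  vals <- tibble::tibble(ls_mean = 0, hs_mean = c(0.4, 0.3, 0.2, 0.1, -0.4, -0.3, -0.2, -0.1))
  pc <- hs_ls_paired_contrast(vals)
  expect_gt(pc$p_w_two, 0.5)
  expect_gt(pc$p_t_two, 0.9)
})

test_that("paired-contrast degenerate inputs are rejected, zeros dropped", {
  zeros <- tibble::tibble(hs_mean = rep(1, 5), ls_mean = rep(1, 5))
  expect_error(hs_ls_paired_contrast(zeros), "zero")
  expect_error(
    hs_ls_paired_contrast(tibble::tibble(hs_mean = 1:3, ls_mean = 0:2)),
    "at least 4"
  )
  some_zero <- tibble::tibble(hs_mean = c(1, 2, 3, 4, 5), ls_mean = c(1, 1, 1, 1, 5))
  pc <- hs_ls_paired_contrast(some_zero)
  expect_equal(pc$n_zero_dropped, 2)
})

test_that("the Wilcoxon exact route matches full sign enumeration", {
  set.seed(17)
  for (n in c(5, 8, 10, 12)) {
    d <- round(rnorm(n), 3)
    while (any(duplicated(abs(d))) || any(d == 0)) d <- round(rnorm(n), 3)
    vals <- tibble::tibble(ls_mean = 0, hs_mean = d)
    if (n >= 4) {
      pc <- hs_ls_paired_contrast(vals)
      expect_equal(pc$p_w_two, wilcoxon_enum_oracle(d), tolerance = 1e-12)
    }
  }
})
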