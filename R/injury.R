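#' Mean AFD over high- and low-strain regions for one subject
#'
#' @param afd 3D array of apparent fiber density.
#' @param regions A `region_mask` with a non-empty HS set.
#' @return One-row tibble: `afd_hs`, `afd_ls`, `ratio` (`afd_hs / afd_ls`).
#' @export
roi_afd_summary <- function(afd, regions) {
  stopifnot(inherits(regions, "region_mask"))
  check_same_grid(afd, regions$hs, "AFD volume", "region mask")
  if (sum(regions$hs) == 0L)
    stop("high-strain region is empty; cannot summarise AFD", call. = FALSE)
  if (sum(regions$ls) == 0L)
    stop("low-strain region is empty; ratio normalisation is undefined", call. = FALSE)
  afd_hs <- mean(afd[regions$hs], na.rm = TRUE)
  afd_ls <- mean(afd[regions$ls], na.rm = TRUE)
  if (!is.finite(afd_ls) || afd_ls == 0)
    stop("mean AFD over the low-strain region is zero; ratio is degenerate", call. = FALSE)
  tibble::tibble(afd_hs = afd_hs, afd_ls = afd_ls, ratio = afd_hs / afd_ls)
}

#' Per-subject cohort table of region-wise AFD summaries
#'
#' Applies [roi_afd_summary()] to every subject of an AFD cohort, keeping the
#' group labels; this is the table consumed by [interaction_anova()] and
#' [directed_contrast()].
#'
#' @param cohort An `afd_cohort` from [simulate_afd_cohort()], or a list with
#'   `volumes` and a `manifest` tibble (`subject_id`, `group`).
#' @param regions A `region_mask`.
#' @return Tibble: `subject_id`, `group`, `afd_hs`, `afd_ls`, `ratio`.
#' @export
cohort_afd_table <- function(cohort, regions) {
  stopifnot(is.list(cohort), !is.null(cohort$volumes), !is.null(cohort$manifest))
  summaries <- purrr::map(cohort$volumes, roi_afd_summary, regions = regions)
  dplyr::bind_cols(cohort$manifest, dplyr::bind_rows(summaries))
}

check_cohort_table <- function(table) {
  needed <- c("subject_id", "group", "afd_hs", "afd_ls")
  if (!all(needed %in% names(table)))
    stop("cohort table needs columns subject_id, group, afd_hs, afd_ls", call. = FALSE)
  counts <- table(factor(table$group))
  if (length(counts) != 2L || any(counts < 2L))
    stop("cohort table needs exactly 2 groups with at least 2 subjects each", call. = FALSE)
  invisible(TRUE)
}

#' Mixed-design 2x2 region-by-group ANOVA on AFD
#'
#' Region (HS vs LS) is within-subject and group (e.g. mTBI vs control)
#' between-subject; the statistic of interest is the interaction. Two routes
#' are computed and cross-checked: the mixed ANOVA via [stats::aov()] with an
#' `Error(subject/region)` stratum, and the identity `F = t^2` where `t` is
#' the pooled two-sample t on per-subject `afd_hs - afd_ls` differences. The
#' same contrast on the ratio scale (`afd_hs / afd_ls`) is reported alongside.
#'
#' @param table Cohort tibble with `subject_id`, `group`, `afd_hs`, `afd_ls`
#'   (see [cohort_afd_table()]); both groups need >= 2 subjects.
#' @return A `strain_anova` object: interaction `F`, `p`, degrees of freedom,
#'   2x2 `cell_means`, the equivalent two-sample `t_diff`, ratio-scale
#'   `F_ratio`/`p_ratio`, and the per-stratum ANOVA table.
#' @export
interaction_anova <- function(table) {
  check_cohort_table(table)
  groups <- sort(unique(table$group))
  long <- tidyr::pivot_longer(
    dplyr::select(table, "subject_id", "group", "afd_hs", "afd_ls"),
    cols = c("afd_hs", "afd_ls"), names_to = "region", values_to = "afd"
  )
  long$region <- factor(sub("afd_", "", long$region), levels = c("hs", "ls"))
  long$group <- factor(long$group, levels = groups)
  long$subject_id <- factor(long$subject_id)

  fit <- stats::aov(afd ~ group * region + Error(subject_id / region), data = long)
  strata <- summary(fit)
  within <- NULL
  for (s in strata) {
    tab <- s[[1]]
    if (any(grepl("group:region", rownames(tab)))) within <- tab
  }
  if (is.null(within)) stop("could not locate the interaction stratum", call. = FALSE)
  row <- which(grepl("group:region", rownames(within)))
  F_int <- within[row, "F value"]
  p_int <- within[row, "Pr(>F)"]
  df1 <- within[row, "Df"]
  df2 <- within[nrow(within), "Df"]

  # independent route: two-sample pooled t on the within-subject differences
  d <- table$afd_hs - table$afd_ls
  tt <- stats::t.test(d[table$group == groups[1]], d[table$group == groups[2]],
    var.equal = TRUE
  )
  if (abs(F_int - unname(tt$statistic)^2) > 1e-6 * max(1, abs(F_int)))
    warning("ANOVA and t^2 routes disagree beyond tolerance", call. = FALSE)

  r <- table$afd_hs / table$afd_ls
  tr <- stats::t.test(r[table$group == groups[1]], r[table$group == groups[2]],
    var.equal = TRUE
  )
  cell_means <- matrix(
    c(
      mean(table$afd_hs[table$group == groups[1]]),
      mean(table$afd_ls[table$group == groups[1]]),
      mean(table$afd_hs[table$group == groups[2]]),
      mean(table$afd_ls[table$group == groups[2]])
    ),
    nrow = 2, byrow = TRUE, dimnames = list(groups, c("hs", "ls"))
  )
  structure(
    list(
      F = unname(F_int), p = unname(p_int), df = c(df1 = df1, df2 = df2),
      t_diff = unname(tt$statistic), cell_means = cell_means,
      F_ratio = unname(tr$statistic)^2, p_ratio = tr$p.value,
      groups = groups, n = unname(table(factor(table$group))),
      anova_table = strata
    ),
    class = "strain_anova"
  )
}

#' @export
print.strain_anova <- function(x, ...) {
  cat(sprintf(
    "<strain_anova> region x group interaction: F(%d, %d) = %.3f, p = %.3g\n",
    x$df[["df1"]], x$df[["df2"]], x$F, x$p
  ))
  print(round(x$cell_means, 4))
  invisible(x)
}

#' Directed contrast: differentially lower AFD in high-strain regions
#'
#' One-tailed two-sample pooled t on the per-subject `afd_hs - afd_ls`
#' differences, testing the directed hypothesis that the injured group's AFD
#' deficit is differentially larger in high-strain regions. The statistic is
#' positive when the deficit goes in the hypothesised direction
#' (control differences exceed injured-group differences).
#'
#' @inheritParams interaction_anova
#' @param control,injured Group labels; defaults `"control"` and the other
#'   level present.
#' @return Tibble: `t`, `df`, `p_one_tailed`.
#' @export
directed_contrast <- function(table, control = "control", injured = NULL) {
  check_cohort_table(table)
  groups <- unique(table$group)
  if (!control %in% groups)
    stop(sprintf("no group labelled \"%s\" in the table", control), call. = FALSE)
  if (is.null(injured)) injured <- setdiff(groups, control)
  d <- table$afd_hs - table$afd_ls
  tt <- stats::t.test(d[table$group == control], d[table$group == injured],
    var.equal = TRUE, alternative = "greater"
  )
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_one_tailed = tt$p.value
  )
}

#' Threshold-agnostic binned strain-injury analysis
#'
#' At each in-mask voxel the average control AFD minus the average injured
#' AFD gives the differential deficit `delta`. Voxels are assigned to
#' half-open bins `[lo, lo + width)` of the group-mean z-scored OSS spanning
#' its whole observed range; each bin's median `delta` is reported, with
#' empty bins retained as missing rather than dropped. The trend statistic is
#' the Spearman rank correlation (average ranks for ties) of median `delta`
#' against bin centre over non-empty bins.
#'
#' @param group_oss 3D array of z-scored OSS averaged across participants.
#' @param control_afds,mtbi_afds Lists of aligned per-subject AFD arrays.
#' @param bin_width Bin width in z units (default 0.25).
#' @param mask Logical analysis mask; defaults to finite `group_oss` voxels.
#' @return A `bin_table`: tibble (`bin_center`, `bin_halfwidth`, `n_voxels`,
#'   `median_delta_afd`) with `trend_rho` and `trend_p` attributes.
#' @export
binned_strain_injury <- function(group_oss, control_afds, mtbi_afds,
                                 bin_width = 0.25, mask = NULL) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive", call. = FALSE)
  if (is.null(mask)) mask <- is.finite(group_oss)
  check_mask(mask)
  for (v in c(control_afds, mtbi_afds)) check_same_grid(v, group_oss, "AFD volume", "group OSS")

  mean_vol <- function(vols) Reduce(`+`, vols) / length(vols)
  delta <- mean_vol(control_afds) - mean_vol(mtbi_afds)

  z <- group_oss[mask]
  dl <- delta[mask]
  lo0 <- min(z)
  k <- pmin(floor((z - lo0) / bin_width), floor((max(z) - lo0) / bin_width))
  kk <- seq(0L, max(k))
  centers <- lo0 + (kk + 0.5) * bin_width
  counts <- vapply(kk, function(i) sum(k == i), integer(1))
  medians <- vapply(kk, function(i) {
    if (any(k == i)) median(dl[k == i]) else NA_real_
  }, numeric(1))

  tab <- tibble::tibble(
    bin_center = centers, bin_halfwidth = bin_width / 2,
    n_voxels = counts, median_delta_afd = medians
  )
  ok <- !is.na(medians)
  if (sum(ok) >= 3L) {
    ct <- suppressWarnings(
      stats::cor.test(centers[ok], medians[ok], method = "spearman", exact = FALSE)
    )
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  } else {
    rho <- NA_real_; rho_p <- NA_real_
  }
  structure(tab, class = c("bin_table", class(tab)), trend_rho = rho, trend_p = rho_p)
}

#' Paired high-strain vs low-strain contrast across subjects
#'
#' Tests per-subject HS-region means against LS-region means for a quantity
#' such as z-OSS, strain energy, or the dispersion index. Returns both a
#' paired t-test and a Wilcoxon matched-pairs signed-rank test (exact for
#' n <= 25 without ties, normal approximation with continuity correction
#' otherwise; zero differences are dropped with their count reported), each
#' with a two-sided p and the one-sided p in the hypothesised HS > LS
#' direction.
#'
#' @param values Tibble (or data frame) with columns `hs_mean` and `ls_mean`,
#'   one row per subject; >= 4 finite pairs required.
#' @param label Quantity label, e.g. `"oss"`, `"energy"`, `"dispersion_index"`.
#' @return A `paired_contrast` object.
#' @export
hs_ls_paired_contrast <- function(values, label = "oss") {
  if (!all(c("hs_mean", "ls_mean") %in% names(values)))
    stop("values needs hs_mean and ls_mean columns", call. = FALSE)
  hs <- values$hs_mean; ls <- values$ls_mean
  ok <- is.finite(hs) & is.finite(ls)
  hs <- hs[ok]; ls <- ls[ok]
  if (length(hs) < 4L)
    stop("paired contrast needs at least 4 subjects with finite values", call. = FALSE)
  d <- hs - ls
  n_zero <- sum(d == 0)
  d_nz <- d[d != 0]
  if (length(d_nz) == 0L)
    stop("all paired differences are zero; contrast is degenerate", call. = FALSE)

  tt <- stats::t.test(d)
  t_stat <- unname(tt$statistic)
  df <- unname(tt$parameter)
  p_t_one <- stats::pt(t_stat, df, lower.tail = FALSE)

  exact <- length(d_nz) <= 25 && !any(duplicated(abs(d_nz)))
  wt2 <- suppressWarnings(stats::wilcox.test(d_nz, exact = exact, correct = TRUE))
  wt1 <- suppressWarnings(
    stats::wilcox.test(d_nz, exact = exact, correct = TRUE, alternative = "greater")
  )
  structure(
    list(
      label = label, n = length(d), n_zero_dropped = n_zero,
      t = t_stat, df = df, p_t_two = tt$p.value, p_t_one = p_t_one,
      W = unname(wt2$statistic), p_w_two = wt2$p.value, p_w_one = wt1$p.value,
      wilcoxon_exact = exact,
      mean_hs = mean(hs), mean_ls = mean(ls)
    ),
    class = "paired_contrast"
  )
}

#' @export
print.paired_contrast <- function(x, ...) {
  cat(sprintf(
    "<paired_contrast> %s, n = %d: paired t(%d) = %.3f (p = %.3g two-sided); Wilcoxon W = %g (p = %.3g%s)\n",
    x$label, x$n, x$df, x$t, x$p_t_two, x$W, x$p_w_two,
    if (x$wilcoxon_exact) ", exact" else ""
  ))
  invisible(x)
}
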