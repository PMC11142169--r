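#' Z-normalise a scalar volume within a mask
#'
#' Standardises the in-mask voxel values to mean 0 and sample standard
#' deviation 1 (n - 1 denominator), the within-subject normalisation applied
#' to OSS before any group-level statistics. Out-of-mask voxels become `NA`.
#'
#' @param vol 3D numeric array.
#' @param mask Logical 3D array with at least two in-mask voxels.
#' @return 3D array of z-scores (`NA` outside the mask).
#' @export
znormalize <- function(vol, mask) {
  check_mask(mask)
  check_same_grid(vol, mask, "volume", "mask")
  v <- vol[mask]
  if (sum(mask) < 2L) stop("mask must contain at least 2 voxels", call. = FALSE)
  s <- sd(v)
  if (!is.finite(s) || s == 0)
    stop("volume is constant within the mask; z-normalisation is degenerate",
      call. = FALSE
    )
  out <- array(NA_real_, dim(vol))
  out[mask] <- (v - mean(v)) / s
  out
}

#' Voxelwise one-sample group t-map
#'
#' At each in-mask voxel, tests the across-subject z-values against zero with
#' a one-sample t on `n - 1` degrees of freedom and a two-tailed p-value.
#' Voxels with zero across-subject variance are flagged (`zero_variance`) and
#' carry `NA` statistics rather than being silently dropped.
#'
#' @param zmaps List of >= 3 aligned 3D arrays (per-subject z-normalised
#'   volumes).
#' @param mask Logical 3D analysis mask.
#' @return A `tmap_vol`: list with 3D arrays `t`, `p`, `zero_variance`, plus
#'   `mask`, `n_subjects` and `df`.
#' @export
group_tmap <- function(zmaps, mask) {
  check_mask(mask)
  n <- length(zmaps)
  if (n < 3L) stop("group t-map needs at least 3 subjects", call. = FALSE)
  for (i in seq_len(n)) {
    check_same_grid(zmaps[[i]], mask, sprintf("zmaps[[%d]]", i), "mask")
  }
  X <- matrix(vapply(zmaps, function(z) z[mask], numeric(sum(mask))), nrow = sum(mask))
  m <- rowMeans(X)
  v <- rowSums((X - m)^2) / (n - 1)
  s <- sqrt(v)
  tt <- m / (s / sqrt(n))
  zero <- !is.na(s) & s == 0
  tt[zero] <- NA_real_
  pp <- 2 * stats::pt(-abs(tt), df = n - 1)

  t_arr <- array(NA_real_, dim(mask)); t_arr[mask] <- tt
  p_arr <- array(NA_real_, dim(mask)); p_arr[mask] <- pp
  z_arr <- array(FALSE, dim(mask)); z_arr[mask] <- zero
  structure(
    list(
      t = t_arr, p = p_arr, zero_variance = z_arr, mask = mask,
      n_subjects = n, df = n - 1
    ),
    class = "tmap_vol"
  )
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`: sort the p-values ascending, find the
#' largest `i` with `p_(i) <= i q / m`, and reject every p-value at or below
#' `p_(i)`. Implemented through [stats::p.adjust()]; also returns the
#' realised p-value threshold (0 when nothing is rejected).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in `(0, 1)`.
#' @return List with logical `rejected` and numeric `p_threshold`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  rejected <- stats::p.adjust(pvals, method = "BH") <= q
  list(
    rejected = rejected,
    p_threshold = if (any(rejected)) max(pvals[rejected]) else 0
  )
}

#' Define high- and low-strain regions from a group t-map
#'
#' High-strain (HS) voxels are those at or above `t_threshold` that also
#' survive Benjamini-Hochberg FDR at level `q` (two-tailed p-values; the HS
#' threshold itself takes the positive tail). All remaining in-mask voxels
#' form the low-strain (LS) set. Zero-variance voxels are excluded from the
#' FDR pool and fall into LS; their count is recorded. An empty HS set is
#' recorded as a warning in the provenance, not raised as an error.
#'
#' @param tmap A [group_tmap()] result.
#' @param t_threshold HS t-statistic threshold (default 4.0).
#' @param q FDR level (default 0.05).
#' @return A `region_mask`: logical `hs` and `ls` arrays plus the thresholds
#'   and a provenance list.
#' @export
define_regions <- function(tmap, t_threshold = 4.0, q = 0.05) {
  stopifnot(inherits(tmap, "tmap_vol"))
  valid <- tmap$mask & !tmap$zero_variance & !is.na(tmap$p)
  hs <- array(FALSE, dim(tmap$mask))
  p_threshold <- 0
  if (any(valid)) {
    fdr <- bh_fdr(tmap$p[valid], q)
    hs[valid] <- (tmap$t[valid] >= t_threshold) & fdr$rejected
    p_threshold <- fdr$p_threshold
  }
  ls <- tmap$mask & !hs
  prov <- list(
    source = "group_tmap", n_subjects = tmap$n_subjects,
    t_threshold = t_threshold, fdr_q = q, p_threshold = p_threshold,
    n_hs = sum(hs), n_ls = sum(ls), n_zero_variance = sum(tmap$zero_variance),
    warning = if (sum(hs) == 0L) "empty high-strain region" else NULL
  )
  structure(
    list(hs = hs, ls = ls, t_threshold = t_threshold, fdr_q = q, provenance = list(prov)),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf(
    "<region_mask> HS %d voxels, LS %d voxels (t >= %g, FDR q = %g)\n",
    sum(x$hs), sum(x$ls), x$t_threshold, x$fdr_q
  ))
  invisible(x)
}

#' Intersect two region masks across actuation conditions
#'
#' The actuation-invariant high-strain region: `hs = a$hs & b$hs`, with LS the
#' rest of the shared analysis mask. Provenance lists are concatenated; an
#' empty intersection is recorded there as a warning.
#'
#' @param a,b `region_mask` objects on the same grid.
#' @return A `region_mask`.
#' @export
intersect_regions <- function(a, b) {
  stopifnot(inherits(a, "region_mask"), inherits(b, "region_mask"))
  check_same_grid(a$hs, b$hs, "first region mask", "second region mask")
  mask <- (a$hs | a$ls) & (b$hs | b$ls)
  hs <- a$hs & b$hs
  ls <- mask & !hs
  prov <- c(a$provenance, b$provenance, list(list(
    source = "intersect_regions", n_hs = sum(hs), n_ls = sum(ls),
    warning = if (sum(hs) == 0L) "empty high-strain intersection" else NULL
  )))
  structure(
    list(
      hs = hs, ls = ls,
      t_threshold = max(a$t_threshold, b$t_threshold),
      fdr_q = min(a$fdr_q, b$fdr_q), provenance = prov
    ),
    class = "region_mask"
  )
}

#' Leave-one-out cross-validation of the strain-concentration regions
#'
#' For every fold, high/low-strain regions are defined from the group t-map of
#' the `n - 1` training subjects only (same thresholding rule as
#' [define_regions()]), and the left-out subject's mean z-OSS is extracted
#' over those regions. Folds whose training HS set is empty are flagged and
#' excluded from the paired statistics, with the count reported.
#'
#' @param zmaps List of >= 4 aligned per-subject z-OSS arrays.
#' @param mask Logical 3D analysis mask.
#' @param t_threshold,q Region-definition thresholds (defaults 4.0, 0.05).
#' @return A `loo_cv`: per-subject tibble (`subject`, `hs_mean`, `ls_mean`,
#'   `excluded`), the paired HS-vs-LS contrast ([hs_ls_paired_contrast()])
#'   over included folds, and `n_excluded`.
#' @export
loo_crossvalidate <- function(zmaps, mask, t_threshold = 4.0, q = 0.05) {
  check_mask(mask)
  n <- length(zmaps)
  if (n < 4L) stop("leave-one-out cross-validation needs at least 4 subjects", call. = FALSE)
  for (i in seq_len(n)) check_same_grid(zmaps[[i]], mask, sprintf("zmaps[[%d]]", i), "mask")

  X <- matrix(vapply(zmaps, function(z) z[mask], numeric(sum(mask))), nrow = sum(mask))
  s1 <- rowSums(X)
  s2 <- rowSums(X^2)
  rows <- purrr::map(seq_len(n), function(i) {
    n1 <- n - 1L
    m <- (s1 - X[, i]) / n1
    v <- pmax((s2 - X[, i]^2 - n1 * m^2) / (n1 - 1), 0)
    s <- sqrt(v)
    tt <- m / (s / sqrt(n1))
    zero <- !is.na(s) & s == 0
    tt[zero] <- NA_real_
    pp <- 2 * stats::pt(-abs(tt), df = n1 - 1)
    t_arr <- array(NA_real_, dim(mask)); t_arr[mask] <- tt
    p_arr <- array(NA_real_, dim(mask)); p_arr[mask] <- pp
    z_arr <- array(FALSE, dim(mask)); z_arr[mask] <- zero
    tm <- structure(
      list(t = t_arr, p = p_arr, zero_variance = z_arr, mask = mask,
        n_subjects = n1, df = n1 - 1),
      class = "tmap_vol"
    )
    reg <- define_regions(tm, t_threshold = t_threshold, q = q)
    if (sum(reg$hs) == 0L) {
      tibble::tibble(subject = i, hs_mean = NA_real_, ls_mean = NA_real_, excluded = TRUE)
    } else {
      tibble::tibble(
        subject = i,
        hs_mean = mean(zmaps[[i]][reg$hs], na.rm = TRUE),
        ls_mean = mean(zmaps[[i]][reg$ls], na.rm = TRUE),
        excluded = FALSE
      )
    }
  })
  table <- dplyr::bind_rows(rows)
  included <- dplyr::filter(table, !.data$excluded)
  contrast <- if (nrow(included) >= 4L) {
    hs_ls_paired_contrast(included, label = "oss")
  } else {
    NULL
  }
  structure(
    list(
      table = table, contrast = contrast,
      n_excluded = sum(table$excluded),
      t_threshold = t_threshold, fdr_q = q
    ),
    class = "loo_cv"
  )
}

#' @export
print.loo_cv <- function(x, ...) {
  inc <- dplyr::filter(x$table, !.data$excluded)
  cat(sprintf(
    "<loo_cv> %d folds (%d excluded); HS > LS in %d/%d left-out subjects\n",
    nrow(x$table), x$n_excluded, sum(inc$hs_mean > inc$ls_mean), nrow(inc)
  ))
  if (!is.null(x$contrast)) print(x$contrast)
  invisible(x)
}
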