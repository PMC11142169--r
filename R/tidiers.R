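#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn loo_crossvalidate `tidy()` returns the per-subject fold table.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.loo_cv <- function(x, ...) x$table

#' @describeIn loo_crossvalidate `glance()` returns a one-row summary with the
#'   paired statistics over included folds.
#' @export
glance.loo_cv <- function(x, ...) {
  inc <- dplyr::filter(x$table, !.data$excluded)
  base <- tibble::tibble(
    n_folds = nrow(x$table), n_excluded = x$n_excluded,
    frac_hs_gt_ls = if (nrow(inc)) mean(inc$hs_mean > inc$ls_mean) else NA_real_,
    t_threshold = x$t_threshold, fdr_q = x$fdr_q
  )
  if (is.null(x$contrast)) return(base)
  dplyr::bind_cols(base, tibble::tibble(
    paired_t = x$contrast$t, p_t_two = x$contrast$p_t_two,
    wilcoxon_W = x$contrast$W, p_w_two = x$contrast$p_w_two
  ))
}

#' @describeIn interaction_anova `tidy()` returns one row per effect
#'   (group, region, interaction) with F statistics where defined.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.strain_anova <- function(x, ...) {
  rows <- list()
  for (s in x$anova_table) {
    tab <- s[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_len(nrow(tab))) {
      if (terms[i] == "Residuals") next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = terms[i], df = tab[i, "Df"],
        statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"]
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' @describeIn interaction_anova `glance()` returns a one-row summary of the
#'   interaction on both the AFD and the ratio scale.
#' @export
glance.strain_anova <- function(x, ...) {
  tibble::tibble(
    F_interaction = x$F, p_interaction = x$p,
    df1 = x$df[["df1"]], df2 = x$df[["df2"]],
    t_diff = x$t_diff, F_ratio = x$F_ratio, p_ratio = x$p_ratio,
    n_group1 = x$n[1], n_group2 = x$n[2]
  )
}

#' @describeIn hs_ls_paired_contrast `tidy()` returns one row per test
#'   (paired t, Wilcoxon signed-rank).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.paired_contrast <- function(x, ...) {
  tibble::tibble(
    test = c("paired_t", "wilcoxon_signed_rank"),
    statistic = c(x$t, x$W),
    p.two.sided = c(x$p_t_two, x$p_w_two),
    p.one.sided = c(x$p_t_one, x$p_w_one)
  )
}

#' @describeIn hs_ls_paired_contrast `glance()` returns a one-row summary.
#' @export
glance.paired_contrast <- function(x, ...) {
  tibble::tibble(
    label = x$label, n = x$n, n_zero_dropped = x$n_zero_dropped,
    t = x$t, df = x$df, p_t_two = x$p_t_two,
    W = x$W, p_w_two = x$p_w_two, wilcoxon_exact = x$wilcoxon_exact,
    mean_hs = x$mean_hs, mean_ls = x$mean_ls
  )
}

#' @describeIn binned_strain_injury `glance()` returns the rank-correlation
#'   trend across non-empty bins.
#' @param x A `bin_table`.
#' @param ... Unused.
#' @export
glance.bin_table <- function(x, ...) {
  tibble::tibble(
    n_bins = nrow(x), n_nonempty = sum(!is.na(x$median_delta_afd)),
    trend_rho = attr(x, "trend_rho"), trend_p = attr(x, "trend_p")
  )
}

#' @describeIn run_pipeline `glance()` returns the pipeline's headline
#'   statistics as a one-row tibble.
#' @param x A `strain_pipeline`.
#' @param ... Unused.
#' @export
glance.strain_pipeline <- function(x, ...) {
  s <- x$stats
  tibble::as_tibble(s[vapply(s, function(v) is.numeric(v) && length(v) == 1L, logical(1))])
}
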