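#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_hline labs scale_fill_gradient2 coord_equal theme_minimal
#' @export
ggplot2::autoplot

slice_df <- function(arr, slice) {
  d <- dim(arr)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  m <- arr[, , slice]
  tibble::tibble(
    x = rep(seq_len(d[1]), times = d[2]),
    y = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(m)
  )
}

#' Plot an axial slice of a group t-map
#'
#' @param object A [group_tmap()] result.
#' @param slice Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmap_vol <- function(object, slice = NULL, ...) {
  df <- slice_df(object$t, slice)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
      na.value = "grey20", name = "t"
    ) +
    coord_equal() +
    labs(title = "Group strain-concentration t-map", x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot high/low-strain regions on an axial slice
#'
#' @param object A `region_mask`.
#' @param slice Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_mask <- function(object, slice = NULL, ...) {
  lab <- array(NA_real_, dim(object$hs))
  lab[object$ls] <- 0
  lab[object$hs] <- 1
  df <- slice_df(lab, slice)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2(low = "grey80", high = "firebrick", na.value = "grey20",
      name = "HS", limits = c(0, 1)
    ) +
    coord_equal() +
    labs(title = "High-strain (red) vs low-strain regions", x = NULL, y = NULL) +
    theme_minimal()
}

#' Paired HS vs LS means across leave-one-out folds
#'
#' @param object A [loo_crossvalidate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loo_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::filter(object$table, !.data$excluded),
    cols = c("hs_mean", "ls_mean"), names_to = "region", values_to = "z_oss"
  )
  df$region <- factor(sub("_mean", "", df$region), levels = c("ls", "hs"))
  ggplot(df, aes(x = .data$region, y = .data$z_oss, group = .data$subject)) +
    geom_line(alpha = 0.4) +
    geom_point() +
    labs(
      title = "Left-out subject mean z-OSS by training-set region",
      x = "region", y = "mean z-scored OSS"
    ) +
    theme_minimal()
}

#' Median differential AFD deficit by strain bin
#'
#' @param object A [binned_strain_injury()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bin_table <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$median_delta_afd))
  ggplot(df, aes(x = .data$bin_center, y = .data$median_delta_afd)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_line(colour = "grey60") +
    geom_point(aes(size = .data$n_voxels)) +
    labs(
      title = "Differential AFD deficit vs strain concentration",
      x = "z-scored OSS bin centre", y = "median control - mTBI AFD",
      size = "voxels"
    ) +
    theme_minimal()
}
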