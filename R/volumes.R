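#' @title Internal array helpers shared across the volume layer
#' @name volume-helpers
#' @keywords internal
NULL

# Shift an array along one axis by `by` voxels so that out[i] = a[i - by],
# padding with `fill`. Works for any number of dimensions and for logical,
# numeric or complex storage.
shift_arr <- function(a, axis, by, fill = 0) {
  d <- dim(a)
  if (is.null(d)) stop("shift_arr() expects an array", call. = FALSE)
  if (by == 0L) return(a)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) seq_len(n - by) else seq(1 - by, n)
  dst <- src + by
  ix <- rep(list(quote(expr = )), length(d))
  ix_src <- ix; ix_src[[axis]] <- src
  ix_dst <- ix; ix_dst[[axis]] <- dst
  piece <- do.call(`[`, c(list(a), ix_src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), ix_dst, list(piece)))
}

# Value of the neighbour `s` voxels ahead along `axis`: out[i] = a[i + s].
neighbour <- function(a, axis, s, fill = 0) shift_arr(a, axis, -s, fill = fill)

# Separable Gaussian smoothing of a 3D array (zero padding at the faces).
# Used for blob edges and for correlated subject-level noise fields; exact
# boundary behaviour is immaterial for both.
gaussian_smooth <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  for (axis in 1:3) {
    acc <- array(0, dim(arr))
    for (j in seq_along(k)) {
      s <- j - r - 1L
      acc <- acc + k[j] * neighbour(arr, axis, s)
    }
    arr <- acc
  }
  arr
}

check_same_grid <- function(a, b, what_a = "first volume", what_b = "second volume") {
  da <- dim(a)[1:3]
  db <- dim(b)[1:3]
  if (!identical(da, db)) {
    stop(sprintf(
      "grid mismatch: %s is %s but %s is %s",
      what_a, paste(da, collapse = "x"), what_b, paste(db, collapse = "x")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

check_mask <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("mask must be a logical 3D array", call. = FALSE)
  invisible(TRUE)
}

#' Dice overlap coefficient between two boolean volumes
#'
#' `2|A & B| / (|A| + |B|)`; returns `NA` when both sets are empty.
#'
#' @param a,b Logical arrays on the same grid.
#' @return A single number in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  check_same_grid(a, b, "a", "b")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
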