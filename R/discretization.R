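#' Discretize VOI intensities to d equispaced gray levels
#'
#' Maps every in-mask intensity to an integer level in `1..d` using
#' equispaced bins over a calibration range. With the default
#' `mode = "voi_minmax"` the range is the VOI's own min-max, so
#' `level(v) = 1 + floor(d * (I(v) - I_min) / (I_max - I_min))`, clamped to
#' `d` at the maximum. A constant VOI (zero intensity range) yields all
#' levels equal to 1 with a warning.
#'
#' @param voi a [extract_voi()] result.
#' @param d number of gray levels, an integer in `2..256` (the usual choice
#'   is a power of two between 8 and 256).
#' @param mode `"voi_minmax"` (per-data-set relative binning, default) or
#'   `"fixed_range"`.
#' @param fixed_range numeric length-2 `(lo, hi)`; required when
#'   `mode = "fixed_range"`. Intensities outside are clamped into the range.
#' @return Object of class `discretized_voi`: `levels` (integer, length `N`,
#'   aligned with the VOI scan order), `d`, `calibration` (the `(lo, hi)`
#'   range used), plus the grid geometry inherited from `voi`.
#' @export
discretize <- function(voi, d, mode = c("voi_minmax", "fixed_range"),
                       fixed_range = NULL) {
  mode <- match.arg(mode)
  if (length(voi$intensities) == 0L) stop("empty VOI")
  d <- as.integer(d)
  if (is.na(d) || d < 2L || d > 256L)
    stop("'d' must be an integer in 2..256")
  x <- voi$intensities
  if (mode == "voi_minmax") {
    lo <- min(x); hi <- max(x)
  } else {
    if (is.null(fixed_range) || length(fixed_range) != 2L ||
        fixed_range[2] <= fixed_range[1])
      stop("'fixed_range' must be (lo, hi) with hi > lo")
    lo <- fixed_range[1]; hi <- fixed_range[2]
    x <- pmin(pmax(x, lo), hi)
  }
  if (hi == lo) {
    warning("constant VOI: all voxels assigned gray level 1")
    levels <- rep(1L, length(x))
  } else {
    levels <- 1L + as.integer(floor(d * (x - lo) / (hi - lo)))
    levels[levels > d] <- d
  }
  structure(
    list(levels = levels, d = d, calibration = c(lo, hi),
         index_map = voi$index_map, grid_index = voi$grid_index,
         shape = voi$shape, spacing = voi$spacing),
    class = "discretized_voi")
}

#' @export
print.discretized_voi <- function(x, ...) {
  cat(sprintf("<discretized_voi> N = %d voxels, d = %d gray levels\n",
              length(x$levels), x$d))
  invisible(x)
}

# Full-grid integer level array with 0 marking out-of-mask voxels.
.level_grid <- function(dvoi) {
  g <- integer(prod(dvoi$shape))
  g[dvoi$grid_index] <- dvoi$levels
  g
}
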