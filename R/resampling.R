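#' Resampling target specification
#'
#' @param pixel_size in-plane pixel size `P` in mm.
#' @param slice_thickness slice thickness `T` in mm.
#' @return Object of class `resampling_spec`.
#' @export
resampling_spec <- function(pixel_size, slice_thickness) {
  if (pixel_size <= 0 || slice_thickness <= 0)
    stop("pixel size and slice thickness must be strictly positive")
  structure(list(pixel_size = pixel_size, slice_thickness = slice_thickness),
            class = "resampling_spec")
}

#' Default one-factor-at-a-time resampling grid
#'
#' Four pixel-size variants in `[0.58, 1.38]` mm (applied at the original
#' slice thickness) and six slice-thickness variants in `[1, 4]` mm (applied
#' at the original pixel size). Expanding a subject over this grid and
#' prepending the original yields 11 data sets per subject.
#'
#' @param pixel_sizes pixel-size variants, mm.
#' @param thicknesses slice-thickness variants, mm.
#' @return Object of class `resampling_grid`.
#' @export
resampling_grid <- function(pixel_sizes = c(0.58, 0.78, 1.17, 1.38),
                            thicknesses = c(1, 1.5, 2, 2.5, 3.5, 4)) {
  if (any(pixel_sizes <= 0) || any(thicknesses <= 0))
    stop("grid values must be strictly positive")
  structure(list(pixel_sizes = pixel_sizes, thicknesses = thicknesses),
            class = "resampling_grid")
}

# Continuous 0-based source indices of the output voxel centers along one
# axis, plus the output length. Output extent covers the input center range;
# out-of-support queries are clamped to the edge value.
.axis_targets <- function(n_in, sp_in, sp_out) {
  n_out <- ceiling((n_in - 1) * sp_in / sp_out - 1e-9) + 1
  s <- (seq_len(n_out) - 1) * sp_out / sp_in
  list(n = as.integer(n_out), src = pmin(pmax(s, 0), n_in - 1))
}

# Vectorized trilinear interpolation of a 3D array at the tensor grid of
# continuous 0-based indices sx/sy/sz (already clamped into range).
.trilinear_grid <- function(arr, sx, sy, sz) {
  d <- dim(arr)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  nxo <- length(sx); nyo <- length(sy); nzo <- length(sz)
  ix0 <- pmin(floor(sx), nx - 1); fx <- sx - ix0
  iy0 <- pmin(floor(sy), ny - 1); fy <- sy - iy0
  iz0 <- pmin(floor(sz), nz - 1); fz <- sz - iz0
  ix1 <- pmin(ix0 + 1, nx - 1)
  iy1 <- pmin(iy0 + 1, ny - 1)
  iz1 <- pmin(iz0 + 1, nz - 1)
  out <- numeric(nxo * nyo * nzo)
  for (cz in 0:1) {
    iz <- if (cz == 0) iz0 else iz1
    wz <- if (cz == 0) 1 - fz else fz
    for (cy in 0:1) {
      iy <- if (cy == 0) iy0 else iy1
      wy <- if (cy == 0) 1 - fy else fy
      for (cx in 0:1) {
        ix <- if (cx == 0) ix0 else ix1
        wx <- if (cx == 0) 1 - fx else fx
        lin <- rep(ix + 1, times = nyo * nzo) +
          rep(rep(iy * nx, each = nxo), times = nzo) +
          rep(iz * nx * ny, each = nxo * nyo)
        w <- rep(wx, times = nyo * nzo) *
          rep(rep(wy, each = nxo), times = nzo) *
          rep(wz, each = nxo * nyo)
        out <- out + w * arr[lin]
      }
    }
  }
  array(out, c(nxo, nyo, nzo))
}

#' Resample a volume to a target pixel size and slice thickness
#'
#' Trilinear interpolation on the voxel-center lattice; the output grid
#' shares the input origin, covers the input physical extent and clamps to
#' edge values outside the input support. Resampling to the volume's own
#' spacing reproduces it exactly (interpolation at lattice points).
#'
#' @param volume an [image_volume()].
#' @param spec a [resampling_spec()].
#' @return A new [image_volume()] with spacing
#'   `(pixel_size, pixel_size, slice_thickness)`.
#' @export
resample_volume <- function(volume, spec) {
  sp_out <- c(spec$pixel_size, spec$pixel_size, spec$slice_thickness)
  d <- dim(volume$values)
  if (any(sp_out > d * volume$spacing))
    stop("degenerate target: voxel coarser than the whole volume along an axis")
  ax <- .axis_targets(d[1], volume$spacing[1], sp_out[1])
  ay <- .axis_targets(d[2], volume$spacing[2], sp_out[2])
  az <- .axis_targets(d[3], volume$spacing[3], sp_out[3])
  vals <- .trilinear_grid(volume$values, ax$src, ay$src, az$src)
  image_volume(vals, sp_out, volume$origin)
}

#' Resample a VOI mask
#'
#' The binary mask is trilinearly interpolated as a 0/1 field and
#' re-binarized at 0.5 (`mask_mode = "linear_threshold"`, the default), or
#' sampled with nearest-neighbor lookup (`"nearest"`). Voxel count and
#' physical volume are recomputed on the new grid.
#'
#' @param mask a [voi_mask()].
#' @param spec a [resampling_spec()].
#' @param mask_mode `"linear_threshold"` or `"nearest"`.
#' @return A new [voi_mask()].
#' @export
resample_mask <- function(mask, spec,
                          mask_mode = c("linear_threshold", "nearest")) {
  mask_mode <- match.arg(mask_mode)
  sp_out <- c(spec$pixel_size, spec$pixel_size, spec$slice_thickness)
  d <- dim(mask$flags)
  if (any(sp_out > d * mask$spacing))
    stop("degenerate target: voxel coarser than the whole volume along an axis")
  ax <- .axis_targets(d[1], mask$spacing[1], sp_out[1])
  ay <- .axis_targets(d[2], mask$spacing[2], sp_out[2])
  az <- .axis_targets(d[3], mask$spacing[3], sp_out[3])
  if (mask_mode == "linear_threshold") {
    field <- .trilinear_grid(array(as.numeric(mask$flags), d),
                             ax$src, ay$src, az$src)
    flags <- field >= 0.5
  } else {
    ix <- round(ax$src) + 1; iy <- round(ay$src) + 1; iz <- round(az$src) + 1
    flags <- mask$flags[ix, iy, iz, drop = FALSE]
  }
  if (!any(flags)) stop("resampled mask is empty at the requested voxel size")
  voi_mask(array(flags, c(ax$n, ay$n, az$n)), sp_out, mask$origin)
}

#' Expand a subject across the one-factor-at-a-time resampling set
#'
#' Produces the original data set plus the pixel-size variants (at the
#' original slice thickness) and the slice-thickness variants (at the
#' original pixel size): 11 entries for the default grid.
#'
#' @param volume an [image_volume()].
#' @param mask the aligned [voi_mask()].
#' @param grid a [resampling_grid()].
#' @param mask_mode passed to [resample_mask()].
#' @return A list of entries `list(label, pixel_size, slice_thickness,
#'   volume, mask)`; the original is first, labelled `"original"`.
#' @export
expand_resampled_set <- function(volume, mask, grid = resampling_grid(),
                                 mask_mode = "linear_threshold") {
  p0 <- volume$spacing[1]
  t0 <- volume$spacing[3]
  specs <- c(
    lapply(grid$pixel_sizes, function(p) resampling_spec(p, t0)),
    lapply(grid$thicknesses, function(t) resampling_spec(p0, t)))
  out <- vector("list", length(specs) + 1L)
  out[[1]] <- list(label = "original", pixel_size = p0, slice_thickness = t0,
                   volume = volume, mask = mask)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    out[[i + 1L]] <- list(
      label = sprintf("P%.2f_T%.2f", sp$pixel_size, sp$slice_thickness),
      pixel_size = sp$pixel_size, slice_thickness = sp$slice_thickness,
      volume = resample_volume(volume, sp),
      mask = resample_mask(mask, sp, mask_mode = mask_mode))
  }
  out
}
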