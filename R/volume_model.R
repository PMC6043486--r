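#' Construct an image volume
#'
#' An `image_volume` is a 3D scalar grid with per-axis voxel spacing in mm.
#' The first two axes are the in-plane (pixel) axes, the third is the slice
#' axis, so `spacing` is `(P, P, T)` for pixel size `P` and slice thickness
#' `T`. Voxel indices are 0-based in world-coordinate arithmetic: the center
#' of voxel `(i, j, k)` sits at `origin + c(i, j, k) * spacing`.
#'
#' @param values 3D numeric array of intensities (HU-like; dimensionless for
#'   synthetic data).
#' @param spacing numeric length-3, voxel spacing in mm, all strictly
#'   positive.
#' @param origin numeric length-3, world coordinate of the first voxel
#'   center in mm.
#' @return An object of class `image_volume` with fields `values`, `spacing`,
#'   `origin`.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive finite numbers")
  if (!all(is.finite(values)))
    stop("volume values must be finite")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' Construct a VOI mask
#'
#' A `voi_mask` is a binary grid aligned with an [image_volume()]. Its voxel
#' count `N` and physical volume `voi_volume = N * P * P * T` are computed at
#' construction; the identity `voi_volume / (P * P * T) == N` is exact up to
#' floating-point rounding and is relied on throughout the package.
#'
#' @param flags 3D logical array (or 0/1 numeric; values > 0.5 are true).
#' @param spacing voxel spacing of the aligned volume, mm.
#' @param origin world coordinate of the first voxel center, mm.
#' @return Object of class `voi_mask` with fields `flags`, `spacing`,
#'   `origin`, `n_voxels`, `voi_volume`.
#' @export
voi_mask <- function(flags, spacing, origin = c(0, 0, 0)) {
  if (!is.array(flags) || length(dim(flags)) != 3L)
    stop("'flags' must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive numbers")
  if (!is.logical(flags)) {
    flags <- array(as.numeric(flags) > 0.5, dim = dim(flags))
  }
  n <- sum(flags)
  if (n < 1L) stop("empty VOI: mask has no true voxels")
  structure(
    list(flags = flags, spacing = as.numeric(spacing),
         origin = as.numeric(origin), n_voxels = as.integer(n),
         voi_volume = n * prod(spacing)),
    class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> N = %d voxels, volume %.1f mm^3\n",
              x$n_voxels, x$voi_volume))
  invisible(x)
}

#' Number of voxels inside a VOI
#'
#' @param mask a [voi_mask()].
#' @return Integer voxel count `N`.
#' @export
voxel_count <- function(mask) mask$n_voxels

#' Physical VOI volume in mm^3
#'
#' @param mask a [voi_mask()].
#' @return `N * P * P * T` in mm^3.
#' @export
voi_volume <- function(mask) mask$voi_volume

#' Read an image volume from a NIfTI file
#'
#' Spacing is taken from the header `pixdim`; the axis order is the NIfTI
#' on-disk order `(x, y, z)` with `z` the slice axis.
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3D scalar image.
#' @return An [image_volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("non-3D image: ", path, " has ", length(dim(a)), " dimensions")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in header of ", path)
  image_volume(a, sp)
}

#' Read a VOI mask from a NIfTI file
#'
#' @param path path to a NIfTI mask (uint8 0/1; float masks are binarized at
#'   0.5).
#' @param reference the [image_volume()] the mask belongs to; shapes must
#'   match.
#' @return A [voi_mask()] with `N` and `voi_volume` computed from the
#'   reference spacing.
#' @export
load_mask <- function(path, reference) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L) stop("non-3D mask: ", path)
  if (!identical(dim(a), dim(reference$values)))
    stop("mask shape (", paste(dim(a), collapse = "x"),
         ") does not match reference volume (",
         paste(dim(reference$values), collapse = "x"), ")")
  voi_mask(a, reference$spacing, reference$origin)
}

#' Write an image volume to NIfTI
#'
#' @param volume an [image_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a VOI mask to NIfTI (uint8)
#'
#' @param mask a [voi_mask()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$flags), dim = dim(mask$flags)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Extract the masked intensity set of a VOI
#'
#' Enumerates the in-mask voxel intensities in the fixed column-major scan
#' order (x fastest, then y, then z-major), keeping the linear and 3D grid
#' coordinates of every entry so that texture matrices can be built on the
#' original lattice.
#'
#' @param volume an [image_volume()].
#' @param mask a [voi_mask()] with the same grid shape.
#' @return Object of class `voi_extract`: `intensities` (length `N`),
#'   `index_map` (`N x 3` integer, 1-based grid coordinates), `grid_index`
#'   (linear indices), `shape`, `spacing`.
#' @export
extract_voi <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$flags)))
    stop("volume and mask shapes differ")
  idx <- which(mask$flags)
  structure(
    list(intensities = as.numeric(volume$values[idx]),
         index_map = arrayInd(idx, dim(mask$flags)),
         grid_index = idx,
         shape = dim(mask$flags),
         spacing = mask$spacing),
    class = "voi_extract")
}

#' @export
print.voi_extract <- function(x, ...) {
  cat(sprintf("<voi_extract> N = %d voxels on a %s grid\n",
              length(x$intensities), paste(x$shape, collapse = "x")))
  invisible(x)
}
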