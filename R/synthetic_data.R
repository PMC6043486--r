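# Synthetic stand-ins for the study data: textured ellipsoidal tumor VOIs
# with volumes spanning more than an order of magnitude, and a
# homogeneous-texture phantom VOI replicated across pseudo-scanners. The
# texture model is a Gaussian-smoothed white-noise random field -- the
# simplest stationary model in which the voxel-count and gray-level scaling
# laws of the feature panel can be exercised; it makes no claim of
# lung-tumor realism.

# Gaussian smoothing along one axis via a dense band-normalized kernel
# matrix (kernel truncated at 3 sigma and renormalized at the edges).
.smooth_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0.05) return(arr)
  d <- dim(arr)
  n <- d[axis]
  h <- max(1L, ceiling(3 * sigma_vox))
  off <- -h:h
  k <- exp(-off^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (o in seq_along(off)) {
    j <- seq_len(n) + off[o]
    ok <- j >= 1 & j <= n
    K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + k[o]
  }
  K <- K / rowSums(K)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  dp <- dim(a)
  a <- array(K %*% matrix(a, dp[1], dp[2] * dp[3]), dp)
  aperm(a, order(perm))
}

#' Generate a stationary correlated texture field
#'
#' White Gaussian noise smoothed with a separable Gaussian kernel whose
#' physical scale realizes the requested autocorrelation length (the
#' distance at which the field's Gaussian autocorrelation falls to
#' `exp(-1/2)`), then rescaled to the stated mean and standard deviation.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel spacing, mm.
#' @param corr_length autocorrelation length, mm.
#' @param mean,sd target field mean and standard deviation (`sd = 0` gives a
#'   constant field).
#' @param seed optional integer; if given, seeds the RNG for a fully
#'   deterministic field.
#' @return An [image_volume()].
#' @export
generate_texture_field <- function(shape, spacing, corr_length, mean = 0,
                                   sd = 1, seed = NULL) {
  if (any(shape < 1) || any(spacing <= 0) || corr_length <= 0 || sd < 0)
    stop("shape, spacing and correlation length must be positive")
  if (corr_length < max(spacing))
    warning("correlation length below voxel size: texture is unresolvable ",
            "along at least one axis")
  if (!is.null(seed)) set.seed(seed)
  f <- array(rnorm(prod(shape)), shape)
  # smoothing two kernels of scale s gives autocorrelation scale s*sqrt(2)
  sig_mm <- corr_length / sqrt(2)
  for (ax in 1:3) f <- .smooth_axis(f, sig_mm / spacing[ax], ax)
  if (sd == 0 || stats::sd(f) == 0) {
    f[] <- mean
  } else {
    f <- (f - base::mean(f)) / stats::sd(f) * sd + mean
  }
  image_volume(f, spacing)
}

#' Cohort specification for the synthetic tumor generator
#'
#' Defaults emulate the study conditions: 18 subjects with VOI volumes drawn
#' log-uniformly from 4-123 cm^3 on a 1.17 x 1.17 x 3 mm grid. Between-
#' subject heterogeneity enters through per-subject draws of the texture
#' correlation length, mean intensity and intensity SD, so that per-voxel
#' feature levels vary across subjects independently of VOI size.
#'
#' @param n_subjects number of subjects (default 18).
#' @param volume_range_cm3 VOI volume range, cm^3 (default `c(4, 123)`).
#' @param spacing base voxel spacing, mm (default `c(1.17, 1.17, 3)`).
#' @param corr_length_range per-subject texture correlation length range, mm.
#' @param mean_intensity population mean intensity (HU-like).
#' @param mean_sd between-subject SD of the mean intensity.
#' @param sd_range per-subject total intensity SD range (texture plus
#'   noise).
#' @param noise_fraction_range per-subject range of the fraction of
#'   intensity variance contributed by voxelwise white noise (CT image
#'   noise); drawn log-uniformly, so the cohort spans nearly-smooth to
#'   noise-dominated tumors.
#' @param axis_ratio_range ellipsoid semi-axis ratio range (avoids
#'   spheres-only degeneracy).
#' @param focal_rate expected number of focal components per tumor
#'   (calcification-like bright and necrosis/air-like dark inclusions),
#'   Poisson-distributed per subject.
#' @param focal_amplitude_range absolute intensity contrast range of focal
#'   components (HU-like; sign drawn at random).
#' @param focal_radius_frac focal component radius range as a fraction of
#'   the tumor's mean semi-axis (inclusion size scales with tumor size).
#' @param margin_voxels empty margin around the ellipsoid, voxels.
#' @param seed RNG seed fixing all randomness.
#' @param field_seed optional separate seed for the intensity fields;
#'   defaults to `seed + 7919`, so changing it alone changes the textures
#'   but not the mask geometry.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 18, volume_range_cm3 = c(4, 123),
                        spacing = c(1.17, 1.17, 3),
                        corr_length_range = c(3, 12),
                        mean_intensity = 45, mean_sd = 10,
                        sd_range = c(45, 60),
                        noise_fraction_range = c(0.05, 0.9),
                        axis_ratio_range = c(0.6, 1.4),
                        focal_rate = 1.5,
                        focal_amplitude_range = c(80, 350),
                        focal_radius_frac = c(0.15, 0.35),
                        margin_voxels = 4L, seed = 20180712,
                        field_seed = NULL) {
  if (n_subjects < 1) stop("need at least one subject")
  if (any(volume_range_cm3 <= 0)) stop("volumes must be positive")
  if (is.null(field_seed)) field_seed <- seed + 7919
  structure(list(n_subjects = as.integer(n_subjects),
                 volume_range_cm3 = volume_range_cm3, spacing = spacing,
                 corr_length_range = corr_length_range,
                 mean_intensity = mean_intensity, mean_sd = mean_sd,
                 sd_range = sd_range,
                 noise_fraction_range = noise_fraction_range,
                 axis_ratio_range = axis_ratio_range,
                 focal_rate = focal_rate,
                 focal_amplitude_range = focal_amplitude_range,
                 focal_radius_frac = focal_radius_frac,
                 margin_voxels = as.integer(margin_voxels),
                 seed = seed, field_seed = field_seed),
            class = "cohort_spec")
}

# Ellipsoid mask on a grid: voxel centers inside (x/a)^2+(y/b)^2+(z/c)^2<=1.
.ellipsoid_mask <- function(shape, spacing, semi_axes) {
  ctr <- (shape - 1) / 2 * spacing
  x2 <- ((seq_len(shape[1]) - 1) * spacing[1] - ctr[1])^2 / semi_axes[1]^2
  y2 <- ((seq_len(shape[2]) - 1) * spacing[2] - ctr[2])^2 / semi_axes[2]^2
  z2 <- ((seq_len(shape[3]) - 1) * spacing[3] - ctr[3])^2 / semi_axes[3]^2
  q <- outer(outer(x2, y2, "+"), z2, "+")
  array(q <= 1, shape)
}

#' Generate a synthetic tumor cohort
#'
#' Per subject, an ellipsoidal VOI whose analytic volume is drawn
#' log-uniformly from the configured range is embedded (with margin) in a
#' stationary textured field. The realized voxelized volume is within a few
#' percent of the analytic draw at the base spacing for all default volume
#' sizes.
#'
#' @param spec a [cohort_spec()].
#' @return List of subjects, each `list(id, volume, mask, analytic_volume_mm3,
#'   params)`; a manifest data.frame is attached as attribute `"manifest"`.
#' @export
generate_tumor_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  vr <- spec$volume_range_cm3 * 1000  # mm^3
  vols <- exp(runif(n, log(vr[1]), log(vr[2])))
  s1 <- runif(n, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
  s2 <- runif(n, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
  corr <- runif(n, spec$corr_length_range[1], spec$corr_length_range[2])
  mu <- rnorm(n, spec$mean_intensity, spec$mean_sd)
  sig <- runif(n, spec$sd_range[1], spec$sd_range[2])
  nfr <- exp(runif(n, log(spec$noise_fraction_range[1]),
                   log(spec$noise_fraction_range[2])))
  voxvol <- prod(spec$spacing)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (vols[i] / voxvol < 8)
      stop("subject volume too small to contain at least 8 voxels")
    cax <- (3 * vols[i] / (4 * pi * s1[i] * s2[i]))^(1 / 3)
    semi <- c(s1[i] * cax, s2[i] * cax, cax)
    shape <- ceiling(2 * semi / spec$spacing) + 2L * spec$margin_voxels
    flags <- .ellipsoid_mask(shape, spec$spacing, semi)
    sd_tex <- sig[i] * sqrt(1 - nfr[i])
    sd_noise <- sig[i] * sqrt(nfr[i])
    field <- generate_texture_field(shape, spec$spacing, corr[i],
                                    mean = mu[i], sd = sd_tex,
                                    seed = spec$field_seed + i)
    if (sd_noise > 0) {
      # CT-like image noise: correlated in-plane by the reconstruction
      # kernel (~0.6 pixel), independent across slices
      noise <- array(rnorm(prod(shape)), shape)
      noise <- .smooth_axis(.smooth_axis(noise, 0.6, 1), 0.6, 2)
      field$values <- field$values + noise / stats::sd(noise) * sd_noise
    }
    # focal components: flat-topped inclusions emulating calcifications
    # (bright) and necrotic/air pockets (dark), which stretch the tumor's
    # intensity range the way real lung lesions do
    n_focal <- stats::rpois(1, spec$focal_rate)
    if (n_focal > 0) {
      ctr <- (shape - 1) / 2 * spec$spacing
      xs <- (seq_len(shape[1]) - 1) * spec$spacing[1] - ctr[1]
      ys <- (seq_len(shape[2]) - 1) * spec$spacing[2] - ctr[2]
      zs <- (seq_len(shape[3]) - 1) * spec$spacing[3] - ctr[3]
      for (b in seq_len(n_focal)) {
        u <- runif(3, -0.7, 0.7)
        pos <- u * semi
        w <- runif(1, spec$focal_radius_frac[1], spec$focal_radius_frac[2]) *
          prod(semi)^(1 / 3)
        amp <- sample(c(-1, 1), 1) *
          runif(1, spec$focal_amplitude_range[1],
                spec$focal_amplitude_range[2])
        r4 <- outer(outer((xs - pos[1])^2, (ys - pos[2])^2, "+"),
                    (zs - pos[3])^2, "+")^2
        field$values <- field$values + amp * exp(-r4 / w^4)
      }
    }
    out[[i]] <- list(
      id = sprintf("S%02d", i),
      volume = field,
      mask = voi_mask(flags, spec$spacing),
      analytic_volume_mm3 = vols[i],
      params = list(semi_axes = semi, corr_length = corr[i], mean = mu[i],
                    sd = sig[i], noise_fraction = nfr[i]))
  }
  attr(out, "manifest") <- data.frame(
    id = vapply(out, `[[`, "", "id"),
    analytic_volume_mm3 = vols,
    realized_volume_mm3 = vapply(out, function(s) s$mask$voi_volume, 0),
    n_voxels = vapply(out, function(s) s$mask$n_voxels, 0L),
    corr_length = corr, mean = mu, sd = sig, noise_fraction = nfr,
    pixel_size = spec$spacing[1], slice_thickness = spec$spacing[3],
    seed = spec$seed)
  out
}

#' Generate phantom-like homogeneous texture scans
#'
#' One cuboidal VOI of (approximately) the requested physical volume per
#' pseudo-scanner, carved out of a shared stationary texture field.
#' Per-scanner differences are an additive intensity offset and voxelwise
#' white noise; with both perturbations at 0 the scans are identical.
#'
#' @param n_scanners number of pseudo-scanners (default 8).
#' @param voi_volume_cm3 VOI volume (default 14.2 cm^3).
#' @param spacing voxel spacing, mm (default `c(0.98, 0.98, 3)`).
#' @param corr_length texture correlation length, mm.
#' @param mean_intensity,intensity_sd shared field statistics.
#' @param scanner_offset_sd SD of the per-scanner additive offset.
#' @param scanner_noise_sd SD of the per-scanner voxelwise noise.
#' @param margin_voxels empty margin around the cuboid, voxels.
#' @param seed RNG seed.
#' @return List of scans, each `list(id, volume, mask)`.
#' @export
generate_phantom_scans <- function(n_scanners = 8, voi_volume_cm3 = 14.2,
                                   spacing = c(0.98, 0.98, 3),
                                   corr_length = 5, mean_intensity = 70,
                                   intensity_sd = 30, scanner_offset_sd = 5,
                                   scanner_noise_sd = 5, margin_voxels = 4L,
                                   seed = 20180712) {
  if (n_scanners < 1 || voi_volume_cm3 <= 0 || any(spacing <= 0))
    stop("invalid phantom parameters")
  set.seed(seed)
  voi_mm3 <- voi_volume_cm3 * 1000
  n_target <- round(voi_mm3 / prod(spacing))
  nz <- max(2L, round(voi_mm3^(1 / 3) / spacing[3]))
  nxy <- n_target / nz
  nx <- max(2L, round(sqrt(nxy)))
  ny <- max(2L, round(nxy / nx))
  shape <- c(nx, ny, nz) + 2L * margin_voxels
  base <- generate_texture_field(shape, spacing, corr_length,
                                 mean = mean_intensity, sd = intensity_sd)
  flags <- array(FALSE, shape)
  flags[margin_voxels + seq_len(nx), margin_voxels + seq_len(ny),
        margin_voxels + seq_len(nz)] <- TRUE
  mask <- voi_mask(flags, spacing)
  offsets <- rnorm(n_scanners, 0, scanner_offset_sd)
  out <- vector("list", n_scanners)
  for (k in seq_len(n_scanners)) {
    noise <- if (scanner_noise_sd > 0)
      array(rnorm(prod(shape), 0, scanner_noise_sd), shape)
    else array(0, shape)
    out[[k]] <- list(
      id = sprintf("SC%d", k),
      volume = image_volume(base$values + offsets[k] + noise, spacing),
      mask = mask)
  }
  out
}

#' Write a cohort to NIfTI pairs plus a manifest CSV
#'
#' @param cohort result of [generate_tumor_cohort()] or
#'   [generate_phantom_scans()].
#' @param dir output directory (created if missing).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort) {
    write_volume(s$volume, file.path(dir, paste0(s$id, "_volume.nii.gz")))
    write_mask(s$mask, file.path(dir, paste0(s$id, "_mask.nii.gz")))
  }
  manifest <- attr(cohort, "manifest")
  if (is.null(manifest)) {
    manifest <- data.frame(
      id = vapply(cohort, `[[`, "", "id"),
      n_voxels = vapply(cohort, function(s) s$mask$n_voxels, 0L))
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
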