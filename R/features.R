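# The 24-feature panel: 4 intensity-histogram features, 11 GLCM, 4 GLRLM,
# 1 GLSZM and 4 NGTDM features, plus the per-feature normalization tables.

.F24 <- c(
  "Intensity-TGV", "Intensity-Energy", "Intensity-Entropy",
  "Intensity-Contrast",
  "GLCM-Entropy", "GLCM-Sum Entropy", "GLCM-Difference Entropy",
  "GLCM-Sum Average", "GLCM-Difference Average", "GLCM-Dissimilarity",
  "GLCM-Sum Variance", "GLCM-Difference Variance", "GLCM-Mean",
  "GLCM-Contrast", "GLCM-Inverse Variance",
  "GLRLM-GLNU", "GLRLM-RLNU", "GLRLM-HGRE", "GLRLM-SRHGE",
  "GLSZM-HIE",
  "NGTDM-Contrast", "NGTDM-Complexity", "NGTDM-Coarseness",
  "NGTDM-Texture Strength")

#' The feature panel with its normalization rules
#'
#' One row per feature: the family it belongs to, the voxel-size
#' normalization rule (exactly one of multiply by N, divide by N, divide by
#' log N, or none; 10 features carry a rule), and the gray-level
#' normalization factor g(d) (a function of the discretization level count
#' d; 17 texture features carry a factor, with `"one"` meaning the feature
#' is in the gray-level panel but needs no rescaling). The table is plain
#' data and can be edited and passed back into the normalization functions.
#'
#' @return A data.frame with columns `name`, `family`, `voxel_norm_rule`
#'   (`"multiply_N"`, `"divide_N"`, `"divide_logN"`, `"none"`) and
#'   `gl_norm_factor` (`"one"`, `"d"`, `"d2"`, `"log2d"`, `"none"`).
#' @export
feature_definitions <- function() {
  def <- data.frame(
    name = .F24,
    family = c(rep("intensity", 4), rep("GLCM", 11), rep("GLRLM", 4),
               "GLSZM", rep("NGTDM", 4)),
    voxel_norm_rule = "none",
    gl_norm_factor = "none",
    stringsAsFactors = FALSE)
  rownames(def) <- def$name
  def[c("Intensity-TGV", "Intensity-Energy", "GLCM-Mean",
        "GLCM-Inverse Variance", "GLRLM-GLNU", "GLRLM-RLNU"),
      "voxel_norm_rule"] <- "divide_N"
  def[c("Intensity-Entropy", "Intensity-Contrast"),
      "voxel_norm_rule"] <- "divide_logN"
  def[c("NGTDM-Coarseness", "NGTDM-Texture Strength"),
      "voxel_norm_rule"] <- "multiply_N"
  def[c("GLCM-Entropy", "GLCM-Sum Entropy", "GLCM-Difference Entropy"),
      "gl_norm_factor"] <- "log2d"
  def[c("GLCM-Sum Average", "GLCM-Difference Average", "GLCM-Dissimilarity",
        "GLCM-Mean", "NGTDM-Complexity"),
      "gl_norm_factor"] <- "d"
  def[c("GLCM-Sum Variance", "GLCM-Contrast", "GLRLM-HGRE", "GLRLM-SRHGE",
        "GLSZM-HIE", "NGTDM-Contrast", "NGTDM-Texture Strength"),
      "gl_norm_factor"] <- "d2"
  def[c("GLRLM-GLNU", "NGTDM-Coarseness"), "gl_norm_factor"] <- "one"
  rownames(def) <- NULL
  def
}

.gl_factor_value <- function(code, d) {
  switch(code,
         one = 1,
         d = d,
         d2 = d^2,
         log2d = log2(d),
         none = 1,
         stop("unknown gray-level factor code: ", code))
}

.xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Intensity-histogram features
#'
#' Computes the four first-order features from the VOI intensities:
#' * Energy: `sum(I^2)` over all in-mask voxels;
#' * Entropy: Shannon entropy (bits) of the intensity histogram over
#'   `entropy_bins` equispaced bins spanning the VOI min-max;
#' * TGV (total gray-level variation): `sum |I(v) - I(u)|` over ordered
#'   in-mask 6-neighbor pairs `(v, u)`;
#' * Contrast: the VOI intensity range `max - min`.
#'
#' @param voi a [extract_voi()] result.
#' @param entropy_bins number of histogram bins for the entropy (default 64).
#' @return Named numeric vector of the four features.
#' @export
intensity_features <- function(voi, entropy_bins = 64) {
  x <- voi$intensities
  if (length(x) == 0L) stop("empty VOI")
  energy <- sum(x^2)
  contrast <- max(x) - min(x)
  if (contrast == 0) {
    entropy <- 0
  } else {
    lev <- suppressWarnings(discretize(voi, entropy_bins))$levels
    p <- tabulate(lev, nbins = entropy_bins) / length(lev)
    entropy <- -sum(.xlogx(p))
  }
  # TGV over the 3 axis directions; each unordered pair contributes twice
  grid <- array(NA_real_, voi$shape)
  grid[voi$grid_index] <- x
  tgv <- 0
  d <- voi$shape
  if (d[1] > 1) {
    a <- grid[-d[1], , , drop = FALSE]; b <- grid[-1, , , drop = FALSE]
    tgv <- tgv + sum(abs(a - b), na.rm = TRUE)
  }
  if (d[2] > 1) {
    a <- grid[, -d[2], , drop = FALSE]; b <- grid[, -1, , drop = FALSE]
    tgv <- tgv + sum(abs(a - b), na.rm = TRUE)
  }
  if (d[3] > 1) {
    a <- grid[, , -d[3], drop = FALSE]; b <- grid[, , -1, drop = FALSE]
    tgv <- tgv + sum(abs(a - b), na.rm = TRUE)
  }
  c("Intensity-TGV" = 2 * tgv, "Intensity-Energy" = energy,
    "Intensity-Entropy" = entropy, "Intensity-Contrast" = contrast)
}

#' GLCM features
#'
#' The 11 second-order features computed from a co-occurrence probability
#' matrix `p` and its sum/difference marginals: entropies in bits,
#' mean-centered sum/difference variances, and the usual contrast,
#' dissimilarity, mean and inverse-variance summaries. A single-level matrix
#' has no off-diagonal mass, so Inverse Variance is 0 there.
#'
#' @param m a [build_glcm()] result.
#' @return Named numeric vector of 11 features.
#' @export
glcm_features <- function(m) {
  p <- m$p
  d <- m$d
  i <- row(p); j <- col(p)
  ks <- as.numeric(names(m$p_sum))
  kd <- as.numeric(names(m$p_diff))
  sum_avg <- sum(ks * m$p_sum)
  diff_avg <- sum(kd * m$p_diff)
  off <- i != j
  inv_var <- if (any(p[off] > 0)) sum(p[off] / (i[off] - j[off])^2) else 0
  c("GLCM-Entropy" = -sum(.xlogx(p)),
    "GLCM-Sum Entropy" = -sum(.xlogx(m$p_sum)),
    "GLCM-Difference Entropy" = -sum(.xlogx(m$p_diff)),
    "GLCM-Sum Average" = sum_avg,
    "GLCM-Difference Average" = diff_avg,
    "GLCM-Dissimilarity" = sum(abs(i - j) * p),
    "GLCM-Sum Variance" = sum((ks - sum_avg)^2 * m$p_sum),
    "GLCM-Difference Variance" = sum((kd - diff_avg)^2 * m$p_diff),
    "GLCM-Mean" = sum(i * p),
    "GLCM-Contrast" = sum((i - j)^2 * p),
    "GLCM-Inverse Variance" = inv_var)
}

#' GLRLM features
#'
#' Gray level non-uniformity (GLNU), run length non-uniformity (RLNU), high
#' gray-level run emphasis (HGRE) and short-run high gray-level emphasis
#' (SRHGE), all normalized by the total run count.
#'
#' @param m a [build_glrlm()] result.
#' @return Named numeric vector of 4 features.
#' @export
glrlm_features <- function(m) {
  r <- m$r
  nr <- m$n_runs
  if (nr <= 0) stop("GLRLM features undefined: zero runs")
  i <- row(r); j <- col(r)
  c("GLRLM-GLNU" = sum(rowSums(r)^2) / nr,
    "GLRLM-RLNU" = sum(colSums(r)^2) / nr,
    "GLRLM-HGRE" = sum(r * i^2) / nr,
    "GLRLM-SRHGE" = sum(r * i^2 / j^2) / nr)
}

#' GLSZM features
#'
#' High intensity emphasis (HIE) on zones: `sum s(i, j) * i^2 / N_z`.
#'
#' @param m a [build_glszm()] result.
#' @return Named numeric vector of 1 feature.
#' @export
glszm_features <- function(m) {
  if (m$n_zones <= 0) stop("GLSZM features undefined: zero zones")
  i <- row(m$s)
  c("GLSZM-HIE" = sum(m$s * i^2) / m$n_zones)
}

#' NGTDM features
#'
#' Coarseness, Contrast, Complexity and Texture Strength computed from the
#' per-level occurrence probabilities `p_i` and neighborhood-difference sums
#' `s_i`. `eps` guards the reciprocals for homogeneous VOIs (where all
#' `s_i = 0`, Coarseness saturates at `1/eps`).
#'
#' @param m a [build_ngtdm()] result.
#' @param eps denominator guard (default `1e-6`).
#' @return Named numeric vector of 4 features.
#' @export
ngtdm_features <- function(m, eps = 1e-6) {
  occ <- which(m$p_i > 0)
  p <- m$p_i[occ]
  s <- m$s_i[occ]
  lev <- occ
  ngp <- length(occ)
  nv <- m$n_valid
  dif2 <- outer(lev, lev, function(a, b) (a - b)^2)
  contrast <- if (ngp > 1) {
    (sum(outer(p, p) * dif2) / (ngp * (ngp - 1))) * (sum(s) / nv)
  } else 0
  if (ngp > 1) {
    adif <- sqrt(dif2)
    num <- outer(p * s, p * s, "+")
    den <- outer(p, p, "+")
    complexity <- sum(adif * num / den) / nv
    strength <- sum(outer(p, p, "+") * dif2) / (eps + sum(s))
  } else {
    complexity <- 0
    strength <- 0
  }
  c("NGTDM-Contrast" = contrast,
    "NGTDM-Complexity" = complexity,
    "NGTDM-Coarseness" = 1 / (eps + sum(p * s)),
    "NGTDM-Texture Strength" = strength)
}

#' Extract the full 24-feature panel from a volume + mask
#'
#' Convenience wrapper: extracts the VOI, discretizes it to `d` gray levels,
#' builds the four texture matrices and evaluates all 24 features.
#'
#' @param volume an [image_volume()].
#' @param mask the aligned [voi_mask()].
#' @param d number of gray levels for the texture matrices (default 64).
#' @param entropy_bins histogram bins for Intensity-Entropy (default 64).
#' @return Named numeric vector of 24 features, with attributes `n_voxels`,
#'   `d`, `pixel_size`, `slice_thickness`.
#' @export
extract_features <- function(volume, mask, d = 64, entropy_bins = 64) {
  voi <- extract_voi(volume, mask)
  dvoi <- suppressWarnings(discretize(voi, d))
  vals <- c(intensity_features(voi, entropy_bins),
            glcm_features(build_glcm(dvoi)),
            glrlm_features(build_glrlm(dvoi)),
            glszm_features(build_glszm(dvoi)),
            ngtdm_features(build_ngtdm(dvoi)))
  vals <- vals[.F24]
  attr(vals, "n_voxels") <- mask$n_voxels
  attr(vals, "d") <- d
  attr(vals, "pixel_size") <- volume$spacing[1]
  attr(vals, "slice_thickness") <- volume$spacing[3]
  vals
}

#' Apply voxel-size normalization to a feature vector
#'
#' Rescales each feature by its rule from the definitions table: `f * N`,
#' `f / N` or `f / log(N)` (natural log). Features whose rule is `"none"`
#' pass through unchanged. `N` must exceed 1 whenever a `divide_logN`
#' feature is present.
#'
#' @param values named numeric feature vector (names as in
#'   [feature_definitions()]).
#' @param n_voxels the voxel count `N` of the data set.
#' @param defs definitions table (default [feature_definitions()]).
#' @return Named numeric vector of the same length and names.
#' @export
apply_voxel_normalization <- function(values, n_voxels,
                                      defs = feature_definitions()) {
  rules <- defs$voxel_norm_rule[match(names(values), defs$name)]
  rules[is.na(rules)] <- "none"
  if (any(rules == "divide_logN") && n_voxels <= 1)
    stop("voxel-size normalization by log(N) requires N > 1")
  out <- values
  out[rules == "multiply_N"] <- values[rules == "multiply_N"] * n_voxels
  out[rules == "divide_N"] <- values[rules == "divide_N"] / n_voxels
  out[rules == "divide_logN"] <- values[rules == "divide_logN"] / log(n_voxels)
  out
}

#' Apply gray-level normalization to a feature vector
#'
#' Divides each feature in the gray-level panel by its factor `g(d)` (1,
#' `d`, `d^2` or `log2(d)`); features outside the panel pass through.
#'
#' @param values named numeric feature vector.
#' @param d the gray-level count the features were extracted at.
#' @param defs definitions table (default [feature_definitions()]).
#' @return Named numeric vector of the same length and names.
#' @export
apply_gl_normalization <- function(values, d, defs = feature_definitions()) {
  if (d < 2) stop("gray-level normalization requires d >= 2")
  codes <- defs$gl_norm_factor[match(names(values), defs$name)]
  codes[is.na(codes)] <- "none"
  g <- vapply(codes, .gl_factor_value, numeric(1), d = d)
  values / g
}
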