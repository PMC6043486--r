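# Texture-matrix builders. All four operate on the discretized VOI laid out
# on its 3D grid, treat out-of-mask voxels as absent, and use the standard
# volumetric conventions: 13 unique lattice directions at Chebyshev distance
# 1 for GLCM pairs and GLRLM runs, 26-connectivity for GLSZM zones and NGTDM
# neighborhoods.

#' Build a gray level co-occurrence matrix (GLCM)
#'
#' Voxel pairs at Chebyshev distance 1 are counted along the 13 unique 3D
#' directions (both pair orders, i.e. the matrix is symmetrized). With
#' `aggregation = "average"` each direction's count matrix is normalized to
#' a probability matrix and the per-direction matrices are averaged; with
#' `"merge"` counts are pooled across directions before normalizing.
#'
#' @param dvoi a [discretize()]d VOI.
#' @param aggregation `"average"` (default) or `"merge"`.
#' @return Object of class `glcm`: `p` (d x d symmetric probability matrix,
#'   unit mass), `p_sum` (marginal of `i + j`, indexed `2..2d`), `p_diff`
#'   (marginal of `|i - j|`, indexed `0..d-1`), `d`.
#' @export
build_glcm <- function(dvoi, aggregation = c("average", "merge")) {
  aggregation <- match.arg(aggregation)
  d <- dvoi$d
  counts <- array(glcm_pair_counts_cpp(.level_grid(dvoi), as.integer(dvoi$shape), d),
                  c(d, d, 13))
  mass <- apply(counts, 3, sum)
  if (sum(mass) == 0)
    stop("GLCM undefined: VOI has no voxel pair at distance 1")
  if (aggregation == "average") {
    keep <- which(mass > 0)
    p <- matrix(0, d, d)
    for (k in keep) {
      s <- counts[, , k] + t(counts[, , k])
      p <- p + s / sum(s)
    }
    p <- p / length(keep)
  } else {
    s <- apply(counts, c(1, 2), sum)
    s <- s + t(s)
    p <- s / sum(s)
  }
  i <- row(p); j <- col(p)
  p_sum <- vapply(2:(2 * d), function(k) sum(p[i + j == k]), numeric(1))
  names(p_sum) <- 2:(2 * d)
  p_diff <- vapply(0:(d - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  names(p_diff) <- 0:(d - 1)
  structure(list(p = p, p_sum = p_sum, p_diff = p_diff, d = d),
            class = "glcm")
}

#' Build a gray level run length matrix (GLRLM)
#'
#' Maximal runs of equal level confined to the mask are collected along the
#' 13 unique 3D directions. With `aggregation = "sum"` (default) run counts
#' are summed over directions; `"average"` divides the summed counts by 13.
#'
#' @param dvoi a [discretize()]d VOI.
#' @param aggregation `"sum"` (default) or `"average"`.
#' @return Object of class `glrlm`: `r` (d x L run-count matrix, L the
#'   longest observed run), `n_runs` (total number of runs), `d`,
#'   `per_direction` (d x L x 13 raw counts).
#' @export
build_glrlm <- function(dvoi, aggregation = c("sum", "average")) {
  aggregation <- match.arg(aggregation)
  d <- dvoi$d
  lmax <- max(dvoi$shape)
  counts <- array(glrlm_run_counts_cpp(.level_grid(dvoi), as.integer(dvoi$shape), d),
                  c(d, lmax, 13))
  r <- apply(counts, c(1, 2), sum)
  if (aggregation == "average") r <- r / 13
  lkeep <- max(c(1L, which(colSums(r) > 0)))
  r <- r[, seq_len(lkeep), drop = FALSE]
  n_runs <- sum(r)
  if (n_runs == 0) stop("GLRLM undefined: no runs (empty VOI)")
  structure(list(r = r, n_runs = n_runs, d = d,
                 per_direction = counts[, seq_len(lkeep), , drop = FALSE]),
            class = "glrlm")
}

#' Build a gray level size zone matrix (GLSZM)
#'
#' Zones are 26-connected components of equal level within the mask.
#'
#' @param dvoi a [discretize()]d VOI.
#' @return Object of class `glszm`: `s` (d x Z zone-count matrix, Z the
#'   largest zone size), `n_zones`, `d`.
#' @export
build_glszm <- function(dvoi) {
  d <- dvoi$d
  zones <- glszm_zones_cpp(.level_grid(dvoi), as.integer(dvoi$shape))
  if (nrow(zones) == 0) stop("GLSZM undefined: empty VOI")
  zmax <- max(zones[, 2])
  s <- matrix(0, d, zmax)
  for (i in seq_len(nrow(zones)))
    s[zones[i, 1], zones[i, 2]] <- s[zones[i, 1], zones[i, 2]] + 1
  structure(list(s = s, n_zones = nrow(zones), d = d), class = "glszm")
}

#' Build a neighborhood gray tone difference matrix (NGTDM)
#'
#' For every in-mask voxel with at least one in-mask 26-neighbor, the
#' absolute difference between its level and the mean level of its in-mask
#' neighbors is accumulated into the per-level sum `s_i`; `p_i` is the
#' fraction of such voxels holding level `i`.
#'
#' @param dvoi a [discretize()]d VOI.
#' @return Object of class `ngtdm`: `n_i`, `p_i`, `s_i` (length-d vectors),
#'   `n_valid`, `d`.
#' @export
build_ngtdm <- function(dvoi) {
  d <- dvoi$d
  st <- ngtdm_stats_cpp(.level_grid(dvoi), as.integer(dvoi$shape), d)
  if (st$n_valid == 0)
    stop("NGTDM undefined: no voxel has an in-mask neighbor")
  structure(list(n_i = st$n, p_i = st$n / st$n_valid, s_i = st$s,
                 n_valid = st$n_valid, d = d),
            class = "ngtdm")
}
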