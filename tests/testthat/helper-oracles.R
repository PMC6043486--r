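# Brute-force oracles, written as plain double/triple loops independent of
# the package's compiled kernels, plus small fixture builders.

# The 13 unique lattice directions, in the package's documented order.
oracle_dirs <- function() {
  list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
       c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1),
       c(0, 1, -1),
       c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# Level pattern with no equal levels at Chebyshev distance 1: an
# 8-coloring by coordinate parities.
parity8_grid <- function(dims) {
  g <- array(0L, dims)
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2]))
    for (x in seq_len(dims[1]))
      g[x, y, z] <- 1L + (x %% 2L) + 2L * (y %% 2L) + 4L * (z %% 2L)
  g
}

in_grid <- function(p, dims) all(p >= 1) && all(p <= dims)

# Co-occurrence probability matrix: ordered pairs counted over both signs of
# each direction, normalized per direction and averaged over directions with
# mass (mirrors aggregation = "average").
oracle_glcm <- function(grid, d) {
  dims <- dim(grid)
  dirs <- oracle_dirs()
  acc <- matrix(0, d, d)
  used <- 0
  for (dir in dirs) {
    C <- matrix(0, d, d)
    for (z in seq_len(dims[3])) for (y in seq_len(dims[2]))
      for (x in seq_len(dims[1])) {
        g1 <- grid[x, y, z]
        if (g1 == 0) next
        for (sgn in c(1, -1)) {
          q <- c(x, y, z) + sgn * dir
          if (!in_grid(q, dims)) next
          g2 <- grid[q[1], q[2], q[3]]
          if (g2 == 0) next
          C[g1, g2] <- C[g1, g2] + 1
        }
      }
    if (sum(C) > 0) {
      acc <- acc + C / sum(C)
      used <- used + 1
    }
  }
  acc / used
}

# Run table per direction: walk every voxel back to its run start, then
# forward, marking visited positions.
oracle_glrlm <- function(grid, d) {
  dims <- dim(grid)
  dirs <- oracle_dirs()
  lmax <- max(dims)
  out <- array(0, c(d, lmax, length(dirs)))
  for (k in seq_along(dirs)) {
    dir <- dirs[[k]]
    visited <- array(FALSE, dims)
    for (z in seq_len(dims[3])) for (y in seq_len(dims[2]))
      for (x in seq_len(dims[1])) {
        if (visited[x, y, z]) next
        g <- grid[x, y, z]
        if (g == 0) next
        p <- c(x, y, z)
        while (TRUE) {
          q <- p - dir
          if (!in_grid(q, dims) || grid[q[1], q[2], q[3]] != g) break
          p <- q
        }
        len <- 0
        while (in_grid(p, dims) && grid[p[1], p[2], p[3]] == g) {
          visited[p[1], p[2], p[3]] <- TRUE
          len <- len + 1
          p <- p + dir
        }
        out[g, len, k] <- out[g, len, k] + 1
      }
  }
  out
}

# Zones by breadth-first flood fill over the 26-neighborhood.
oracle_glszm <- function(grid) {
  dims <- dim(grid)
  seen <- array(FALSE, dims)
  zones <- NULL
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2]))
    for (x in seq_len(dims[1])) {
      if (seen[x, y, z] || grid[x, y, z] == 0) next
      g <- grid[x, y, z]
      queue <- list(c(x, y, z))
      seen[x, y, z] <- TRUE
      size <- 0
      while (length(queue) > 0) {
        p <- queue[[1]]
        queue <- queue[-1]
        size <- size + 1
        for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
          if (ox == 0 && oy == 0 && oz == 0) next
          q <- p + c(ox, oy, oz)
          if (!in_grid(q, dims)) next
          if (!seen[q[1], q[2], q[3]] && grid[q[1], q[2], q[3]] == g) {
            seen[q[1], q[2], q[3]] <- TRUE
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
      zones <- rbind(zones, c(g, size))
    }
  zones
}

# Per-level occurrence counts and neighborhood-difference sums.
oracle_ngtdm <- function(grid, d) {
  dims <- dim(grid)
  n_i <- numeric(d)
  s_i <- numeric(d)
  nv <- 0
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2]))
    for (x in seq_len(dims[1])) {
      g <- grid[x, y, z]
      if (g == 0) next
      tot <- 0
      cnt <- 0
      for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
        if (ox == 0 && oy == 0 && oz == 0) next
        q <- c(x, y, z) + c(ox, oy, oz)
        if (!in_grid(q, dims)) next
        g2 <- grid[q[1], q[2], q[3]]
        if (g2 == 0) next
        tot <- tot + g2
        cnt <- cnt + 1
      }
      if (cnt == 0) next
      nv <- nv + 1
      n_i[g] <- n_i[g] + 1
      s_i[g] <- s_i[g] + abs(g - tot / cnt)
    }
  list(n = n_i, s = s_i, n_valid = nv)
}

# Trilinear interpolation at one continuous 0-based index (clamped).
oracle_trilinear <- function(arr, sx, sy, sz) {
  dims <- dim(arr)
  s <- pmin(pmax(c(sx, sy, sz), 0), dims - 1)
  i0 <- pmin(floor(s), dims - 2)
  i0[dims == 1] <- 0
  f <- s - i0
  val <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    idx <- pmin(i0 + c(cx, cy, cz), dims - 1) + 1
    w <- prod(ifelse(c(cx, cy, cz) == 1, f, 1 - f))
    val <- val + w * arr[idx[1], idx[2], idx[3]]
  }
  val
}

# Two-way ANOVA sums of squares written out longhand.
oracle_icc <- function(m) {
  n <- nrow(m)
  d <- ncol(m)
  grand <- sum(m) / (n * d)
  rm_ <- numeric(n)
  for (i in seq_len(n)) rm_[i] <- sum(m[i, ]) / d
  cm_ <- numeric(d)
  for (j in seq_len(d)) cm_[j] <- sum(m[, j]) / n
  ss_sub <- 0
  for (i in seq_len(n)) ss_sub <- ss_sub + d * (rm_[i] - grand)^2
  bms <- ss_sub / (n - 1)
  ss_res <- 0
  for (i in seq_len(n)) for (j in seq_len(d))
    ss_res <- ss_res + (m[i, j] - rm_[i] - cm_[j] + grand)^2
  rms <- ss_res / ((n - 1) * (d - 1))
  (bms - rms) / (bms + (d - 1) * rms)
}

# --- fixture builders -------------------------------------------------------

# A discretized VOI built directly from a level grid (0 = out of mask).
make_dvoi <- function(grid, d, spacing = c(1, 1, 1)) {
  idx <- which(grid > 0)
  structure(
    list(levels = as.integer(grid[idx]), d = as.integer(d),
         calibration = c(0, 1), index_map = arrayInd(idx, dim(grid)),
         grid_index = idx, shape = dim(grid), spacing = spacing),
    class = "discretized_voi")
}

random_level_grid <- function(shape = c(5, 5, 3), d = 5, p_mask = 0.8) {
  g <- array(sample.int(d, prod(shape), replace = TRUE), shape)
  g[runif(prod(shape)) > p_mask] <- 0L
  if (all(g == 0)) g[1] <- 1L
  g
}

make_voi <- function(values, flags, spacing = c(1, 1, 1)) {
  extract_voi(image_volume(values, spacing),
              voi_mask(flags, spacing))
}

rel_spread <- function(x) diff(range(x)) / mean(x)
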