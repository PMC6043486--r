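test_that("intensity features on degenerate and two-valued VOIs", {
  n <- 24
  voi <- make_voi(array(3, c(4, 3, 2)), array(TRUE, c(4, 3, 2)))
  f <- intensity_features(voi)
  expect_equal(f[["Intensity-Energy"]], n * 9)
  expect_equal(f[["Intensity-Entropy"]], 0)
  expect_equal(f[["Intensity-TGV"]], 0)
  expect_equal(f[["Intensity-Contrast"]], 0)

  # half a, half b: two equal-mass histogram bins give 1 bit of entropy
  vals <- array(rep(c(10, 50), each = 12), c(4, 3, 2))
  f2 <- intensity_features(make_voi(vals, array(TRUE, c(4, 3, 2))))
  expect_equal(f2[["Intensity-Entropy"]], 1)
  expect_equal(f2[["Intensity-Contrast"]], 40)
})

test_that("intensity energy, entropy and TGV match direct summation oracles", {
  set.seed(41)
  vals <- array(rnorm(60, 50, 10), c(5, 4, 3))
  flags <- array(runif(60) > 0.3, c(5, 4, 3)); flags[1] <- TRUE
  voi <- make_voi(vals, flags)
  f <- intensity_features(voi)
  x <- vals[flags]
  expect_equal(f[["Intensity-Energy"]], sum(x^2), tolerance = 1e-12)

  lo <- min(x); hi <- max(x)
  lev <- pmin(1 + floor(64 * (x - lo) / (hi - lo)), 64)
  p <- as.numeric(table(lev)) / length(x)
  expect_equal(f[["Intensity-Entropy"]], -sum(p * log2(p)), tolerance = 1e-12)

  # TGV: ordered in-mask 6-neighbor pairs
  tgv <- 0
  dims <- dim(vals)
  for (z in 1:dims[3]) for (y in 1:dims[2]) for (x_ in 1:dims[1]) {
    if (!flags[x_, y, z]) next
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
      q <- c(x_, y, z) + off
      if (any(q < 1) || any(q > dims)) next
      if (!flags[q[1], q[2], q[3]]) next
      tgv <- tgv + abs(vals[x_, y, z] - vals[q[1], q[2], q[3]])
    }
  }
  expect_equal(f[["Intensity-TGV"]], tgv, tolerance = 1e-10)
})

test_that("GLCM features on forced two-entry matrices and random instances", {
  const <- build_glcm(make_dvoi(array(3L, c(3, 3, 2)), 5))
  fc <- glcm_features(const)
  expect_equal(fc[["GLCM-Entropy"]], 0)
  expect_equal(fc[["GLCM-Contrast"]], 0)
  expect_equal(fc[["GLCM-Dissimilarity"]], 0)
  expect_equal(fc[["GLCM-Mean"]], 3)
  expect_equal(fc[["GLCM-Inverse Variance"]], 0)

  # perfectly alternating 1D pattern: all mass at p(1,2) = p(2,1) = 0.5
  alt <- array(rep(c(1L, 2L), 5), c(10, 1, 1))
  fa <- glcm_features(build_glcm(make_dvoi(alt, 2)))
  expect_equal(fa[["GLCM-Contrast"]], 1)
  expect_equal(fa[["GLCM-Dissimilarity"]], 1)
  expect_equal(fa[["GLCM-Entropy"]], 1)

  set.seed(42)
  for (rep in 1:5) {
    d <- sample(4:6, 1)
    g <- random_level_grid(c(5, 5, 3), d = d)
    m <- build_glcm(make_dvoi(g, d))
    f <- glcm_features(m)
    p <- m$p
    ent <- sa <- da <- dis <- con <- mea <- iv <- 0
    for (i in 1:d) for (j in 1:d) {
      if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
      dis <- dis + abs(i - j) * p[i, j]
      con <- con + (i - j)^2 * p[i, j]
      mea <- mea + i * p[i, j]
      if (i != j) iv <- iv + p[i, j] / (i - j)^2
    }
    ps <- numeric(2 * d); pd <- numeric(d)
    for (i in 1:d) for (j in 1:d) {
      ps[i + j] <- ps[i + j] + p[i, j]
      pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    }
    sa <- sum((1:(2 * d)) * ps); da <- sum((0:(d - 1)) * pd)
    sv <- sum(((1:(2 * d)) - sa)^2 * ps)
    dv <- sum(((0:(d - 1)) - da)^2 * pd)
    se <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
    de <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
    expect_equal(f[["GLCM-Entropy"]], ent, tolerance = 1e-10)
    expect_equal(f[["GLCM-Sum Entropy"]], se, tolerance = 1e-10)
    expect_equal(f[["GLCM-Difference Entropy"]], de, tolerance = 1e-10)
    expect_equal(f[["GLCM-Sum Average"]], sa, tolerance = 1e-10)
    expect_equal(f[["GLCM-Difference Average"]], da, tolerance = 1e-10)
    expect_equal(f[["GLCM-Dissimilarity"]], dis, tolerance = 1e-10)
    expect_equal(f[["GLCM-Sum Variance"]], sv, tolerance = 1e-10)
    expect_equal(f[["GLCM-Difference Variance"]], dv, tolerance = 1e-10)
    expect_equal(f[["GLCM-Mean"]], mea, tolerance = 1e-10)
    expect_equal(f[["GLCM-Contrast"]], con, tolerance = 1e-10)
    expect_equal(f[["GLCM-Inverse Variance"]], iv, tolerance = 1e-10)
  }
})

test_that("GLRLM features follow the run-table formulas", {
  # single run of level g, length L
  single <- structure(list(r = {
    r <- matrix(0, 5, 6); r[3, 6] <- 1; r
  }, n_runs = 1, d = 5), class = "glrlm")
  f <- glrlm_features(single)
  expect_equal(f[["GLRLM-GLNU"]], 1)
  expect_equal(f[["GLRLM-RLNU"]], 1)
  expect_equal(f[["GLRLM-HGRE"]], 9)
  expect_equal(f[["GLRLM-SRHGE"]], 9 / 36)

  # all runs of length 1, split evenly between two levels
  nr <- 40
  cb <- structure(list(r = {
    r <- matrix(0, 2, 3); r[1, 1] <- nr / 2; r[2, 1] <- nr / 2; r
  }, n_runs = nr, d = 2), class = "glrlm")
  fc <- glrlm_features(cb)
  expect_equal(fc[["GLRLM-RLNU"]], nr)
  expect_equal(fc[["GLRLM-GLNU"]], nr / 2)

  set.seed(43)
  g <- random_level_grid(c(5, 5, 3), d = 4)
  m <- build_glrlm(make_dvoi(g, 4))
  fr <- glrlm_features(m)
  glnu <- rlnu <- hgre <- srhge <- 0
  for (i in seq_len(nrow(m$r))) glnu <- glnu + sum(m$r[i, ])^2
  for (j in seq_len(ncol(m$r))) rlnu <- rlnu + sum(m$r[, j])^2
  for (i in seq_len(nrow(m$r))) for (j in seq_len(ncol(m$r))) {
    hgre <- hgre + m$r[i, j] * i^2
    srhge <- srhge + m$r[i, j] * i^2 / j^2
  }
  expect_equal(fr[["GLRLM-GLNU"]], glnu / m$n_runs, tolerance = 1e-10)
  expect_equal(fr[["GLRLM-RLNU"]], rlnu / m$n_runs, tolerance = 1e-10)
  expect_equal(fr[["GLRLM-HGRE"]], hgre / m$n_runs, tolerance = 1e-10)
  expect_equal(fr[["GLRLM-SRHGE"]], srhge / m$n_runs, tolerance = 1e-10)
})

test_that("GLSZM high intensity emphasis weights zones by squared level", {
  g <- array(4L, c(2, 2, 2))
  f <- glszm_features(build_glszm(make_dvoi(g, 5)))
  expect_equal(f[["GLSZM-HIE"]], 16)

  two <- structure(list(s = {
    s <- matrix(0, 3, 2); s[1, 1] <- 1; s[3, 2] <- 1; s
  }, n_zones = 2, d = 3), class = "glszm")
  expect_equal(glszm_features(two)[["GLSZM-HIE"]], (1 + 9) / 2)
})

test_that("NGTDM features match hand-evaluated formulas", {
  const <- build_ngtdm(make_dvoi(array(2L, c(2, 2, 2)), 3))
  f <- ngtdm_features(const)
  expect_equal(f[["NGTDM-Coarseness"]], 1e6)
  expect_equal(f[["NGTDM-Contrast"]], 0)
  expect_equal(f[["NGTDM-Complexity"]], 0)

  # 1x1x3 line (1,2,1): p = (2/3, 1/3), s = (2, 1), N_valid = 3
  line <- build_ngtdm(make_dvoi(array(c(1L, 2L, 1L), c(1, 1, 3)), 2))
  fl <- ngtdm_features(line, eps = 0)
  expect_equal(fl[["NGTDM-Contrast"]],
               (2 * (2 / 3) * (1 / 3) * 1 / (2 * 1)) * (3 / 3),
               tolerance = 1e-12)
  expect_equal(fl[["NGTDM-Complexity"]],
               2 * (1 * ((2 / 3) * 2 + (1 / 3) * 1) / 1) / 3,
               tolerance = 1e-12)
  expect_equal(fl[["NGTDM-Coarseness"]], 1 / (2 / 3 * 2 + 1 / 3 * 1),
               tolerance = 1e-12)
  expect_equal(fl[["NGTDM-Texture Strength"]], 2 * 1 / 3, tolerance = 1e-12)

  set.seed(44)
  g <- random_level_grid(c(5, 5, 3), d = 5)
  m <- build_ngtdm(make_dvoi(g, 5))
  fr <- ngtdm_features(m, eps = 1e-6)
  occ <- which(m$p_i > 0)
  co <- cx <- st_num <- 0
  for (i in occ) for (j in occ) {
    co <- co + m$p_i[i] * m$p_i[j] * (i - j)^2
    if (i != j)
      cx <- cx + abs(i - j) * (m$p_i[i] * m$s_i[i] + m$p_i[j] * m$s_i[j]) /
        (m$p_i[i] + m$p_i[j])
    st_num <- st_num + (m$p_i[i] + m$p_i[j]) * (i - j)^2
  }
  ngp <- length(occ)
  expect_equal(fr[["NGTDM-Contrast"]],
               co / (ngp * (ngp - 1)) * sum(m$s_i) / m$n_valid,
               tolerance = 1e-10)
  expect_equal(fr[["NGTDM-Complexity"]], cx / m$n_valid, tolerance = 1e-10)
  expect_equal(fr[["NGTDM-Coarseness"]],
               1 / (1e-6 + sum(m$p_i * m$s_i)), tolerance = 1e-10)
  expect_equal(fr[["NGTDM-Texture Strength"]],
               st_num / (1e-6 + sum(m$s_i)), tolerance = 1e-10)
})

test_that("the definitions table carries 24 features, 10 voxel rules, 17 GL factors", {
  defs <- feature_definitions()
  expect_identical(nrow(defs), 24L)
  expect_identical(sum(defs$voxel_norm_rule != "none"), 10L)
  expect_identical(sum(defs$gl_norm_factor != "none"), 17L)
  expect_identical(sum(defs$family == "GLCM" & defs$gl_norm_factor != "none"), 9L)
  expect_identical(sum(defs$family == "GLRLM" & defs$gl_norm_factor != "none"), 3L)
  expect_identical(sum(defs$family == "GLSZM" & defs$gl_norm_factor != "none"), 1L)
  expect_identical(sum(defs$family == "NGTDM" & defs$gl_norm_factor != "none"), 4L)
})

test_that("voxel-size normalization applies exactly one rule per feature", {
  vals <- c("GLRLM-GLNU" = 200, "NGTDM-Coarseness" = 0.5,
            "Intensity-Entropy" = 6, "GLCM-Contrast" = 3.14)
  out <- apply_voxel_normalization(vals, n_voxels = 100)
  expect_equal(out[["GLRLM-GLNU"]], 2)            # divide_N
  expect_equal(out[["NGTDM-Coarseness"]], 50)     # multiply_N
  expect_equal(out[["Intensity-Entropy"]], 6 / log(100))
  expect_identical(out[["GLCM-Contrast"]], vals[["GLCM-Contrast"]])

  # f = N for a divide_N feature cancels exactly at every N
  for (n in c(10, 1000, 54321))
    expect_equal(apply_voxel_normalization(c("Intensity-Energy" = n),
                                           n)[["Intensity-Energy"]], 1)

  expect_error(apply_voxel_normalization(c("Intensity-Entropy" = 1), 1),
               "N > 1")
})

test_that("voxel normalization flattens energy on a constant field across the grid", {
  vol <- image_volume(array(9, c(16, 16, 8)), c(1.17, 1.17, 3))
  flags <- array(FALSE, c(16, 16, 8)); flags[4:13, 4:13, 3:6] <- TRUE
  mask <- voi_mask(flags, vol$spacing)
  sets <- expand_resampled_set(vol, mask)
  expect_length(sets, 11)
  for (e in sets) {
    voi <- extract_voi(e$volume, e$mask)
    energy <- sum(voi$intensities^2)
    n <- e$mask$n_voxels
    norm <- apply_voxel_normalization(c("Intensity-Energy" = energy), n)
    expect_equal(norm[["Intensity-Energy"]], 81, tolerance = 1e-9)
  }
})

test_that("gray-level normalization divides by the declared factor of d", {
  vals <- c("GLCM-Entropy" = 12, "GLCM-Contrast" = 640, "GLCM-Mean" = 32,
            "GLRLM-GLNU" = 77, "Intensity-Energy" = 5)
  out <- apply_gl_normalization(vals, d = 64)
  expect_equal(out[["GLCM-Entropy"]], 12 / log2(64))
  expect_equal(out[["GLCM-Contrast"]], 640 / 64^2)
  expect_equal(out[["GLCM-Mean"]], 32 / 64)
  expect_identical(out[["GLRLM-GLNU"]], 77)       # factor one
  expect_identical(out[["Intensity-Energy"]], 5)  # outside the GL panel

  # maximal-entropy matrix: entropy 2*log2(d), so the normalized value is
  # constant in d
  for (d in c(8, 32, 256)) {
    h <- -sum(rep(1 / d^2, d^2) * log2(rep(1 / d^2, d^2)))
    nv <- apply_gl_normalization(c("GLCM-Entropy" = h), d)
    expect_equal(nv[["GLCM-Entropy"]], 2, tolerance = 1e-12)
  }
})

test_that("pass-through features are bit-identical under both normalizations", {
  set.seed(45)
  vals <- extract_features(
    image_volume(array(rnorm(14 * 14 * 6, 40, 20), c(14, 14, 6)),
                 c(1, 1, 2.5)),
    voi_mask(array(TRUE, c(14, 14, 6)), c(1, 1, 2.5)), d = 16)
  defs <- feature_definitions()
  vn <- apply_voxel_normalization(vals, attr(vals, "n_voxels"))
  keep <- defs$name[defs$voxel_norm_rule == "none"]
  expect_identical(unclass(vn)[keep], unclass(vals)[keep])
  gn <- apply_gl_normalization(vals, 16)
  keep2 <- defs$name[defs$gl_norm_factor %in% c("none", "one")]
  expect_identical(unclass(gn)[keep2], unclass(vals)[keep2])
})

test_that("voxel-count scaling laws hold on stationary fields", {
  # white-noise field: run statistics are stable under resampling
  set.seed(46)
  noise <- image_volume(array(rnorm(40 * 40 * 16, 100, 30), c(40, 40, 16)),
                        c(1.17, 1.17, 3))
  flags <- array(FALSE, c(40, 40, 16)); flags[5:36, 5:36, 3:14] <- TRUE
  mask <- voi_mask(flags, noise$spacing)
  sets <- expand_resampled_set(noise, mask)
  vals <- sapply(sets, function(e) {
    v <- extract_features(e$volume, e$mask, d = 64)
    n <- attr(v, "n_voxels")
    c(N = n, E = v[["Intensity-Energy"]], G = v[["GLRLM-GLNU"]],
      R = v[["GLRLM-RLNU"]])
  })
  n <- vals["N", ]
  for (row in c("E", "G", "R")) {
    expect_gt(cor(n, vals[row, ], method = "spearman"), 0.95)
  }
  expect_lt(rel_spread(vals["E", ] / n), 0.05)
  expect_lt(rel_spread(vals["R", ] / n), 0.10)
  expect_lt(rel_spread(vals["G", ] / n), 0.30)
  # normalization flattens by an order of magnitude
  expect_gt(rel_spread(vals["E", ]) / rel_spread(vals["E", ] / n), 10)

  # smooth field: normalized energy is nearly exactly conserved
  smooth <- generate_texture_field(c(40, 40, 16), c(1.17, 1.17, 3),
                                   corr_length = 8, mean = 100, sd = 20,
                                   seed = 46)
  sets2 <- expand_resampled_set(smooth, mask)
  e2 <- sapply(sets2, function(e) {
    v <- extract_features(e$volume, e$mask, d = 64)
    v[["Intensity-Energy"]] / attr(v, "n_voxels")
  })
  expect_lt(rel_spread(e2), 0.05)
})

test_that("coarseness falls with VOI size and multiplying by N removes the trend", {
  set.seed(47)
  f <- image_volume(array(rnorm(40 * 40 * 16, 100, 30), c(40, 40, 16)),
                    c(1.17, 1.17, 3))
  res <- sapply(c(10, 14, 18, 22, 26), function(k) {
    fl <- array(FALSE, dim(f$values)); fl[5:(4 + k), 5:(4 + k), 3:13] <- TRUE
    m <- voi_mask(fl, f$spacing)
    v <- extract_features(f, m, d = 64)
    c(raw = v[["NGTDM-Coarseness"]], norm = v[["NGTDM-Coarseness"]] * m$n_voxels)
  })
  expect_true(all(diff(res["raw", ]) < 0))
  expect_lt(rel_spread(res["norm", ]), 0.10)
})

test_that("GL normalization stabilizes features across the gray-level ladder", {
  smooth <- generate_texture_field(c(40, 40, 16), c(1.17, 1.17, 3),
                                   corr_length = 8, mean = 100, sd = 20,
                                   seed = 48)
  flags <- array(FALSE, c(40, 40, 16)); flags[5:36, 5:36, 3:14] <- TRUE
  voi <- extract_voi(smooth, voi_mask(flags, smooth$spacing))
  ds <- c(8, 16, 32, 64, 128, 256)
  feats <- sapply(ds, function(d) {
    g <- build_glcm(discretize(voi, d))
    f <- glcm_features(g)
    c(H = f[["GLCM-Entropy"]], HS = f[["GLCM-Sum Entropy"]],
      HD = f[["GLCM-Difference Entropy"]], K = f[["GLCM-Contrast"]])
  })
  # non-normalized entropies vary by > 50% across the ladder; dividing by
  # log2(d) shrinks the variation at least twofold (the residual is the
  # per-field differential-entropy offset divided by log2 d)
  for (row in c("H", "HS", "HD")) {
    raw <- rel_spread(feats[row, ])
    norm <- rel_spread(feats[row, ] / log2(ds))
    expect_gt(raw, 0.5)
    expect_lt(norm, raw / 2)
  }
  # sum entropy, whose additive offset is small, is nearly constant
  expect_lt(rel_spread(feats["HS", ] / log2(ds)), 0.06)
  # contrast scales as d^2: successive normalized ratios rise toward 1
  ratio <- (feats["K", -1] / ds[-1]^2) / (feats["K", -6] / ds[-6]^2)
  expect_true(all(diff(ratio) > 0))
  expect_lt(abs(ratio[5] - 1), 0.01)
  expect_lt(abs(ratio[4] - 1), 0.05)
})
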