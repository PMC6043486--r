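# Robustness metrics: absolute Spearman rank correlation against voxel
# count, and the two-way consistency ICC across discretization levels.

#' Absolute Spearman rank correlation with a Fisher-z confidence interval
#'
#' Ranks use average ties; the coefficient is the Pearson correlation of the
#' ranks. The 95% CI is computed on the signed coefficient via the Fisher z
#' transform with standard error `1/sqrt(n - 3)`.
#'
#' @param x,y numeric vectors of equal length (at least 4 pairs, each with
#'   at least 2 distinct values).
#' @param conf_level confidence level (default 0.95).
#' @return List: `estimate` (`|r_s|`), `r` (signed), `conf_low`, `conf_high`
#'   (CI on the signed coefficient), `n`.
#' @export
spearman_abs <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("at least 4 pairs required")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("correlation undefined: constant sequence")
  r <- cor(x, y, method = "spearman")
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(c(z - q * se, z + q * se))
  list(estimate = abs(r), r = r, conf_low = ci[1], conf_high = ci[2], n = n)
}

#' Categorize an absolute Spearman coefficient
#'
#' `< 0.5` means no correlation with the voxel count, `> 0.9` high
#' correlation, anything between (boundaries included) moderate.
#'
#' @param rs_abs `|r_s|` in `[0, 1]`.
#' @return `"no"`, `"moderate"` or `"high"`.
#' @export
categorize_rs <- function(rs_abs) {
  if (!is.finite(rs_abs) || rs_abs < 0 || rs_abs > 1)
    stop("|r_s| must lie in [0, 1]")
  if (rs_abs < 0.5) "no" else if (rs_abs <= 0.9) "moderate" else "high"
}

#' Two-way consistency ICC across discretization levels
#'
#' For a subjects x levels table without replication, the two-way ANOVA
#' decomposition removes subject and level main effects; with `BMS` the
#' between-subjects mean square and `RMS` the residual mean square,
#' `ICC = (BMS - RMS) / (BMS + (d - 1) * RMS)` where `d` is the number of
#' level columns. Negative values arise when within-subject disagreement
#' exceeds between-subject spread. The 95% CI uses the F-distribution bounds
#' on `BMS/RMS`.
#'
#' @param table numeric matrix, rows = subjects (>= 3), columns = levels
#'   (>= 2), no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return List: `icc`, `conf_low`, `conf_high`, `bms`, `rms`, `n_subjects`,
#'   `n_levels`.
#' @export
icc_consistency <- function(table, conf_level = 0.95) {
  m <- as.matrix(table)
  if (any(!is.finite(m))) stop("table must be complete and finite")
  n <- nrow(m); d <- ncol(m)
  if (d < 2) stop("ICC undefined: need at least 2 levels")
  if (n < 3) stop("ICC requires at least 3 subjects")
  grand <- mean(m)
  if (all(m == grand)) stop("ICC undefined: zero total variance")
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  bms <- d * sum((rm_ - grand)^2) / (n - 1)
  resid <- m - outer(rm_, rep(1, d)) - outer(rep(1, n), cm_) + grand
  rms <- sum(resid^2) / ((n - 1) * (d - 1))
  icc <- if (bms == 0 && rms == 0) stop("ICC undefined: zero total variance")
         else (bms - rms) / (bms + (d - 1) * rms)
  if (rms == 0) {
    ci <- c(1, 1)
  } else {
    alpha <- 1 - conf_level
    fobs <- bms / rms
    fl <- fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (d - 1))
    fu <- fobs * qf(1 - alpha / 2, (n - 1) * (d - 1), n - 1)
    ci <- c((fl - 1) / (fl + d - 1), (fu - 1) / (fu + d - 1))
  }
  list(icc = icc, conf_low = ci[1], conf_high = ci[2], bms = bms, rms = rms,
       n_subjects = n, n_levels = d)
}

#' Categorize an ICC value
#'
#' `< 0.5` not stable, `> 0.8` highly stable, between (boundaries included)
#' intermediately stable.
#'
#' @param icc value in `[-1, 1]`.
#' @return `"not stable"`, `"intermediate"` or `"highly stable"`.
#' @export
categorize_icc <- function(icc) {
  if (!is.finite(icc) || icc < -1 || icc > 1)
    stop("ICC must lie in [-1, 1]")
  if (icc < 0.5) "not stable" else if (icc <= 0.8) "intermediate"
  else "highly stable"
}
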