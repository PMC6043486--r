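# End-to-end experiments: voxel-size robustness (features vs N across a
# resampling set) and gray-level robustness (ICC across discretization
# levels), plus report writing.

#' Experiment configuration
#'
#' @param mode `"both"`, `"voxel"` or `"gl"`.
#' @param cohort a [cohort_spec()].
#' @param grid a [resampling_grid()] for the voxel-size experiment.
#' @param gl_levels gray-level ladder for the gray-level experiment
#'   (nonempty powers of two in 8..256).
#' @param d_voxel fixed gray-level count for the voxel-size experiment
#'   (default 64).
#' @param seed optional seed overriding the cohort spec's seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("both", "voxel", "gl"),
                              cohort = cohort_spec(),
                              grid = resampling_grid(),
                              gl_levels = c(8, 16, 32, 64, 128, 256),
                              d_voxel = 64, seed = NULL) {
  mode <- match.arg(mode)
  if (length(gl_levels) < 1 ||
      any(gl_levels < 8 | gl_levels > 256 |
          bitwAnd(as.integer(gl_levels), as.integer(gl_levels) - 1L) != 0))
    stop("gl_levels must be nonempty powers of two in 8..256")
  if (!is.null(seed)) {
    cohort$seed <- seed
    cohort$field_seed <- seed + 7919
  }
  structure(list(mode = mode, cohort = cohort, grid = grid,
                 gl_levels = gl_levels, d_voxel = d_voxel),
            class = "experiment_config")
}

.stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[radnorm %s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

# One wide feature row per data set and variant.
.feature_row <- function(id, label, variant, vals) {
  row <- data.frame(id = id, dataset = label, variant = variant,
                    pixel_size = attr(vals, "pixel_size"),
                    slice_thickness = attr(vals, "slice_thickness"),
                    d = attr(vals, "d"), n_voxels = attr(vals, "n_voxels"),
                    stringsAsFactors = FALSE)
  cbind(row, as.data.frame(as.list(vals), check.names = FALSE,
                           col.names = names(vals)))
}

#' Run the voxel-size robustness experiment
#'
#' Expands every subject across the one-factor-at-a-time resampling set,
#' extracts the 24-feature panel at `d_voxel` gray levels in non-normalized
#' and voxel-normalized variants, and computes the absolute Spearman
#' correlation of each of the 10 voxel-normalizable features with the voxel
#' count `N` across all data sets.
#'
#' @param config an [experiment_config()].
#' @param subjects optional pre-built cohort (list with `id`, `volume`,
#'   `mask` per element, e.g. from [generate_phantom_scans()]); defaults to
#'   [generate_tumor_cohort()] on `config$cohort`.
#' @param verbose log stage boundaries (default TRUE).
#' @return List: `features` (wide data.frame, one row per data set and
#'   variant), `report` (per-feature Spearman statistics and categories),
#'   `config`.
#' @export
run_voxel_experiment <- function(config = experiment_config(),
                                 subjects = NULL, verbose = TRUE) {
  t0 <- Sys.time()
  if (is.null(subjects)) {
    .stage_log(verbose, "generating cohort (n = %d)", config$cohort$n_subjects)
    subjects <- generate_tumor_cohort(config$cohort)
  }
  defs <- feature_definitions()
  rows <- list()
  for (s in subjects) {
    sets <- expand_resampled_set(s$volume, s$mask, config$grid)
    for (e in sets) {
      vals <- extract_features(e$volume, e$mask, d = config$d_voxel)
      rows[[length(rows) + 1L]] <- .feature_row(s$id, e$label,
                                                "non-normalized", vals)
      nvals <- apply_voxel_normalization(vals, attr(vals, "n_voxels"), defs)
      attributes(nvals) <- attributes(vals)
      rows[[length(rows) + 1L]] <- .feature_row(s$id, e$label,
                                                "voxel-normalized", nvals)
    }
    .stage_log(verbose, "subject %s: %d data sets", s$id, length(sets))
  }
  features <- do.call(rbind, rows)
  n_sets <- sum(features$variant == "non-normalized")
  .stage_log(verbose, "extracted %d data sets x 2 variants", n_sets)
  if (n_sets < 4)
    stop("insufficient data: Spearman correlation needs at least 4 data sets")
  panel <- defs$name[defs$voxel_norm_rule != "none"]
  rep_rows <- list()
  for (variant in c("non-normalized", "voxel-normalized")) {
    sub <- features[features$variant == variant, ]
    for (f in panel) {
      st <- spearman_abs(sub$n_voxels, sub[[f]])
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        feature = f, variant = variant, statistic = "spearman_abs",
        estimate = st$estimate, conf_low = st$conf_low,
        conf_high = st$conf_high, category = categorize_rs(st$estimate),
        n = st$n, stringsAsFactors = FALSE)
    }
  }
  .stage_log(verbose, "voxel experiment done in %.1f s",
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  list(features = features, report = do.call(rbind, rep_rows),
       config = config)
}

#' Run the gray-level robustness experiment
#'
#' Extracts the feature panel from every subject at each gray-level count in
#' `config$gl_levels` (original voxel size, no resampling), in
#' non-normalized and gray-level-normalized variants, then computes the
#' two-way consistency ICC across levels for each of the 17 gray-level-panel
#' features.
#'
#' @inheritParams run_voxel_experiment
#' @return List: `features` (wide data.frame), `report` (per-feature ICC
#'   with CI and category), `config`.
#' @export
run_gl_experiment <- function(config = experiment_config(),
                              subjects = NULL, verbose = TRUE) {
  t0 <- Sys.time()
  if (length(config$gl_levels) < 2)
    stop("ICC undefined: need at least 2 gray-level counts")
  if (is.null(subjects)) {
    .stage_log(verbose, "generating cohort (n = %d)", config$cohort$n_subjects)
    subjects <- generate_tumor_cohort(config$cohort)
  }
  defs <- feature_definitions()
  rows <- list()
  for (s in subjects) {
    voi <- extract_voi(s$volume, s$mask)
    for (d in config$gl_levels) {
      dvoi <- suppressWarnings(discretize(voi, d))
      vals <- c(intensity_features(voi),
                glcm_features(build_glcm(dvoi)),
                glrlm_features(build_glrlm(dvoi)),
                glszm_features(build_glszm(dvoi)),
                ngtdm_features(build_ngtdm(dvoi)))
      vals <- vals[defs$name]
      attr(vals, "n_voxels") <- s$mask$n_voxels
      attr(vals, "d") <- d
      attr(vals, "pixel_size") <- s$volume$spacing[1]
      attr(vals, "slice_thickness") <- s$volume$spacing[3]
      lab <- sprintf("GL%d", d)
      rows[[length(rows) + 1L]] <- .feature_row(s$id, lab,
                                                "non-normalized", vals)
      nvals <- apply_gl_normalization(vals, d, defs)
      attributes(nvals) <- attributes(vals)
      rows[[length(rows) + 1L]] <- .feature_row(s$id, lab,
                                                "gl-normalized", nvals)
    }
  }
  features <- do.call(rbind, rows)
  .stage_log(verbose, "extracted %d data sets x 2 variants",
             sum(features$variant == "non-normalized"))
  panel <- defs$name[defs$gl_norm_factor != "none"]
  ids <- unique(features$id)
  rep_rows <- list()
  for (variant in c("non-normalized", "gl-normalized")) {
    sub <- features[features$variant == variant, ]
    for (f in panel) {
      tab <- matrix(NA_real_, length(ids), length(config$gl_levels),
                    dimnames = list(ids, config$gl_levels))
      for (i in seq_along(ids))
        for (j in seq_along(config$gl_levels))
          tab[i, j] <- sub[[f]][sub$id == ids[i] &
                                sub$d == config$gl_levels[j]]
      st <- icc_consistency(tab)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        feature = f, variant = variant, statistic = "icc",
        estimate = st$icc, conf_low = st$conf_low, conf_high = st$conf_high,
        category = categorize_icc(st$icc),
        n = st$n_subjects * st$n_levels, stringsAsFactors = FALSE)
    }
  }
  .stage_log(verbose, "gray-level experiment done in %.1f s",
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  list(features = features, report = do.call(rbind, rep_rows),
       config = config)
}

#' Run the configured experiments end to end
#'
#' @param config an [experiment_config()].
#' @param outdir optional output directory; if given, [write_report()] is
#'   called for each experiment.
#' @param verbose log stage boundaries.
#' @return Named list with elements `voxel` and/or `gl`.
#' @export
run_experiment <- function(config = experiment_config(), outdir = NULL,
                           verbose = TRUE) {
  subjects <- generate_tumor_cohort(config$cohort)
  out <- list()
  if (config$mode %in% c("both", "voxel"))
    out$voxel <- run_voxel_experiment(config, subjects, verbose = verbose)
  if (config$mode %in% c("both", "gl"))
    out$gl <- run_gl_experiment(config, subjects, verbose = verbose)
  if (!is.null(outdir)) {
    for (nm in names(out))
      write_report(out[[nm]], file.path(outdir, nm), verbose = verbose)
  }
  out
}

#' Write experiment outputs: CSV tables, JSON summary and bar charts
#'
#' Writes `features.csv` (one row per data set and variant),
#' `robustness.csv` (the per-feature statistics), `results.json` (config
#' echo plus the report) and, where a PNG device is available, a paired bar
#' chart of the robustness statistic before (black) and after (gray)
#' normalization.
#'
#' @param result output of [run_voxel_experiment()] or
#'   [run_gl_experiment()].
#' @param outdir output directory, created if missing.
#' @param verbose log files as they are written.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(result, outdir, verbose = TRUE) {
  if (is.null(result$report) || nrow(result$report) == 0)
    stop("empty report")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- character()
  f_feat <- file.path(outdir, "features.csv")
  write.csv(result$features, f_feat, row.names = FALSE)
  files <- c(files, f_feat)
  f_rep <- file.path(outdir, "robustness.csv")
  write.csv(result$report, f_rep, row.names = FALSE)
  files <- c(files, f_rep)
  f_json <- file.path(outdir, "results.json")
  cfg <- result$config
  cfg_plain <- lapply(unclass(cfg), function(x)
    if (inherits(x, c("cohort_spec", "resampling_grid"))) unclass(x) else x)
  jsonlite::write_json(list(config = cfg_plain, report = result$report),
                       f_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f_json)
  if (capabilities("png")) {
    f_png <- file.path(outdir, "robustness.png")
    stat_lab <- if (result$report$statistic[1] == "icc") "ICC"
                else "|r_s| vs number of voxels"
    rep_ <- result$report
    rep_$variant <- factor(rep_$variant,
                           levels = unique(rep_$variant))
    gg <- ggplot2::ggplot(rep_, ggplot2::aes(
      x = .data$feature, y = .data$estimate, fill = .data$variant)) +
      ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                        width = 0.7, color = "black", linewidth = 0.2) +
      ggplot2::scale_fill_manual(values = c("black", "gray70")) +
      ggplot2::labs(title = sprintf("%s before/after normalization (synthetic data)",
                                    stat_lab),
                    x = NULL, y = stat_lab, fill = NULL) +
      ggplot2::theme_minimal(base_size = 10) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
    ggplot2::ggsave(f_png, gg, width = 8, height = 4.5, dpi = 120)
    files <- c(files, f_png)
  }
  .stage_log(verbose, "wrote %s", paste(basename(files), collapse = ", "))
  invisible(files)
}
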