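#' Run configuration for the end-to-end analysis
#'
#' Collects every threshold of the pipeline in one validated object; nothing
#' downstream uses hidden constants. Defaults are the analysis defaults used
#' throughout: 90 s time step, 1 um/min angle exclusion, 9-degree angle bins,
#' 10.5 min MSD cap, 5 um / 150 s confinement, 2.5 um voxels with 5 um reach
#' in a 400 um domain, Bonferroni correction, and the frame-reduction stop
#' rule (p >= 1e-4 or 55% of frames removed).
#'
#' @param input a `track_set`, or a path readable by [read_tracks()].
#' @param dialect column-name mapping passed to [read_tracks()].
#' @param target_dt,dt_tolerance resampling target and tolerance, seconds.
#' @param min_speed turning-angle exclusion threshold, um/min.
#' @param angle_bin angle bin width, degrees.
#' @param msd_cap_min MSD elapsed-time cap, minutes.
#' @param confine_radius,confine_dwell confinement ball radius (um) and
#'   minimum dwell (s).
#' @param voxel,reach,domain patrolled-volume parameters, um.
#' @param persistence_max_bin open top speed bin for the persistence table,
#'   um/min.
#' @param angle_threshold threshold for the per-cell proportion of low
#'   turning angles, degrees.
#' @param correction multiplicity correction for pairwise tables.
#' @param p_threshold,max_frac_removed outlier-frame reduction stop rule.
#' @param out_dir output directory for the report bundle, or `NULL` to skip
#'   writing.
#' @return object of class `run_config`.
#' @export
run_config <- function(input, dialect = NULL, target_dt = 90,
                       dt_tolerance = 10, min_speed = 1, angle_bin = 9,
                       msd_cap_min = 10.5, confine_radius = 5,
                       confine_dwell = 150, voxel = 2.5, reach = 5,
                       domain = 400, persistence_max_bin = 12,
                       angle_threshold = 90, correction = "bonferroni",
                       p_threshold = 1e-4, max_frac_removed = 0.55,
                       out_dir = NULL) {
  stopifnot(target_dt > 0, dt_tolerance >= 0, min_speed >= 0, angle_bin > 0,
            angle_bin <= 180, msd_cap_min > 0, confine_radius > 0,
            confine_dwell >= 0, voxel > 0, reach > 0, domain > voxel,
            persistence_max_bin > 0, angle_threshold > 0,
            angle_threshold <= 180, p_threshold > 0, p_threshold <= 1,
            max_frac_removed >= 0, max_frac_removed < 1)
  structure(as.list(environment()), class = "run_config")
}

metric_columns <- c("cell_speed", "displacement_speed", "meandering_ratio",
                    "msd_slope", "confined_ratio", "confined_time",
                    "volume_rate")

#' Per-tissue medians of all cell metrics
#'
#' Medians are taken over defined (non-`NA`) values only, with the counts
#' used reported alongside.
#'
#' @param metrics per-cell metrics data.frame from [compute_all()].
#' @return data.frame, one row per tissue: `tissue`, `n_cells`, then for
#'   each metric its median and the count of defined values.
#' @export
summarize_medians <- function(metrics) {
  if (nrow(metrics) == 0) stop("empty metrics table")
  tissues <- sort(unique(metrics$tissue))
  rows <- lapply(tissues, function(ti) {
    m <- metrics[metrics$tissue == ti, , drop = FALSE]
    row <- data.frame(tissue = ti, n_cells = nrow(m),
                      stringsAsFactors = FALSE)
    for (col in metric_columns) {
      v <- m[[col]]
      row[[paste0("median_", col)]] <- stats::median(v, na.rm = TRUE)
      row[[paste0("n_", col)]] <- sum(!is.na(v))
    }
    row
  })
  do.call(rbind, rows)
}

#' Run the full motility analysis
#'
#' Orchestrates the whole pipeline: load (if given a path), normalize time
#' steps with phase-complete subsampling, compute per-cell metrics and the
#' pooled step table, then the comparison layer — per-tissue medians, angle
#' histograms and speed-angle profiles, per-tissue persistence tables,
#' per-cell low-angle proportions, pairwise Mann-Whitney matrices for every
#' metric (plus a Kolmogorov-Smirnov matrix for the patrolled-volume
#' distribution), intra-/inter-tissue ANOVA of cell speed, and the
#' outlier-frame reduction with the ANOVA rerun on the reduced set. When
#' `cfg$out_dir` is set, each table is written as CSV plus a JSON manifest
#' with counts, exclusions, and the configuration.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list with `tracks` (resampled `track_set`),
#'   `timesteps`, `cell_metrics`, `steps`, `medians`, `angle_hist`,
#'   `speed_angle`, `persistence`, `frac_below`, `pairwise` (named list of
#'   `pairwise_matrix`), `anova`, `reduction`, `anova_reduced`, `manifest`.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ts <- stage("load", {
    if (inherits(cfg$input, "track_set")) cfg$input
    else read_tracks(cfg$input, dialect = cfg$dialect)
  })
  rs <- stage("resample",
              resample_tracks(ts, resample_spec(cfg$target_dt,
                                                cfg$dt_tolerance)))
  tstep <- stage("timesteps", timestep_summary(rs))
  all <- stage("metrics", compute_all(rs, list(
    min_speed = cfg$min_speed, msd_cap_min = cfg$msd_cap_min,
    confine_radius = cfg$confine_radius, confine_dwell = cfg$confine_dwell,
    voxel = cfg$voxel, reach = cfg$reach, domain = cfg$domain)))
  cm <- all$cell_metrics
  steps <- all$steps

  med <- stage("medians", summarize_medians(cm))
  tissues <- sort(unique(cm$tissue))

  per_tissue <- function(fun) {
    out <- list()
    for (ti in tissues) {
      res <- tryCatch(fun(ti), error = function(e) NULL)
      if (!is.null(res)) out[[ti]] <- res
    }
    out
  }
  ahist <- stage("angle_histogram", per_tissue(function(ti)
    angle_histogram(steps[steps$tissue == ti, ], cfg$angle_bin)))
  sap <- stage("speed_angle", per_tissue(function(ti)
    speed_angle_profile(steps[steps$tissue == ti, ], cfg$angle_bin)))
  pers <- stage("persistence", per_tissue(function(ti) {
    sub <- rs
    sub$points <- rs$points[rs$points$tissue == ti, , drop = FALSE]
    persistence_table(sub, max_bin = cfg$persistence_max_bin)
  }))
  fb <- stage("fraction_below", fraction_below(steps, cfg$angle_threshold))

  by_tissue <- function(df, col) split(df[[col]], df$tissue)
  pw <- stage("pairwise", {
    out <- list()
    for (col in metric_columns) {
      out[[col]] <- pairwise_ranksum(by_tissue(cm, col), cfg$correction)
    }
    out$angle_frac_below <- pairwise_ranksum(by_tissue(fb, "frac_below"),
                                             cfg$correction)
    out$volume_rate_ks <- pairwise_ks(by_tissue(cm, "volume_rate"),
                                      cfg$correction)
    out
  })
  av <- stage("anova", intra_inter_anova(cm, "cell_speed"))
  red <- stage("reduction",
               reduce_outlier_frames(cm, "cell_speed", cfg$p_threshold,
                                     cfg$max_frac_removed))
  av_red <- stage("anova_reduced", intra_inter_anova(red$metrics,
                                                     "cell_speed"))

  manifest <- list(
    n_tracks = n_tracks(rs),
    n_cells = nrow(cm),
    n_steps = nrow(steps),
    tissues = tissues,
    exclusions = attr(cm, "exclusions"),
    log = rs$log,
    config = cfg[setdiff(names(cfg), c("input", "dialect"))])

  result <- list(tracks = rs, timesteps = tstep, cell_metrics = cm,
                 steps = steps, medians = med, angle_hist = ahist,
                 speed_angle = sap, persistence = pers, frac_below = fb,
                 pairwise = pw, anova = av, reduction = red$report,
                 metrics_reduced = red$metrics, anova_reduced = av_red,
                 manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    stage("write", write_bundle(result, cfg$out_dir))
  }
  invisible(result)
}

write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wcsv(result$cell_metrics, "cell_metrics")
  wcsv(result$steps, "step_table")
  wcsv(result$medians, "tissue_medians")
  wcsv(result$timesteps, "timestep_summary")
  wcsv(result$frac_below, "angle_fraction_below")
  for (ti in names(result$angle_hist)) {
    wcsv(result$angle_hist[[ti]], paste0("angle_histogram_", ti))
    wcsv(result$speed_angle[[ti]], paste0("speed_angle_profile_", ti))
    wcsv(as.data.frame(result$persistence[[ti]]), paste0("persistence_", ti))
  }
  for (nm in names(result$pairwise)) {
    wcsv(as.data.frame(result$pairwise[[nm]]$p), paste0("pairwise_", nm))
  }
  red <- lapply(result$reduction, function(r) {
    data.frame(removed = paste(r$removed, collapse = ";"),
               p_initial = r$p_initial, p_final = r$p_final,
               retained_frames = length(r$retained_frames),
               retained_cells = r$retained_cells, reached = r$reached)
  })
  wcsv(cbind(tissue = names(red), do.call(rbind, red)), "reduction_report")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
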