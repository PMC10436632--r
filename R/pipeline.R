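#' Run the full diaphragm-tracking pipeline
#'
#' Executes the complete chain on a cine loop: read, 3x3 mean filter,
#' threshold segmentation of frame 1, largest-component selection,
#' random seeding of tracking points, DBSCAN stray-point removal,
#' pyramidal Lucas-Kanade tracking, 15-group reduction, displacement
#' and global-strain curves, moving-average smoothing, respiratory
#' cycle detection, drift correction, and per-cycle peak-to-peak
#' summaries. Every stage is driven by the validated configuration and
#' the run is a pure function of (input, config, seed).
#'
#' @param input a [frame_sequence], a multi-frame DICOM file path, or
#'   an image-directory path.
#' @param config named list of configuration overrides, passed through
#'   [validate_config()].
#' @param output_dir optional directory; when given, the curve CSV,
#'   JSON sidecar, and run report are written there.
#' @return invisible list with `curves` (raw), `corrected`
#'   (drift-corrected cumulative and strain curves), `smoothed` (the
#'   final smoothed corrected outputs, as written to disk), `cycles`,
#'   `seeds`, `tracked`, `mask`, and `report` (all parameters,
#'   per-stage point counts, period, peak-to-peak summaries).
#' @export
run_pipeline <- function(input, config = list(), output_dir = NULL) {
  cfg <- validate_config(config)
  say <- function(...) {
    if (cfg$verbosity > 0) message(sprintf(...))
  }

  seq <- if (inherits(input, "frame_sequence")) {
    input
  } else if (dir.exists(input)) {
    if (is.null(cfg$frame_interval)) {
      stop("frame_interval must be configured for image-directory input",
           call. = FALSE)
    }
    read_image_directory(input, cfg$frame_interval)
  } else {
    read_dicom_sequence(input, default_interval = cfg$frame_interval)
  }
  dt <- seq$frame_interval
  say("loaded %d frames (%.4g s/frame) from %s", n_frames(seq), dt,
      seq$source_id)

  manual <- if (identical(cfg$threshold.mode, "manual")) {
    cfg$threshold.value
  } else NULL
  mask <- segment_diaphragm(seq$frames[[1]], manual_threshold = manual)
  say("segmented diaphragm: threshold %.1f, component of %d px",
      mask$threshold_used, sum(mask$binary > 0) )

  seeds <- seed_random_points(mask, n = cfg$seed_points.n,
                              seed = cfg$seed_points.seed)
  seeds <- dbscan_filter(seeds, eps = cfg$dbscan.eps,
                         min_pts = cfg$dbscan.min_pts,
                         keep_all_clusters = cfg$dbscan.keep_all_clusters)
  say("seeded %d points, kept %d after DBSCAN", nrow(seeds$coords),
      sum(seeds$kept_mask))

  tracked <- track_sequence(seq, seeds, m = cfg$lk.window,
                            pyramid_levels = cfg$lk.pyramid_levels,
                            iterations = cfg$lk.iterations,
                            min_eig_floor = cfg$lk.min_eig_floor,
                            max_cond = cfg$lk.max_condition)
  n_final <- sum(tracked$valid[, ncol(tracked$valid)])
  say("tracked %d frames; %d points survive to the last frame",
      n_frames(seq), n_final)
  tracked <- assign_groups(tracked, k = cfg$groups.k)

  curves <- displacement_curves(tracked, dt)
  curves <- strain_curve(curves, tracked)

  cycles <- detect_cycles(smooth_curve(curves[[cfg$cycles.curve]],
                                       cfg$smooth.kernel), dt,
                          min_prominence_frac = cfg$cycles.min_prominence,
                          source_curve = cfg$cycles.curve)
  say("respiratory period %.3f s (%d peaks, %d troughs)",
      cycles$period_T, length(cycles$peaks), length(cycles$troughs))

  # The drift ramp is anchored on the raw cumulative state (the raw
  # curve is the one with S(0) = 0 exactly); smoothing is applied to
  # the corrected curves for the final outputs.
  corrected <- curves
  if (cfg$drift.enabled) {
    for (col in c("cumulative_h", "cumulative_v", "gs")) {
      corrected[[col]] <- drift_correct(curves[[col]], cycles$period_T,
                                        dt)
    }
  }
  smoothed <- corrected
  for (col in c("interframe_h", "interframe_v", "cumulative_h",
                "cumulative_v", "gs")) {
    smoothed[[col]] <- smooth_curve(corrected[[col]], cfg$smooth.kernel)
  }

  pkpk <- lapply(c(cumulative_h = "cumulative_h",
                   cumulative_v = "cumulative_v", gs = "gs"),
                 function(col) {
                   p <- peak_to_peak(smoothed[[col]], cycles)
                   list(per_cycle = p$per_cycle, mean = p$mean, sd = p$sd)
                 })

  report <- list(
    source = seq$source_id,
    n_frames = n_frames(seq),
    frame_interval_s = dt,
    config = cfg[!vapply(cfg, is.null, logical(1))],
    threshold_used = mask$threshold_used,
    n_seeded = nrow(seeds$coords),
    n_kept_after_dbscan = sum(seeds$kept_mask),
    n_surviving_final_frame = n_final,
    period_s = cycles$period_T,
    peak_to_peak = pkpk)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_curves(smoothed, cycles, file.path(output_dir, "curves.csv"),
                 pixel_spacing = seq$pixel_spacing, config = cfg)
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  invisible(list(curves = curves, smoothed = smoothed,
                 corrected = corrected, cycles = cycles, seeds = seeds,
                 tracked = tracked, mask = mask, report = report))
}
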