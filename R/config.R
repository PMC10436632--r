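# Pipeline configuration: flat dotted keys, every key with a documented
# default, unknown keys rejected with the nearest valid name suggested.

.config_defaults <- function() {
  list(
    frame_interval = NULL,          # override, seconds/frame (DICOM fallback)
    seed = 1L,                      # global RNG seed
    threshold.mode = "auto",        # "auto" (Otsu) | "manual"
    threshold.value = NULL,         # manual threshold, 0-255
    seed_points.n = 300L,           # random tracking points to seed
    seed_points.seed = NULL,        # defaults to `seed`
    dbscan.eps = 15,                # DBSCAN radius, pixels
    dbscan.min_pts = 10L,           # DBSCAN density floor
    dbscan.keep_all_clusters = FALSE,
    lk.window = 15L,                # odd LK window side m
    lk.pyramid_levels = 3L,
    lk.iterations = 3L,
    lk.min_eig_floor = 1e-4,
    lk.max_condition = 1e6,
    groups.k = 15L,                 # groups for the band-length chain
    smooth.kernel = 5L,             # odd moving-average kernel
    cycles.curve = "cumulative_v",  # curve used for cycle detection
    cycles.min_prominence = 0.1,    # fraction of global range
    drift.enabled = TRUE,
    verbosity = 1L)
}

#' Validate and complete a pipeline configuration
#'
#' Fills defaults for missing keys, type-checks every supplied value,
#' and rejects unknown keys, suggesting the nearest valid name. All
#' problems are reported at once.
#'
#' @param raw named list of configuration overrides (possibly empty),
#'   e.g. parsed from a YAML file.
#' @return a complete, validated configuration list.
#' @export
validate_config <- function(raw = list()) {
  defaults <- .config_defaults()
  problems <- character(0)

  if (length(raw) && (is.null(names(raw)) || any(names(raw) == ""))) {
    stop("configuration must be a named list", call. = FALSE)
  }
  unknown <- setdiff(names(raw), names(defaults))
  for (key in unknown) {
    dist <- utils::adist(key, names(defaults))
    suggestion <- names(defaults)[which.min(dist)]
    problems <- c(problems, sprintf(
      "unknown key '%s'; did you mean '%s'?", key, suggestion))
  }

  cfg <- utils::modifyList(defaults, raw[setdiff(names(raw), unknown)],
                           keep.null = TRUE)

  chk <- function(cond, msg) {
    if (!cond) problems <<- c(problems, msg)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  if (!is.null(cfg$frame_interval)) {
    chk(num1(cfg$frame_interval) && cfg$frame_interval > 0,
        "frame_interval must be a positive number")
  }
  chk(num1(cfg$seed), "seed must be a number")
  chk(cfg$threshold.mode %in% c("auto", "manual"),
      "threshold.mode must be 'auto' or 'manual'")
  if (identical(cfg$threshold.mode, "manual")) {
    chk(num1(cfg$threshold.value),
        "threshold.value is required when threshold.mode is 'manual'")
  }
  chk(num1(cfg$seed_points.n) && cfg$seed_points.n >= 1,
      "seed_points.n must be a positive count")
  chk(num1(cfg$dbscan.eps) && cfg$dbscan.eps > 0,
      "dbscan.eps must be a positive distance")
  chk(num1(cfg$dbscan.min_pts) && cfg$dbscan.min_pts >= 1,
      "dbscan.min_pts must be a positive count")
  chk(isTRUE(cfg$dbscan.keep_all_clusters) ||
        isFALSE(cfg$dbscan.keep_all_clusters),
      "dbscan.keep_all_clusters must be TRUE or FALSE")
  chk(num1(cfg$lk.window) && cfg$lk.window >= 3 &&
        cfg$lk.window %% 2 == 1,
      "lk.window must be odd and >= 3")
  chk(num1(cfg$lk.pyramid_levels) && cfg$lk.pyramid_levels >= 1,
      "lk.pyramid_levels must be >= 1")
  chk(num1(cfg$lk.iterations) && cfg$lk.iterations >= 1,
      "lk.iterations must be >= 1")
  chk(num1(cfg$lk.min_eig_floor) && cfg$lk.min_eig_floor >= 0,
      "lk.min_eig_floor must be >= 0")
  chk(num1(cfg$lk.max_condition) && cfg$lk.max_condition > 1,
      "lk.max_condition must be > 1")
  chk(num1(cfg$groups.k) && cfg$groups.k >= 2,
      "groups.k must be >= 2")
  chk(num1(cfg$smooth.kernel) && cfg$smooth.kernel >= 1 &&
        cfg$smooth.kernel %% 2 == 1,
      "smooth.kernel must be odd")
  chk(cfg$cycles.curve %in%
        c("cumulative_v", "cumulative_h", "interframe_v", "interframe_h",
          "gs"),
      "cycles.curve must name one of the output curves")
  chk(num1(cfg$cycles.min_prominence) && cfg$cycles.min_prominence > 0 &&
        cfg$cycles.min_prominence < 1,
      "cycles.min_prominence must be in (0, 1)")
  chk(isTRUE(cfg$drift.enabled) || isFALSE(cfg$drift.enabled),
      "drift.enabled must be TRUE or FALSE")

  if (length(problems)) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  if (is.null(cfg$seed_points.seed)) cfg$seed_points.seed <- cfg$seed
  for (key in c("seed", "seed_points.n", "seed_points.seed",
                "dbscan.min_pts", "lk.window", "lk.pyramid_levels",
                "lk.iterations", "groups.k", "smooth.kernel",
                "verbosity")) {
    cfg[[key]] <- as.integer(cfg[[key]])
  }
  cfg
}
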