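#' Specification of a synthetic diaphragm phantom
#'
#' Describes a synthetic B-mode-like cine loop: a bright curved band
#' (the diaphragm) over a darker background, both textured with
#' temporally coherent multiplicative speckle, undergoing periodic
#' breathing motion. The motion model is a half-versine breathing
#' profile `phase(t) = sin^2(pi * t / T)`, which starts and ends each
#' cycle at zero: the band translates by
#' `(amp_h, amp_v) * phase(t)` pixels, shortens along its axis by a
#' factor `1 - (strain_amplitude/100) * phase(t)` (inspiratory
#' contraction, so peak-to-peak global strain equals
#' `strain_amplitude`), and optionally accumulates a linear vertical
#' drift of `drift_rate` pixels per frame. The speckle texture is
#' frozen in the band's material frame and advected with the motion so
#' that it is trackable, as real speckle is over small tissue motion.
#'
#' The defaults emulate the recordings the pipeline is aimed at: a loop
#' of 4 breathing cycles of 2.5 s at 12.5 frames/s, with horizontal
#' excursion larger than vertical and a peak strain of 10%.
#'
#' @param image_size `(rows, cols)` in pixels.
#' @param band_center_row centerline row of the band at rest.
#' @param band_thickness band thickness in pixels.
#' @param band_curvature dome parameter: the centerline is
#'   `row(c) = band_center_row + curvature * (c - c_mid)^2 / (cols/2)`.
#' @param band_col_span fraction of the image width the band occupies,
#'   centered; the band ends inside the image as a real diaphragm
#'   section does, so no tracking window sits on the image border.
#' @param band_mean_intensity,background_mean_intensity gray levels.
#' @param speckle_sigma speckle standard deviation on the band, gray
#'   levels (background scales proportionally; multiplicative model).
#' @param n_frames number of frames.
#' @param frame_interval seconds per frame.
#' @param breath_period respiratory period in seconds
#'   (`>= 4 * frame_interval`).
#' @param translation_amplitude_h,translation_amplitude_v peak
#'   excursion in pixels (equals the cumulative peak-to-peak value).
#' @param strain_amplitude peak band shortening, percent.
#' @param drift_rate vertical drift, pixels per frame.
#' @param seed RNG seed; rendering is fully reproducible from it.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = c(120L, 160L),
                         band_center_row = 55,
                         band_thickness = 10,
                         band_curvature = 0.25,
                         band_col_span = 0.8,
                         band_mean_intensity = 200,
                         background_mean_intensity = 60,
                         speckle_sigma = 10,
                         n_frames = 126L,
                         frame_interval = 0.08,
                         breath_period = 2.5,
                         translation_amplitude_h = 6,
                         translation_amplitude_v = 3,
                         strain_amplitude = 10,
                         drift_rate = 0,
                         seed = 1L) {
  spec <- list(image_size = as.integer(image_size),
               band_center_row = band_center_row,
               band_thickness = band_thickness,
               band_curvature = band_curvature,
               band_col_span = band_col_span,
               band_mean_intensity = band_mean_intensity,
               background_mean_intensity = background_mean_intensity,
               speckle_sigma = speckle_sigma,
               n_frames = as.integer(n_frames),
               frame_interval = frame_interval,
               breath_period = breath_period,
               translation_amplitude_h = translation_amplitude_h,
               translation_amplitude_v = translation_amplitude_v,
               strain_amplitude = strain_amplitude,
               drift_rate = drift_rate,
               seed = as.integer(seed))
  if (spec$breath_period < 4 * spec$frame_interval) {
    stop("breath_period must be at least 4 frame intervals to be ",
         "resolvable", call. = FALSE)
  }
  if (spec$n_frames < 2L) stop("need at least 2 frames", call. = FALSE)
  class(spec) <- "phantom_spec"
  spec
}

# linear interpolation of matrix rows/cols at fractional 1-based
# positions (clamped); pos_r over rows, pos_c over cols
.interp_grid <- function(M, pos_r, pos_c) {
  nr <- nrow(M); nc <- ncol(M)
  pr <- pmin(pmax(pos_r, 1), nr)
  pc <- pmin(pmax(pos_c, 1), nc)
  r0 <- pmin(floor(pr), nr - 1L); fr <- pr - r0
  c0 <- pmin(floor(pc), nc - 1L); fc <- pc - c0
  A <- M[r0, c0, drop = FALSE] * ((1 - fr) %o% (1 - fc)) +
    M[r0, c0 + 1, drop = FALSE] * ((1 - fr) %o% fc) +
    M[r0 + 1, c0, drop = FALSE] * (fr %o% (1 - fc)) +
    M[r0 + 1, c0 + 1, drop = FALSE] * (fr %o% fc)
  A
}

.phase <- function(t, period) sin(pi * t / period)^2

#' Render a synthetic phantom cine loop
#'
#' Draws the loop described by a [phantom_spec()] together with its
#' exact ground truth. Pixels are rendered by inverse-mapping each
#' image position to the band's material frame (undoing translation,
#' drift, and the horizontal contraction about the image center), where
#' both the band geometry and the frozen speckle texture live; the
#' texture is sampled bilinearly, which advects it with the motion.
#'
#' @param spec a `phantom_spec`.
#' @return list with `seq` (a [frame_sequence]), `truth` (a
#'   `phantom_truth`: per-frame `translation_h`, `translation_v`,
#'   `length`, `gs`, plus `period_s` and `mask0`), and `spec`.
#' @export
render_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  cc <- (nc + 1) / 2
  t <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  ph <- .phase(t, spec$breath_period)
  tx <- spec$translation_amplitude_h * ph
  ty <- spec$translation_amplitude_v * ph +
    spec$drift_rate * (seq_len(spec$n_frames) - 1)
  s <- 1 - spec$strain_amplitude / 100 * ph

  r0_of <- function(cm) {
    spec$band_center_row + spec$band_curvature * (cm - cc)^2 / (nc / 2)
  }
  half_span <- spec$band_col_span * nc / 2
  # Anti-aliased band membership in [0, 1]: linear 1-px ramp at the
  # band edges so the edge position is sub-pixel accurate (a hard
  # cutoff would make the edge move in integer jumps and bias the
  # tracked sub-pixel motion).
  band_membership <- function(rm_dist, cm) {
    w_r <- pmin(pmax(spec$band_thickness / 2 + 0.5 - rm_dist, 0), 1)
    w_c <- pmin(pmax(half_span + 0.5 - abs(cm - cc), 0), 1)
    w_r * matrix(w_c, nrow(rm_dist), length(cm), byrow = TRUE)
  }

  # band must stay inside the image at every frame
  cm_span <- seq(cc - half_span, cc + half_span, by = 0.5)
  for (f in seq_len(spec$n_frames)) {
    rows_f <- r0_of(cm_span) + ty[f]
    lo <- min(rows_f) - spec$band_thickness / 2
    hi <- max(rows_f) + spec$band_thickness / 2
    if (lo < 1 || hi > nr) {
      stop("band exits the frame at frame ", f,
           " (rows ", round(lo, 1), "..", round(hi, 1), ")", call. = FALSE)
    }
  }

  # frozen material-frame speckle texture, lightly correlated
  margin <- ceiling(max(abs(ty)) + max(abs(tx)) +
                      nc * spec$strain_amplitude / 100 + 4)
  # Band-limited texture on a 4x supersampled grid: white noise blurred
  # to a speckle correlation length of ~1.2 image px. Sampling it at
  # fractional material positions then approximates a continuous
  # Gaussian-correlated field, so brightness constancy holds under
  # sub-pixel advection (no peak-locking toward integer shifts).
  ss <- 4L
  tex <- withr::with_seed(spec$seed, {
    M <- matrix(stats::rnorm((nr + 2 * margin) * ss *
                               (nc + 2 * margin) * ss),
                (nr + 2 * margin) * ss, (nc + 2 * margin) * ss)
    M <- as.matrix(EBImage::gblur(M, sigma = 1.2 * ss))
    M / stats::sd(M)
  })
  sample_tex <- function(rm, cm) {
    .interp_grid(tex, (rm + margin - 1) * ss + 1, (cm + margin - 1) * ss + 1)
  }

  rel_sigma <- spec$speckle_sigma / spec$band_mean_intensity
  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    rm <- seq_len(nr) - ty[f]                 # material rows per row
    cm <- cc + (seq_len(nc) - tx[f] - cc) / s[f]  # material cols per col
    w <- band_membership(abs(outer(rm, r0_of(cm), "-")), cm)
    base <- spec$background_mean_intensity +
      (spec$band_mean_intensity - spec$background_mean_intensity) * w
    tx_f <- sample_tex(rm, cm)
    img <- base * (1 + rel_sigma * tx_f)
    frames[[f]] <- pmin(pmax(img, 0), 255)
  }

  # ground-truth band length over the band's material span
  span <- seq(cc - half_span, cc + half_span, length.out = 181)
  lengths <- vapply(seq_len(spec$n_frames), function(f) {
    x <- cc + s[f] * (span - cc) + tx[f]
    y <- r0_of(span) + ty[f]
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1))

  mask0 <- matrix(0, nr, nc)
  mask0[band_membership(abs(outer(seq_len(nr), r0_of(seq_len(nc)), "-")),
                        seq_len(nc)) >= 0.5] <- 255

  truth <- structure(list(
    translation_h = tx,
    translation_v = ty,
    length = lengths,
    gs = (lengths - lengths[1]) / lengths[1] * 100,
    period_s = spec$breath_period,
    mask0 = mask0), class = "phantom_truth")

  seq <- frame_sequence(frames, spec$frame_interval,
                        source_id = sprintf("phantom(seed=%d)", spec$seed))
  list(seq = seq, truth = truth, spec = spec)
}

#' Write a phantom fixture to disk
#'
#' Saves the frames as a directory of numbered PNGs plus `truth.json`
#' (ground-truth curves) and `spec.yaml` (the generating spec), so the
#' full pipeline can be exercised from disk exactly as with clinical
#' data, and the fixture can be re-rendered bit-identically from the
#' logged spec.
#'
#' @param phantom the list returned by [render_phantom()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_phantom_fixture <- function(phantom, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_along(phantom$seq$frames)) {
    png::writePNG(phantom$seq$frames[[f]] / 255,
                  file.path(path, sprintf("frame_%04d.png", f)))
  }
  truth <- unclass(phantom$truth)
  truth$mask0 <- NULL
  jsonlite::write_json(truth, file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  sp <- unclass(phantom$spec)
  yaml::write_yaml(sp, file.path(path, "spec.yaml"))
  invisible(path)
}
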