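#' Inter-frame and cumulative displacement curves
#'
#' The per-frame displacement of the band is the mean, over points
#' valid in both frames, of the change in position between adjacent
#' frames; horizontal is the column component, vertical the row
#' component. Cumulative displacement is the running sum, so it is zero
#' at frame 1 by construction.
#'
#' @param tracked a `tracked_points` object.
#' @param frame_interval seconds per frame.
#' @return a `kinematic_curves` data frame with columns `time`,
#'   `interframe_h`, `interframe_v`, `cumulative_h`, `cumulative_v`
#'   (pixels) and placeholder `length`/`gs` columns (`NA` until
#'   [strain_curve()] fills them).
#' @export
displacement_curves <- function(tracked, frame_interval) {
  nf <- ncol(tracked$valid)
  ih <- numeric(nf)
  iv <- numeric(nf)
  for (f in 2:nf) {
    sel <- tracked$valid[, f - 1] & tracked$valid[, f]
    if (!any(sel)) {
      stop("no valid tracking points between frames ", f - 1, " and ", f,
           call. = FALSE)
    }
    iv[f] <- mean(tracked$traj[sel, f, 1] - tracked$traj[sel, f - 1, 1])
    ih[f] <- mean(tracked$traj[sel, f, 2] - tracked$traj[sel, f - 1, 2])
  }
  out <- data.frame(
    time = (seq_len(nf) - 1) * frame_interval,
    interframe_h = ih,
    interframe_v = iv,
    cumulative_h = cumsum(ih),
    cumulative_v = cumsum(iv),
    length = NA_real_,
    gs = NA_real_)
  class(out) <- c("kinematic_curves", "data.frame")
  out
}

#' Band length from ordered group centroids
#'
#' Approximates the diaphragm length as the sum of Euclidean distances
#' between consecutive group centroids (a polyline chord sum).
#'
#' @param centroids k x 2 matrix of ordered `(row, col)` centroids.
#' @return length in pixels.
#' @export
band_length <- function(centroids) {
  if (anyNA(centroids)) {
    stop("cannot compute band length: invalid (NA) centroid present",
         call. = FALSE)
  }
  d <- diff(centroids)
  sum(sqrt(rowSums(d^2)))
}

#' Global strain
#'
#' `GS(t) = (L(t) - L(0)) / L(0) * 100`, in percent. A shortening band
#' (inspiratory contraction) gives negative strain.
#'
#' @param L_t band length at time `t`, pixels.
#' @param L_0 reference length at frame 1, pixels, `> 0`.
#' @return strain in percent.
#' @export
global_strain <- function(L_t, L_0) {
  if (any(L_0 <= 0)) stop("reference length L(0) must be > 0",
                          call. = FALSE)
  (L_t - L_0) / L_0 * 100
}

#' Add band length and global strain to the curve table
#'
#' @param curves a `kinematic_curves` data frame.
#' @param tracked a grouped `tracked_points` object.
#' @return `curves` with `length` and `gs` columns filled.
#' @export
strain_curve <- function(curves, tracked) {
  nf <- ncol(tracked$valid)
  len <- vapply(seq_len(nf),
                function(f) band_length(group_centroids(tracked, f)),
                numeric(1))
  curves$length <- len
  curves$gs <- global_strain(len, len[1])
  curves
}

#' Moving-average curve smoothing
#'
#' Convolves the series with a uniform normalized kernel (default size
#' 5), replicating the end samples so output length equals input
#' length. Series shorter than the kernel are returned unchanged with
#' a warning.
#'
#' @param series numeric vector.
#' @param kernel_size odd kernel length (default 5).
#' @return smoothed numeric vector of the same length.
#' @export
smooth_curve <- function(series, kernel_size = 5L) {
  stopifnot(kernel_size %% 2 == 1, kernel_size >= 1)
  n <- length(series)
  if (n < kernel_size) {
    warning("series shorter than smoothing kernel; returned unchanged",
            call. = FALSE)
    return(series)
  }
  h <- kernel_size %/% 2
  padded <- c(rep(series[1], h), series, rep(series[n], h))
  as.numeric(stats::filter(padded, rep(1 / kernel_size, kernel_size),
                           sides = 2))[(h + 1):(h + n)]
}

# Local extrema with a prominence floor. Returns indices of maxima of
# `x` whose prominence (height above the higher of the two bounding
# saddle levels) is at least min_prom. Flat-topped peaks report their
# first index.
.find_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  s <- sign(diff(x))
  # plateaus belong to the following slope, so a flat-topped peak is
  # reported once, at its first sample
  for (i in rev(seq_len(length(s) - 1L))) {
    if (s[i] == 0) s[i] <- s[i + 1L]
  }
  cand <- which(s[-length(s)] > 0 & s[-1] < 0) + 1L
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    # walk left and right to the valley floors
    lmin <- min(x[1:p])
    rmin <- min(x[p:n])
    left_base <- {
      j <- p
      m <- x[p]
      while (j > 1 && x[j - 1] <= x[p]) { j <- j - 1; m <- min(m, x[j]) }
      if (j == 1) lmin else m
    }
    right_base <- {
      j <- p
      m <- x[p]
      while (j < n && x[j + 1] <= x[p]) { j <- j + 1; m <- min(m, x[j]) }
      if (j == n) rmin else m
    }
    prom <- x[p] - max(left_base, right_base)
    keep[i] <- prom >= min_prom
  }
  cand[keep]
}

#' Detect respiratory cycles from a displacement curve
#'
#' Locates peaks and troughs of the (smoothed) series with a minimum
#' prominence of `min_prominence_frac` times the series' global range,
#' then recovers the respiratory period: every adjacent peak-trough
#' pair spans half a cycle, so `T = 2 * |i_pk - i_th| * frame_interval`,
#' aggregated over all adjacent pairs by the median.
#'
#' @param series numeric vector (typically the smoothed cumulative
#'   vertical displacement).
#' @param frame_interval seconds per sample.
#' @param min_prominence_frac prominence floor as a fraction of the
#'   global range (default 0.1).
#' @param source_curve name of the curve the series came from, recorded
#'   in the annotation.
#' @return a `cycle_annotation`: list with sorted sample indices
#'   `peaks` and `troughs`, `period_T` in seconds, and `source_curve`.
#' @export
detect_cycles <- function(series, frame_interval,
                          min_prominence_frac = 0.1,
                          source_curve = "cumulative_v") {
  rng <- diff(range(series))
  if (rng == 0) {
    stop("flat series: no respiratory extrema found; a recording of ",
         "3-5 breathing cycles is expected", call. = FALSE)
  }
  prom <- min_prominence_frac * rng
  peaks <- .find_peaks(series, prom)
  troughs <- .find_peaks(-series, prom)
  if (length(peaks) == 0L || length(troughs) == 0L) {
    stop("no peak/trough pair found; a recording of 3-5 breathing ",
         "cycles is expected", call. = FALSE)
  }
  ext <- sort(c(peaks, troughs))
  half <- abs(diff(ext)) * frame_interval
  structure(list(peaks = peaks, troughs = troughs,
                 period_T = 2 * stats::median(half),
                 source_curve = source_curve),
            class = "cycle_annotation")
}

#' Drift correction of a cumulative curve
#'
#' Tracking error accumulates over frames, so cumulative displacement
#' and strain curves wander away from zero. Taking the first
#' respiratory cycle as reference — the band should return to its start
#' position at the end of every complete cycle — the correction
#' subtracts the linear ramp anchored at the end of the first cycle:
#' `S_corr(t) = S(t) - (S(T)/T) * t`, with `S(T)` read at the sample
#' nearest `t = T`. The corrected curve is exactly zero at that sample,
#' which makes the correction idempotent.
#'
#' @param series numeric cumulative-type curve (`series[1]` ~ 0).
#' @param period_T respiratory period in seconds.
#' @param frame_interval seconds per sample.
#' @return corrected numeric vector.
#' @export
drift_correct <- function(series, period_T, frame_interval) {
  t <- (seq_along(series) - 1) * frame_interval
  if (period_T <= 0 || period_T > t[length(t)]) {
    stop("period T (", period_T, " s) not covered by the recording (",
         t[length(t)], " s)", call. = FALSE)
  }
  iT <- which.min(abs(t - period_T))
  series - series[iT] / t[iT] * t
}

#' Per-cycle peak-to-peak values
#'
#' Splits the series into complete-cycle windows (between consecutive
#' troughs when at least two exist, else consecutive peaks) and
#' reports `max - min` within each window, with their mean and SD.
#'
#' @param series numeric vector.
#' @param cycles a `cycle_annotation`.
#' @return list with `per_cycle` (numeric vector), `mean`, `sd`, and
#'   the `windows` (2-column matrix of sample index bounds).
#' @export
peak_to_peak <- function(series, cycles) {
  bounds <- if (length(cycles$troughs) >= 2L) {
    cycles$troughs
  } else if (length(cycles$peaks) >= 2L) {
    cycles$peaks
  } else {
    stop("no complete respiratory cycle in the annotation", call. = FALSE)
  }
  bounds <- sort(bounds)
  windows <- cbind(bounds[-length(bounds)], bounds[-1])
  per_cycle <- apply(windows, 1, function(w) {
    seg <- series[w[1]:w[2]]
    max(seg) - min(seg)
  })
  list(per_cycle = per_cycle, mean = mean(per_cycle),
       sd = stats::sd(per_cycle), windows = windows)
}
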