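#' 3x3 averaging filter
#'
#' Replaces each pixel by the arithmetic mean of its 3x3 neighborhood,
#' the standard pre-filter for speckled B-mode frames. Borders are
#' handled by edge replication and the output is kept real-valued (not
#' re-quantized) so downstream gradients stay smooth.
#'
#' @param frame numeric matrix, at least 3x3.
#' @return numeric matrix of the same dimensions.
#' @export
mean_filter_3x3 <- function(frame) {
  if (!is.matrix(frame) || nrow(frame) < 3L || ncol(frame) < 3L) {
    stop("frame must be a matrix of at least 3x3", call. = FALSE)
  }
  kern <- matrix(1 / 9, 3, 3)
  as.matrix(EBImage::filter2(frame, kern, boundary = "replicate"))
}

#' Select a global intensity threshold (Otsu)
#'
#' Finds the threshold maximizing between-class variance of the
#' intensity histogram (Otsu's method) for separating the bright
#' diaphragm band from the darker background. A manual threshold, when
#' supplied, overrides the automatic choice.
#'
#' @param frame numeric matrix with at least 2 distinct intensities.
#' @param manual optional numeric threshold overriding the automatic one.
#' @return a single threshold on the `[0, 255]` intensity scale.
#' @export
select_threshold <- function(frame, manual = NULL) {
  if (!is.null(manual)) return(as.numeric(manual))
  rng <- range(frame)
  if (diff(rng) == 0) {
    stop("cannot threshold a constant frame (no separable classes)",
         call. = FALSE)
  }
  EBImage::otsu(frame / 255, range = c(0, 1), levels = 256) * 255
}

#' Binary threshold segmentation
#'
#' Maps pixels at or above the threshold to 255 (white) and the rest to
#' 0 (black).
#'
#' @param frame numeric matrix.
#' @param T intensity threshold.
#' @return matrix of the same dimensions containing only 0 and 255.
#' @export
threshold_segment <- function(frame, T) {
  out <- matrix(0, nrow(frame), ncol(frame))
  out[frame >= T] <- 255
  out
}

#' Retain the largest connected white region
#'
#' Labels the white (255) pixels with 8-connectivity and keeps only the
#' component with the greatest pixel count — taken to be the diaphragm
#' band, which is the dominant bright structure after thresholding.
#' Size ties are broken in favor of the component with the smallest
#' `(row_min, col_min)` bounding corner.
#'
#' @param binary matrix of 0/255 values with at least one white pixel.
#' @return a `diaphragm_mask`: list with `binary` (0/255 matrix of the
#'   surviving component), `threshold_used` (`NA` here; filled by
#'   [segment_diaphragm()]), `component_label`, and `bbox`
#'   `(row_min, col_min, row_max, col_max)` inclusive.
#' @export
largest_component <- function(binary) {
  if (!any(binary > 0)) {
    stop("no diaphragm found: thresholded image is all black",
         call. = FALSE)
  }
  lab <- .label8(binary > 0)
  sizes <- tabulate(lab[lab > 0])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    corners <- t(vapply(best, function(l) {
      w <- which(lab == l, arr.ind = TRUE)
      c(min(w[, 1]), min(w[, 2]))
    }, numeric(2)))
    best <- best[order(corners[, 1], corners[, 2])[1]]
  }
  keep <- lab == best
  out <- matrix(0, nrow(binary), ncol(binary))
  out[keep] <- 255
  w <- which(keep, arr.ind = TRUE)
  bbox <- c(row_min = min(w[, 1]), col_min = min(w[, 2]),
            row_max = max(w[, 1]), col_max = max(w[, 2]))
  structure(list(binary = out, threshold_used = NA_real_,
                 component_label = as.integer(best), bbox = bbox),
            class = "diaphragm_mask")
}

# 8-connectivity labeling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally using a union over the label-adjacency
# graph.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2L || nc < 2L || max(lab) <= 1L) return(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]     # down-right diagonal pairs
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]    # down-left diagonal pairs
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  g <- igraph::graph_from_edgelist(apply(pairs, 2, as.character),
                                   directed = FALSE)
  comp <- igraph::components(g)
  remap <- seq_len(max(lab))
  members <- split(as.integer(igraph::V(g)$name), comp$membership)
  for (m in members) remap[m] <- min(m)
  # compress to consecutive labels
  used <- sort(unique(remap[sort(unique(lab[lab > 0]))]))
  final <- integer(max(lab))
  final[used] <- seq_along(used)
  out <- lab
  out[lab > 0] <- final[remap[lab[lab > 0]]]
  out
}

#' Segment the diaphragm band in the first frame
#'
#' Convenience wrapper: 3x3 mean filter, automatic (or manual)
#' threshold, binary segmentation, largest-component selection.
#'
#' @param frame numeric matrix (frame 0 of the loop).
#' @param manual_threshold optional manual threshold.
#' @return a `diaphragm_mask` with `threshold_used` filled in.
#' @export
segment_diaphragm <- function(frame, manual_threshold = NULL) {
  filt <- mean_filter_3x3(frame)
  T <- select_threshold(filt, manual = manual_threshold)
  mask <- largest_component(threshold_segment(filt, T))
  mask$threshold_used <- T
  mask
}

#' Seed random tracking points inside the diaphragm mask
#'
#' Samples `n` distinct integer pixel positions uniformly without
#' replacement from the white pixels of the mask (all of which lie
#' inside its bounding box). When fewer than `n` white pixels exist,
#' all of them are used and a warning is issued.
#'
#' @param mask a `diaphragm_mask`.
#' @param n number of points to seed (default 300).
#' @param seed RNG seed for reproducibility.
#' @return a `seed_points` object: list with `coords` (n x 2 matrix of
#'   `(row, col)`), `n_requested`, `seed`, and logical `kept_mask`
#'   (all `TRUE` until [dbscan_filter()] runs).
#' @export
seed_random_points <- function(mask, n = 300L, seed = 1L) {
  white <- which(mask$binary == 255, arr.ind = TRUE)
  if (nrow(white) == 0L) stop("mask has no white pixels", call. = FALSE)
  if (nrow(white) < n) {
    warning("mask has only ", nrow(white), " white pixels; using all ",
            "of them instead of ", n, call. = FALSE)
    idx <- seq_len(nrow(white))
  } else {
    idx <- withr::with_seed(seed, sample.int(nrow(white), n))
  }
  coords <- white[idx, , drop = FALSE]
  dimnames(coords) <- list(NULL, c("row", "col"))
  structure(list(coords = coords, n_requested = as.integer(n),
                 seed = as.integer(seed),
                 kept_mask = rep(TRUE, nrow(coords))),
            class = "seed_points")
}

#' DBSCAN clustering of 2-D points
#'
#' Density-based spatial clustering (Euclidean metric) following the
#' published algorithm: a point with at least `min_pts` neighbors within
#' `eps` (itself included) is a core point; clusters grow by
#' density-reachability from core points; points reachable from no core
#' point are noise.
#'
#' @param coords numeric matrix of points, one row per point.
#' @param eps neighborhood radius in pixels.
#' @param min_pts minimum neighborhood size (the point itself counts).
#' @return integer vector of cluster labels, `0` for noise.
#' @export
dbscan_labels <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)          # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      if (core[p]) {
        for (q in nb[[p]]) {
          if (labels[q] == 0L) labels[q] <- cl
          if (!visited[q]) {
            visited[q] <- TRUE
            if (core[q]) queue <- c(queue, q)
          }
        }
      }
    }
  }
  labels
}

#' Remove stray seed points with DBSCAN
#'
#' Clusters the seeded points and keeps only the largest cluster: seed
#' points that fell on bright speckle outside the coherent diaphragm
#' band form sparse groups or isolated noise and are discarded. Ties in
#' cluster size are broken in favor of the cluster containing the
#' point of smallest index.
#'
#' @param points a `seed_points` object.
#' @param eps DBSCAN radius in pixels (default 15).
#' @param min_pts DBSCAN density floor (default 10).
#' @param keep_all_clusters if `TRUE`, keep every non-noise cluster
#'   instead of only the largest.
#' @return the same `seed_points` with `kept_mask` updated; coordinates
#'   are never altered.
#' @export
dbscan_filter <- function(points, eps = 15, min_pts = 10,
                          keep_all_clusters = FALSE) {
  coords <- points$coords
  if (nrow(coords) < 1L) stop("no points to filter", call. = FALSE)
  labels <- dbscan_labels(coords, eps, min_pts)
  if (all(labels == 0L)) {
    stop("DBSCAN classified every point as noise; ",
         "increase eps or decrease min_pts", call. = FALSE)
  }
  if (keep_all_clusters) {
    points$kept_mask <- labels > 0L
  } else {
    sizes <- tabulate(labels)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      first_idx <- vapply(best, function(l) min(which(labels == l)),
                          integer(1))
      best <- best[which.min(first_idx)]
    }
    points$kept_mask <- labels == best
  }
  points$dbscan_labels <- labels
  points
}

#' Coordinates of the kept seed points
#' @param points a `seed_points` object.
#' @return matrix of `(row, col)` coordinates with `kept_mask == TRUE`.
#' @export
kept_points <- function(points) {
  points$coords[points$kept_mask, , drop = FALSE]
}
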