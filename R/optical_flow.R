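#' Spatial and temporal image gradients
#'
#' Computes the gradients entering the Lucas-Kanade normal equations:
#' `Ix` (horizontal, along columns) and `Iy` (vertical, along rows) by
#' central differences on `frame_t` with one-sided differences at the
#' borders, and the temporal derivative `It = frame_t1 - frame_t`.
#'
#' @param frame_t,frame_t1 numeric matrices of equal dimensions.
#' @return list with matrices `Ix`, `Iy`, `It`.
#' @export
image_gradients <- function(frame_t, frame_t1) {
  if (!all(dim(frame_t) == dim(frame_t1))) {
    stop("frames have mismatched dimensions", call. = FALSE)
  }
  nr <- nrow(frame_t); nc <- ncol(frame_t)
  Ix <- matrix(0, nr, nc)
  Iy <- matrix(0, nr, nc)
  if (nc >= 3L) {
    Ix[, 2:(nc - 1)] <- (frame_t[, 3:nc] - frame_t[, 1:(nc - 2)]) / 2
  }
  Ix[, 1] <- frame_t[, 2] - frame_t[, 1]
  Ix[, nc] <- frame_t[, nc] - frame_t[, nc - 1]
  if (nr >= 3L) {
    Iy[2:(nr - 1), ] <- (frame_t[3:nr, ] - frame_t[1:(nr - 2), ]) / 2
  }
  Iy[1, ] <- frame_t[2, ] - frame_t[1, ]
  Iy[nr, ] <- frame_t[nr, ] - frame_t[nr - 1, ]
  list(Ix = Ix, Iy = Iy, It = frame_t1 - frame_t)
}

#' Lucas-Kanade flow at a single point
#'
#' Solves the local least-squares flow over an `m` x `m` window
#' centered at the point (rounded to the nearest pixel, window clipped
#' to the frame): structure matrix
#' `[[sum(Ix^2), sum(Ix*Iy)], [sum(Ix*Iy), sum(Iy^2)]]`, right-hand
#' side `[-sum(Ix*It), -sum(Iy*It)]`. Degeneracy is signalled through
#' the `valid` flag, never as an error: the window is rejected when the
#' smaller eigenvalue of the structure matrix falls below
#' `min_eig_floor * m^2` or its condition number exceeds `max_cond`.
#'
#' @param Ix,Iy,It gradient matrices from [image_gradients()].
#' @param point numeric `(row, col)` position.
#' @param m odd window side length (>= 3).
#' @param min_eig_floor per-pixel floor on the smaller eigenvalue.
#' @param max_cond cap on the structure-matrix condition number.
#' @return list with `u` (horizontal, pixels/frame), `v` (vertical),
#'   and logical `valid`.
#' @export
lk_point_flow <- function(Ix, Iy, It, point, m = 15L,
                          min_eig_floor = 1e-4, max_cond = 1e6) {
  stopifnot(m %% 2 == 1, m >= 3)
  h <- m %/% 2
  r <- round(point[1]); c <- round(point[2])
  rows <- max(1, r - h):min(nrow(Ix), r + h)
  cols <- max(1, c - h):min(ncol(Ix), c + h)
  wx <- Ix[rows, cols]; wy <- Iy[rows, cols]; wt <- It[rows, cols]
  gxx <- sum(wx * wx); gxy <- sum(wx * wy); gyy <- sum(wy * wy)
  tr <- gxx + gyy
  det <- gxx * gyy - gxy * gxy
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  lmin <- tr / 2 - disc; lmax <- tr / 2 + disc
  if (lmin < min_eig_floor * m^2 ||
      !is.finite(det) || det <= 0 || lmax / lmin > max_cond) {
    return(list(u = NA_real_, v = NA_real_, valid = FALSE))
  }
  bx <- -sum(wx * wt); by <- -sum(wy * wt)
  list(u = (gyy * bx - gxy * by) / det,
       v = (-gxy * bx + gxx * by) / det,
       valid = TRUE)
}

# Downsample by 2: 3x3 mean filter then decimation. Level-l coordinates
# relate to full-resolution ones by p_l = (p - 1) / 2^l + 1.
.pyr_down <- function(img) {
  f <- mean_filter_3x3(img)
  f[seq(1, nrow(f), by = 2), seq(1, ncol(f), by = 2), drop = FALSE]
}

.build_pyramid <- function(img, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- img
  for (l in seq_len(levels - 1L)) {
    prev <- pyr[[l]]
    if (nrow(prev) < 8L || ncol(prev) < 8L) {
      pyr <- pyr[seq_len(l)]
      break
    }
    pyr[[l + 1L]] <- .pyr_down(prev)
  }
  pyr
}

#' Track seed points through a frame sequence
#'
#' Pyramidal Lucas-Kanade point tracking. Every frame is pre-filtered
#' with the 3x3 averaging filter; for each consecutive frame pair a
#' coarse-to-fine image pyramid relaxes the small-motion assumption
#' (`pyramid_levels = 1` is the plain single-window solution), and each
#' point is advanced by its estimated flow, with sub-pixel positions
#' maintained through bilinear intensity sampling. Points whose window
#' becomes degenerate or that exit the frame are invalidated and stay
#' invalid.
#'
#' @param seq a [frame_sequence].
#' @param seeds a `seed_points` object; only kept points are tracked.
#' @param m odd window side length (default 15).
#' @param pyramid_levels number of pyramid levels (default 3).
#' @param iterations Newton refinement steps per level (default 3).
#' @param min_eig_floor,max_cond degeneracy thresholds, see
#'   [lk_point_flow()].
#' @return a `tracked_points` object: list with `traj` (points x
#'   frames x 2 array of `(row, col)`), `valid` (points x frames
#'   logical), `group_id` (filled by [assign_groups()]), `window_m`.
#' @export
track_sequence <- function(seq, seeds, m = 15L, pyramid_levels = 3L,
                           iterations = 3L, min_eig_floor = 1e-4,
                           max_cond = 1e6) {
  stopifnot(inherits(seq, "frame_sequence"), m %% 2 == 1, m >= 3)
  pts <- kept_points(seeds)
  k <- nrow(pts)
  if (k == 0L) stop("no kept seed points to track", call. = FALSE)
  nf <- n_frames(seq)
  nr <- nrow(seq$frames[[1]]); nc <- ncol(seq$frames[[1]])

  traj <- array(NA_real_, c(k, nf, 2L))
  valid <- matrix(FALSE, k, nf)
  traj[, 1, ] <- pts
  valid[, 1] <- TRUE

  pos <- matrix(as.numeric(pts), k, 2)
  pyr1 <- .build_pyramid(mean_filter_3x3(seq$frames[[1]]), pyramid_levels)
  grad1 <- lapply(pyr1, function(im) image_gradients(im, im)[c("Ix", "Iy")])

  for (f in seq_len(nf - 1L)) {
    pyr0 <- pyr1
    grad0 <- grad1
    pyr1 <- .build_pyramid(mean_filter_3x3(seq$frames[[f + 1L]]),
                           pyramid_levels)
    grad1 <- lapply(pyr1, function(im) image_gradients(im, im)[c("Ix", "Iy")])
    levels <- min(length(pyr0), length(pyr1))

    live <- which(valid[, f])
    if (length(live) == 0L) {
      stop("all tracking points lost before frame ", f, call. = FALSE)
    }
    p0 <- pos[live, , drop = FALSE]
    g <- matrix(0, length(live), 2)
    ok <- rep(TRUE, length(live))
    for (l in seq(levels, 1L)) {
      scale <- 2^(l - 1L)
      pl <- (p0 - 1) / scale + 1
      res <- cpp_lk_level(pyr0[[l]], pyr1[[l]],
                          grad0[[l]]$Ix, grad0[[l]]$Iy,
                          pl, g / scale, as.integer(m),
                          as.integer(iterations),
                          min_eig_floor, max_cond)
      ok <- ok & res[, 3] > 0
      g <- res[, 1:2, drop = FALSE] * scale
    }
    p1 <- p0 + g
    inb <- p1[, 1] >= 1 & p1[, 1] <= nr & p1[, 2] >= 1 & p1[, 2] <= nc
    ok <- ok & inb
    pos[live[ok], ] <- p1[ok, , drop = FALSE]
    traj[live[ok], f + 1L, ] <- p1[ok, , drop = FALSE]
    valid[live[ok], f + 1L] <- TRUE
  }
  if (!any(valid[, nf])) {
    stop("all tracking points lost before the final frame", call. = FALSE)
  }
  structure(list(traj = traj, valid = valid, group_id = NULL,
                 window_m = as.integer(m)),
            class = "tracked_points")
}

#' Partition tracked points into groups along the band
#'
#' Sorts points by their frame-0 column (ties by row) and cuts the
#' order into `k` contiguous, size-balanced groups, so that the chain
#' of group centroids runs along the band's dominant axis and the sum
#' of centroid-to-centroid distances approximates the band length.
#'
#' @param tracked a `tracked_points` object.
#' @param k number of groups (default 15).
#' @return `tracked` with `group_id` (integer in `1..k` per point) set.
#' @export
assign_groups <- function(tracked, k = 15L) {
  n <- nrow(tracked$traj)
  if (sum(tracked$valid[, 1]) < k) {
    stop("need at least ", k, " valid points to form groups",
         call. = FALSE)
  }
  ord <- order(tracked$traj[, 1, 2], tracked$traj[, 1, 1])
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  gid <- integer(n)
  gid[ord] <- rep(seq_len(k), times = sizes)
  tracked$group_id <- gid
  tracked$k_groups <- as.integer(k)
  tracked
}

#' Group centroids at one frame
#'
#' Mean `(row, col)` position of each group's valid points at the given
#' frame, ordered by group id (left to right along the band).
#'
#' @param tracked a grouped `tracked_points` object.
#' @param frame frame index (1-based).
#' @return k x 2 matrix of centroids; rows are `NA` for groups with no
#'   valid point at that frame.
#' @export
group_centroids <- function(tracked, frame) {
  if (is.null(tracked$group_id)) {
    stop("points have not been grouped; call assign_groups() first",
         call. = FALSE)
  }
  k <- tracked$k_groups
  out <- matrix(NA_real_, k, 2)
  for (g in seq_len(k)) {
    sel <- tracked$group_id == g & tracked$valid[, frame]
    if (any(sel)) {
      a <- tracked$traj[sel, frame, , drop = FALSE]
      out[g, ] <- c(mean(a[, 1, 1]), mean(a[, 1, 2]))
    }
  }
  out
}
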