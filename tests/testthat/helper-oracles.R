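# Independent brute-force oracles used to validate the vectorized /
# compiled implementations. These deliberately use the slowest, most
# literal formulation of each operation.

# 3x3 mean by explicit nested loops with edge replication
oracle_mean3 <- function(f) {
  nr <- nrow(f); nc <- ncol(f)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      acc <- 0
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- min(max(r + dr, 1), nr)
          cc <- min(max(c + dc, 1), nc)
          acc <- acc + f[rr, cc]
        }
      }
      out[r, c] <- acc / 9
    }
  }
  out
}

# connected components by recursive flood fill (8-connectivity)
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (!mask[r0, c0] || lab[r0, c0] > 0L) next
      cur <- cur + 1L
      stack <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) {
          for (dc in -1:1) {
            rr <- p[1] + dr; cc <- p[2] + dc
            if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
                mask[rr, cc] && lab[rr, cc] == 0L) {
              lab[rr, cc] <- cur
              stack[[length(stack) + 1L]] <- c(rr, cc)
            }
          }
        }
      }
    }
  }
  lab
}

# DBSCAN by the neighbor-graph definition: core points are clustered
# as connected components of the "within eps, both core" graph; border
# points attach to any cluster with a core point within eps; the rest
# is noise. Returns list(core_partition, is_noise, core, nb) so tests
# can compare partitions up to label permutation and check border
# membership is *a* legal assignment.
oracle_dbscan <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  lab <- integer(n)
  cur <- 0L
  for (i in which(core)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    stack <- i
    lab[i] <- cur
    while (length(stack)) {
      p <- stack[1]
      stack <- stack[-1]
      for (q in intersect(nb[[p]], which(core))) {
        if (lab[q] == 0L) {
          lab[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  is_noise <- !core & vapply(seq_len(n), function(i) {
    !any(core[nb[[i]]])
  }, logical(1))
  list(core_labels = lab, core = core, is_noise = is_noise, nb = nb)
}

# LK normal equations assembled by explicit loops over the window
oracle_lk <- function(Ix, Iy, It, point, m) {
  h <- m %/% 2
  r <- round(point[1]); c <- round(point[2])
  gxx <- gxy <- gyy <- bx <- by <- 0
  for (i in -h:h) {
    for (j in -h:h) {
      rr <- r + i; cc <- c + j
      if (rr < 1 || rr > nrow(Ix) || cc < 1 || cc > ncol(Ix)) next
      gxx <- gxx + Ix[rr, cc]^2
      gxy <- gxy + Ix[rr, cc] * Iy[rr, cc]
      gyy <- gyy + Iy[rr, cc]^2
      bx <- bx - Ix[rr, cc] * It[rr, cc]
      by <- by - Iy[rr, cc] * It[rr, cc]
    }
  }
  uv <- solve(matrix(c(gxx, gxy, gxy, gyy), 2), c(bx, by))
  list(u = uv[1], v = uv[2])
}

# sliding-window mean with edge replication
oracle_smooth <- function(x, k) {
  h <- k %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- pmin(pmax((i - h):(i + h), 1), n)
    mean(x[idx])
  }, numeric(1))
}

# small, fast phantom used across test files
tiny_phantom <- function(seed = 1L, n_frames = 26L, ...) {
  phantom_spec(image_size = c(90L, 120L), n_frames = n_frames,
               breath_period = 2, frame_interval = 0.08,
               seed = seed, ...)
}

# pure integer-translation speckle pair rendered from a static phantom
# frame using exact index shifting (no interpolation)
shift_pair <- function(seed, dr, dc, nr = 100L, nc = 120L) {
  tex <- withr::with_seed(seed, {
    M <- matrix(stats::rnorm((nr + 40) * (nc + 40)), nr + 40, nc + 40)
    as.matrix(EBImage::gblur(M, sigma = 1.5))
  })
  tex <- 120 + 60 * tex / stats::sd(tex)
  tex <- pmin(pmax(tex, 0), 255)
  f0 <- tex[21:(20 + nr), 21:(20 + nc)]
  f1 <- tex[(21 - dr):(20 + nr - dr), (21 - dc):(20 + nc - dc)]
  list(f0 = f0, f1 = f1)
}
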