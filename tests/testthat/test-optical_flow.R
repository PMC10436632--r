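test_that("gradients are exact on ramps and match the loop oracle", {
  ramp <- outer(rep(1, 12), 3 * (1:12))   # f(x, y) = 3x along columns
  g <- image_gradients(ramp, ramp)
  expect_equal(g$Ix[3:10, 3:10], matrix(3, 8, 8))
  expect_equal(g$Iy, matrix(0, 12, 12))
  expect_equal(g$It, matrix(0, 12, 12))

  g5 <- image_gradients(ramp, ramp + 5)
  expect_equal(g5$It, matrix(5, 12, 12))

  expect_error(image_gradients(ramp, ramp[1:5, ]), "mismatch")

  withr::with_seed(41, {
    a <- matrix(runif(100, 0, 255), 10, 10)
    b <- matrix(runif(100, 0, 255), 10, 10)
    g <- image_gradients(a, b)
    for (r in 2:9) {
      for (c in 2:9) {
        expect_equal(g$Ix[r, c], (a[r, c + 1] - a[r, c - 1]) / 2)
        expect_equal(g$Iy[r, c], (a[r + 1, c] - a[r - 1, c]) / 2)
      }
    }
    expect_equal(g$It, b - a)
  })
})

test_that("single-point LK matches the loop-assembled normal equations", {
  withr::with_seed(43, {
    for (i in 1:100) {
      a <- matrix(runif(900, 0, 255), 30, 30)
      b <- a + matrix(rnorm(900, 0, 3), 30, 30)
      g <- image_gradients(a, b)
      pt <- c(sample(8:22, 1), sample(8:22, 1))
      m <- sample(c(5, 7, 9), 1)
      got <- lk_point_flow(g$Ix, g$Iy, g$It, pt, m = m)
      ora <- oracle_lk(g$Ix, g$Iy, g$It, pt, m)
      expect_true(got$valid)
      expect_equal(got$u, ora$u, tolerance = 1e-10)
      expect_equal(got$v, ora$v, tolerance = 1e-10)
    }
  })
})

test_that("LK flags degenerate windows instead of erroring", {
  flat <- matrix(100, 20, 20)
  g <- image_gradients(flat, flat)
  res <- lk_point_flow(g$Ix, g$Iy, g$It, c(10, 10), m = 9)
  expect_false(res$valid)

  withr::with_seed(44, {
    a <- matrix(runif(400, 0, 255), 20, 20)
    g0 <- image_gradients(a, a)   # It = 0: zero flow on any texture
    res0 <- lk_point_flow(g0$Ix, g0$Iy, g0$It, c(10, 10), m = 9)
    expect_true(res0$valid)
    expect_equal(res0$u, 0)
    expect_equal(res0$v, 0)
  })
})

test_that("a half-pixel blob shift is recovered at the flank", {
  blob <- function(cx) {
    outer(seq_len(64), seq_len(64), function(r, c) {
      200 * exp(-((r - 32)^2 + (c - cx)^2) / (2 * 6^2))
    })
  }
  g <- image_gradients(blob(32), blob(32.5))
  res <- lk_point_flow(g$Ix, g$Iy, g$It, c(32, 38), m = 9)
  expect_true(res$valid)
  expect_lt(abs(res$u - 0.5), 0.15)
  expect_lt(abs(res$v), 0.1)
})

test_that("static sequences give constant trajectories", {
  ph <- render_phantom(tiny_phantom(seed = 2, n_frames = 6L,
                                    translation_amplitude_h = 0,
                                    translation_amplitude_v = 0,
                                    strain_amplitude = 0))
  seeds <- dbscan_filter(seed_random_points(
    segment_diaphragm(ph$seq$frames[[1]]), 60, seed = 2))
  tr <- track_sequence(ph$seq, seeds)
  expect_true(all(tr$valid))
  for (f in 2:6) {
    expect_equal(tr$traj[, f, ], tr$traj[, 1, ], tolerance = 1e-6)
  }
})

test_that("integer speckle translations are recovered within 0.25 px", {
  for (seed in 1:3) {
    shifts <- withr::with_seed(100 + seed,
                               list(c(sample(-3:3, 1), sample(-3:3, 1))))[[1]]
    pair <- shift_pair(seed, shifts[1], shifts[2])
    sq <- frame_sequence(list(pair$f0, pair$f1), 0.04)
    pts <- withr::with_seed(seed, cbind(sample(30:70, 40, TRUE),
                                        sample(30:90, 40, TRUE)))
    seeds <- structure(list(coords = pts, n_requested = 40L, seed = seed,
                            kept_mask = rep(TRUE, 40)),
                       class = "seed_points")
    tr <- track_sequence(sq, seeds)
    d <- tr$traj[, 2, ] - tr$traj[, 1, ]
    expect_lt(abs(mean(d[, 1], na.rm = TRUE) - shifts[1]), 0.25)
    expect_lt(abs(mean(d[, 2], na.rm = TRUE) - shifts[2]), 0.25)
  }
})

test_that("tracking a reversed sequence undoes the forward run", {
  ph <- render_phantom(tiny_phantom(seed = 5))
  seeds <- dbscan_filter(seed_random_points(
    segment_diaphragm(ph$seq$frames[[1]]), 100, seed = 5))
  fwd <- track_sequence(ph$seq, seeds)
  nf <- n_frames(ph$seq)
  back_seeds <- seeds
  back_seeds$coords <- fwd$traj[, nf, ]
  back_seeds$kept_mask <- rep(TRUE, nrow(back_seeds$coords))
  bwd <- track_sequence(frame_sequence(rev(ph$seq$frames),
                                       ph$seq$frame_interval), back_seeds)
  ret <- bwd$traj[, nf, ]
  rms <- sqrt(mean(rowSums((ret - kept_points(seeds))^2), na.rm = TRUE))
  expect_lt(rms, 0.3)
})

test_that("flow recovery degrades monotonically with additive noise", {
  err_at_sigma <- function(sigma) {
    errs <- vapply(1:10, function(seed) {
      pair <- shift_pair(200 + seed, 1, 2)
      add <- function(f) {
        pmin(pmax(f + withr::with_seed(
          300 + seed, matrix(rnorm(length(f), 0, sigma), nrow(f))), 0), 255)
      }
      sq <- frame_sequence(list(add(pair$f0), add(pair$f1)), 0.04)
      pts <- withr::with_seed(seed, cbind(sample(30:70, 25, TRUE),
                                          sample(30:90, 25, TRUE)))
      seeds <- structure(list(coords = pts, n_requested = 25L,
                              seed = seed, kept_mask = rep(TRUE, 25)),
                         class = "seed_points")
      tr <- track_sequence(sq, seeds)
      d <- tr$traj[, 2, ] - tr$traj[, 1, ]
      sqrt((mean(d[, 1], na.rm = TRUE) - 1)^2 +
             (mean(d[, 2], na.rm = TRUE) - 2)^2)
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(0, 5, 10, 20), err_at_sigma, numeric(1))
  expect_true(all(diff(errs) >= -0.02))  # non-decreasing in expectation
})

test_that("groups are contiguous, balanced, and ordered along the band", {
  # 30 collinear, equally spaced points
  coords <- cbind(rep(50, 30), seq(10, 97, by = 3))
  traj <- array(NA_real_, c(30, 2, 2))
  traj[, 1, ] <- coords
  traj[, 2, ] <- coords
  tr <- structure(list(traj = traj, valid = matrix(TRUE, 30, 2),
                       group_id = NULL, window_m = 15L),
                  class = "tracked_points")
  g15 <- assign_groups(tr, 15)
  expect_true(all(table(g15$group_id) == 2))
  cents <- group_centroids(g15, 1)
  expect_true(all(diff(cents[, 2]) > 0))   # left-to-right ordering
  # adjacent in sort order -> same or adjacent group
  ord <- order(coords[, 2])
  expect_true(all(diff(g15$group_id[ord]) %in% c(0L, 1L)))

  g30 <- assign_groups(tr, 30)
  expect_equal(group_centroids(g30, 1)[order(coords[, 2]), ],
               coords[order(coords[, 2]), ], ignore_attr = TRUE)

  tr$valid[, 1] <- c(rep(TRUE, 10), rep(FALSE, 20))
  expect_error(assign_groups(tr, 15), "at least 15")
})
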