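make_tracked <- function(traj, valid = NULL) {
  k <- dim(traj)[1]; nf <- dim(traj)[2]
  if (is.null(valid)) valid <- matrix(TRUE, k, nf)
  structure(list(traj = traj, valid = valid, group_id = NULL,
                 window_m = 15L), class = "tracked_points")
}

test_that("displacement curves average point motion and accumulate", {
  # all points translate by (+2 col, -1 row) per frame
  nf <- 11L
  base <- cbind(rep(30, 8), seq(10, 45, by = 5))
  traj <- array(NA_real_, c(8, nf, 2))
  for (f in seq_len(nf)) {
    traj[, f, 1] <- base[, 1] - (f - 1)
    traj[, f, 2] <- base[, 2] + 2 * (f - 1)
  }
  cv <- displacement_curves(make_tracked(traj), 0.04)
  expect_equal(cv$interframe_h[-1], rep(2, nf - 1))
  expect_equal(cv$interframe_v[-1], rep(-1, nf - 1))
  expect_equal(cv$cumulative_h[nf], 20)
  expect_equal(cv$cumulative_v[nf], -10)
  expect_equal(cv$time, 0.04 * (0:10))

  static <- array(rep(base, nf), c(8, 2, nf))
  static <- aperm(static, c(1, 3, 2))
  cv0 <- displacement_curves(make_tracked(static), 0.04)
  expect_true(all(cv0$interframe_h == 0 & cv0$cumulative_v == 0))
})

test_that("displacement curves match the per-point loop oracle", {
  withr::with_seed(51, {
    k <- 12L; nf <- 9L
    traj <- array(runif(k * nf * 2, 10, 90), c(k, nf, 2))
    valid <- matrix(runif(k * nf) > 0.1, k, nf)
    valid[, 1] <- TRUE
    for (f in 2:nf) valid[, f] <- valid[, f] & valid[, f - 1]
    if (!all(colSums(valid) > 0)) valid[1, ] <- TRUE
    cv <- displacement_curves(make_tracked(traj, valid), 0.1)
    for (f in 2:nf) {
      h <- v <- c(); n <- 0
      for (p in 1:k) {
        if (valid[p, f] && valid[p, f - 1]) {
          v <- c(v, traj[p, f, 1] - traj[p, f - 1, 1])
          h <- c(h, traj[p, f, 2] - traj[p, f - 1, 2])
        }
      }
      expect_equal(cv$interframe_h[f], mean(h))
      expect_equal(cv$interframe_v[f], mean(v))
    }
  })
})

test_that("cumulative displacement is exactly the running interframe sum", {
  withr::with_seed(52, {
    traj <- array(runif(10 * 20 * 2, 5, 95), c(10, 20, 2))
    cv <- displacement_curves(make_tracked(traj), 0.05)
    expect_identical(cv$cumulative_h, cumsum(cv$interframe_h))
    expect_identical(cv$cumulative_v, cumsum(cv$interframe_v))
  })
})

test_that("band length is the chord sum of the centroid chain", {
  collinear <- cbind(rep(10, 15), seq(0, 28, by = 2))
  expect_equal(band_length(collinear), 28)
  expect_equal(band_length(matrix(5, 15, 2)), 0)

  theta <- seq(0, pi / 2, length.out = 15)
  arc <- cbind(50 * sin(theta), 50 * cos(theta))
  chord_oracle <- sum(vapply(1:14, function(i) {
    sqrt(sum((arc[i + 1, ] - arc[i, ])^2))
  }, numeric(1)))
  expect_equal(band_length(arc), chord_oracle)
  expect_lt(band_length(arc), 50 * pi / 2)          # below arc length
  expect_gt(band_length(arc), 0.99 * 50 * pi / 2)   # within 1%

  bad <- collinear
  bad[3, 1] <- NA
  expect_error(band_length(bad), "invalid")
})

test_that("global strain follows its defining ratio", {
  expect_equal(global_strain(100, 100), 0)
  expect_equal(global_strain(90, 100), -10)
  expect_equal(global_strain(112.43, 100), 12.43)
  expect_error(global_strain(50, 0), "L\\(0\\)")
})

test_that("uniform-kernel smoothing preserves constants and spreads impulses", {
  expect_equal(smooth_curve(rep(3.5, 40)), rep(3.5, 40))
  imp <- rep(0, 41)
  imp[21] <- 1
  sm <- smooth_curve(imp, 5)
  expect_equal(sm[19:23], rep(0.2, 5))
  expect_equal(sum(sm), 1)
  expect_warning(out <- smooth_curve(c(1, 2, 3), 5), "shorter")
  expect_equal(out, c(1, 2, 3))

  withr::with_seed(53, {
    x <- rnorm(60)
    expect_equal(smooth_curve(x, 5), oracle_smooth(x, 5), tolerance = 1e-10)
    expect_equal(smooth_curve(x, 7), oracle_smooth(x, 7), tolerance = 1e-10)
  })
})

test_that("cycle detection recovers the period of periodic curves", {
  t <- 0:199
  s <- sin(2 * pi * t / 50)
  cyc <- detect_cycles(s, 0.04)
  expect_equal(cyc$period_T, 2.0, tolerance = 0.04 / 2.0)
  # peaks and troughs strictly interleave
  ext <- sort(c(cyc$peaks, cyc$troughs))
  kind <- ext %in% cyc$peaks
  expect_true(all(diff(kind) != 0))

  # single peak/trough pair 15 samples apart at 0.1 s/sample
  x <- c(seq(0, 1, length.out = 11),
         seq(1, -1, length.out = 16)[-1],
         seq(-1, 0, length.out = 11)[-1])
  cyc2 <- detect_cycles(x, 0.1)
  expect_equal(cyc2$peaks, 11L)
  expect_equal(cyc2$troughs, 26L)
  expect_equal(cyc2$period_T, 3.0)

  expect_error(detect_cycles(rep(1, 50), 0.1), "extrema|breathing")
  expect_error(detect_cycles(seq(0, 1, length.out = 50), 0.1), "breathing")
})

test_that("cycle detection tolerates noise on the curve", {
  for (seed in 1:10) {
    s <- withr::with_seed(600 + seed, {
      t <- 0:249
      sin(2 * pi * t / 50) + rnorm(250, 0, 0.05)
    })
    cyc <- detect_cycles(smooth_curve(s, 5), 0.04)
    expect_lt(abs(cyc$period_T - 2.0) / 2.0, 0.1)
  }
})

test_that("drift correction removes ramps, fixes cycle ends, and is idempotent", {
  t <- (0:99) * 0.05
  ramp <- 0.7 * t
  expect_equal(drift_correct(ramp, 2.0, 0.05), rep(0, 100))

  periodic <- sin(2 * pi * t / 2.0)   # S(T) = 0 at a sample
  expect_equal(drift_correct(periodic, 2.0, 0.05), periodic,
               tolerance = 1e-12)

  drifted <- periodic + 0.31 * t
  once <- drift_correct(drifted, 2.0, 0.05)
  twice <- drift_correct(once, 2.0, 0.05)
  expect_equal(twice, once, tolerance = 1e-12)
  iT <- which.min(abs(t - 2.0))
  expect_equal(once[iT], 0)

  expect_error(drift_correct(periodic, 10, 0.05), "not covered")
})

test_that("peak-to-peak per cycle matches the programmed amplitude", {
  t <- 0:299
  s <- 4.2 * sin(2 * pi * t / 60)
  cyc <- detect_cycles(s, 0.04)
  pk <- peak_to_peak(s, cyc)
  expect_true(all(abs(pk$per_cycle - 8.4) / 8.4 < 0.02))
  expect_equal(pk$mean, mean(pk$per_cycle))

  const_cyc <- structure(list(peaks = 10L, troughs = c(1L, 20L),
                              period_T = 1, source_curve = "x"),
                         class = "cycle_annotation")
  expect_equal(peak_to_peak(rep(2, 30), const_cyc)$per_cycle, 0)
})
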