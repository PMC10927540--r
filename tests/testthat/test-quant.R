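# Spot detection, linking, velocimetry, kymographs, colocalization,
# cluster segmentation and MSD analysis.

render_spot_frame <- function(xy, amp = 500, sigma = 0.15, n_px = 64,
                              px = 0.1, bg = 10) {
  xc <- (seq_len(n_px) - 0.5) * px
  f <- matrix(bg, n_px, n_px)
  for (i in seq_len(nrow(xy))) {
    f <- f + amp * exp(-(outer((xc - xy[i, 2])^2, (xc - xy[i, 1])^2,
                               "+")) / (2 * sigma^2))
  }
  f
}

test_that("single synthetic spots localize to sub-pixel accuracy", {
  f <- render_spot_frame(rbind(c(3.225, 2.875)))
  loc <- detect_spots(f, 0.1, expected_size = 4, threshold = 20)
  expect_equal(nrow(loc), 1)
  expect_lt(abs(loc$x - 3.225), 0.01)
  expect_lt(abs(loc$y - 2.875), 0.01)
  # empty frame
  loc0 <- detect_spots(matrix(10, 64, 64), 0.1, threshold = 20)
  expect_equal(nrow(loc0), 0)
  # two spots separated by 5 sigma_psf-scale widths
  f2 <- render_spot_frame(rbind(c(2, 2), c(2 + 5 * 0.15, 2)))
  loc2 <- detect_spots(f2, 0.1, expected_size = 3, threshold = 20)
  expect_equal(nrow(loc2), 2)
})

test_that("linking follows single and crossing tracks", {
  # one particle, ten frames
  loc <- data.frame(frame = 1:10, x = seq(1, 2, length.out = 10), y = 1)
  tr <- link_trajectories(loc, max_displacement = 0.5)
  expect_equal(length(unique(tr$particle)), 1)
  expect_equal(sum(tr$particle == 1), 10)
  # two converging-then-diverging tracks: per-step displacement (0.1)
  # well under the inter-track separation at closest approach (0.4)
  fr <- 1:21
  a <- data.frame(frame = fr, x = 0.1 * fr, y = 1 + 0.2)
  b <- data.frame(frame = fr, x = 0.1 * fr, y = 1 - 0.2)
  tr2 <- link_trajectories(rbind(a, b), max_displacement = 0.15)
  expect_equal(length(unique(tr2$particle)), 2)
  ok <- vapply(split(as.data.frame(tr2), tr2$particle),
               function(p) diff(range(p$y)) == 0, logical(1))
  expect_true(all(ok))
  # zero gate: every localization its own trajectory
  tr0 <- link_trajectories(loc, max_displacement = 0)
  expect_equal(length(unique(tr0$particle)), 10)
})

test_that("velocity maps return exact uniform translations and mask empty bins", {
  tt <- 0:20
  df <- data.frame(particle = 1, t = tt, x = 1 + 0.3 * tt,
                   y = 2 + 0.1 * tt, z = 0)
  tr <- trajectory_set(df, frame_interval = 1)
  vm <- velocity_map(tr, bin_size = 1)
  expect_true(all(abs(vm$vx - 0.3) < 1e-12))
  expect_true(all(abs(vm$vy - 0.1) < 1e-12))
  # bins that saw no steps are absent, not zero
  expect_false(any(vm$n == 0))
})

test_that("kymographs of static images have identical columns", {
  arr <- array(rep(render_spot_frame(rbind(c(3, 3))), 4), c(64, 64, 4))
  s <- image_series(arr, 0.1, 1)
  kym <- build_kymograph(s, rbind(c(1, 3), c(5, 3)))
  for (k in 2:4) expect_equal(kym$intensity[, k], kym$intensity[, 1])
  # line width does not change noiseless ridges on transversely flat data
  flat <- array(rep(matrix(seq(0, 1, length.out = 64), 64, 64,
                           byrow = TRUE), 3), c(64, 64, 3))
  sf <- image_series(flat, 0.1, 1)
  k1 <- build_kymograph(sf, rbind(c(1, 3), c(5, 3)), line_width = 1)
  k5 <- build_kymograph(sf, rbind(c(1, 3), c(5, 3)), line_width = 5)
  expect_equal(k1$intensity, k5$intensity, tolerance = 1e-10)
  expect_error(build_kymograph(s, rbind(c(-1, 3), c(5, 3))), "bounds")
})

test_that("kymograph ridge speeds are recovered across the nm/s range", {
  for (speed in c(2, 7.5, 20)) {
    cl <- data.frame(x0 = 4, y0 = 8, speed = speed, direction = 0,
                     sigma = 0.3, amplitude = 150)
    band <- list(center = c(10, 24), radius = 16, width = 2.5,
                 theta_range = c(-2.2, -0.9), intensity = 60)
    s <- generate_extended_series(band, cl, duration = 900,
                                  frame_interval = 10, fov = 20, seed = 1)
    kym <- build_kymograph(s, rbind(c(1, 8), c(14, 8)), line_width = 5)
    sp <- kymograph_feature_speed(kym, c(2.2, 3.8))
    expect_equal(sp$speed_nm_per_s, speed, tolerance = 0.05)
  }
})

test_that("time-reversing a kymograph negates the extracted speed", {
  cl <- data.frame(x0 = 4, y0 = 8, speed = 7.5, direction = 0,
                   sigma = 0.3, amplitude = 150)
  band <- list(center = c(10, 24), radius = 16, width = 2.5,
               theta_range = c(-2.2, -0.9), intensity = 60)
  s <- generate_extended_series(band, cl, duration = 600,
                                frame_interval = 10, fov = 20, seed = 2)
  kym <- build_kymograph(s, rbind(c(1, 8), c(14, 8)), line_width = 5)
  fwd <- kymograph_feature_speed(kym, c(2.2, 3.8))
  rev_kym <- kym
  rev_kym$intensity <- kym$intensity[, rev(seq_len(ncol(kym$intensity)))]
  bwd <- kymograph_feature_speed(rev_kym, range(fwd$positions) +
                                   c(-0.8, 0.8))
  expect_equal(bwd$speed_nm_per_s, -fwd$speed_nm_per_s, tolerance = 0.1)
})

test_that("Mander's coefficients honor identity, disjointness and rescaling", {
  A <- render_spot_frame(rbind(c(2, 2), c(4, 4)), bg = 0)
  B <- render_spot_frame(rbind(c(2, 2), c(4, 4)), bg = 0)
  r <- manders_coefficients(A, B, thresholds = c(5, 5),
                            background = c(0, 0))
  expect_equal(r$M1, 1, tolerance = 0.01)
  expect_equal(r$M2, 1, tolerance = 0.01)
  # disjoint supports
  Bd <- render_spot_frame(rbind(c(1.5, 5), c(5, 1.5)), bg = 0)
  rd <- manders_coefficients(A, Bd, thresholds = c(5, 5),
                             background = c(0, 0))
  expect_lt(rd$M1, 0.01)
  expect_lt(rd$M2, 0.01)
  # M1 invariant under linear rescaling of channel A
  r2 <- manders_coefficients(3 * A, B, thresholds = c(5, 5),
                             background = c(0, 0))
  expect_equal(r2$M1, r$M1, tolerance = 1e-12)
  expect_error(manders_coefficients(A * 0, B, thresholds = c(5, 5),
                                    background = c(0, 0)),
               "undefined")
})

test_that("cluster time courses track merge-only dynamics", {
  s <- generate_cluster_timelapse(n0 = 15, D_cluster = 0.05,
                                  coalescence_radius = 0.6,
                                  duration = 150, frame_interval = 5,
                                  noiseless = TRUE, seed = 2)
  tab <- cluster_timecourse(s, min_area = 0.05,
                            unit_intensity = attr(s, "unit_intensity"))
  counts <- tapply(tab$id, tab$frame, length)
  areas <- tapply(tab$area_um2, tab$frame, mean)
  truth_counts <- tapply(attr(s, "truth")$id, attr(s, "truth")$frame,
                         length)
  # segmentation may transiently fuse clusters that approach within the
  # optical resolution without coalescing; counts track the truth closely
  expect_gt(mean(counts == truth_counts), 0.7)
  expect_lte(max(abs(counts - truth_counts)), 2)
  expect_lt(counts[length(counts)], counts[1])
  expect_gt(areas[length(areas)], areas[1])
})

test_that("cluster copy numbers and degenerate cases behave", {
  # one spot of known integrated intensity: exact copy number
  unit <- 500
  arr <- array(0, c(64, 64, 1))
  xc <- (seq_len(64) - 0.5) * 0.1
  mass <- 5 * unit
  v <- 0.09
  arr[, , 1] <- mass * 0.01 / (2 * pi * v) *
    exp(-(outer((xc - 3)^2, (xc - 3)^2, "+")) / (2 * v))
  s <- image_series(arr, 0.1, 1)
  tab <- cluster_timecourse(s, threshold = 0.5, min_area = 0.05,
                            unit_intensity = unit)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$copies, 5)
  # min_area above the largest component: no clusters
  tab0 <- cluster_timecourse(s, threshold = 0.5, min_area = 1e3)
  expect_equal(nrow(tab0), 0)
  # all-background frames give empty rows, not an error
  sb <- image_series(array(7, c(16, 16, 2)), 0.1, 1)
  expect_equal(nrow(cluster_timecourse(sb)), 0)
})

test_that("MSD exponents separate diffusive from directed motion", {
  dt <- 0.1
  # ballistic track
  tt <- seq_len(60) * dt
  bal <- trajectory_set(data.frame(particle = 1, t = tt, x = 2 * tt,
                                   y = -1 * tt, z = 0),
                        frame_interval = dt)
  mb <- msd_exponent(bal)
  expect_equal(mb$alpha, 2, tolerance = 0.05)
  # stationary track
  st <- trajectory_set(data.frame(particle = 1, t = tt, x = 1, y = 1,
                                  z = 0), frame_interval = dt)
  ms <- msd_exponent(st)
  expect_lt(max(ms$msd), 1e-12)
  # Brownian ensemble: alpha ~ 1 over 50 independent walks
  set.seed(8)
  D <- 0.5
  walks <- do.call(rbind, lapply(1:50, function(i) {
    data.frame(particle = i, t = tt,
               x = cumsum(rnorm(60, sd = sqrt(2 * D * dt))),
               y = cumsum(rnorm(60, sd = sqrt(2 * D * dt))), z = 0)
  }))
  mw <- msd_exponent(trajectory_set(walks, frame_interval = dt))
  expect_equal(mw$alpha, 1, tolerance = 0.2)
  expect_equal(mw$D, D, tolerance = 0.2)
  expect_error(msd_exponent(trajectory_set(
    data.frame(particle = 1, t = tt[1:10], x = 1:10, y = 1, z = 0),
    frame_interval = dt)), "20 samples")
})
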