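# Synthetic image generators: conservation laws, closed forms, the
# finite-difference oracle, the noise model and reproducibility.

test_that("a non-diffusing spot renders identical noiseless frames", {
  s <- generate_punctual_series(spot_model(100, D = 0), n_frames = 5,
                                noiseless = TRUE, seed = 1)
  for (k in 2:5) {
    expect_identical(s$frames[, , k], s$frames[, , 1])
  }
})

test_that("integrated intensity is conserved while the spot spreads", {
  s <- generate_punctual_series(spot_model(200, D = 0.3), n_frames = 10,
                                fov = 16, noiseless = TRUE, seed = 1)
  bg_total <- 20 * prod(dim(s$frames)[1:2])
  masses <- apply(s$frames, 3, sum) - bg_total
  expect_lt(diff(range(masses)) / mean(masses), 1e-3)
})

test_that("the peak amplitude follows the closed-form decay", {
  # negligible PSF so the un-convolved expression applies exactly:
  # peak halves when 2 D t = sigma0^2
  sp <- spot_model(300, sigma0 = 0.5, D = 0.1)
  psf0 <- psf_model(wavelength = 1e-3)
  t_half <- sp$sigma0^2 / (2 * sp$D)
  n_frames <- 24
  fi <- t_half / 9.5  # place the half time between frame centers
  s <- generate_punctual_series(sp, psf = psf0, frame_interval = fi,
                                n_frames = n_frames, noiseless = TRUE,
                                seed = 1)
  peaks <- apply(s$frames, 3, max) - 20
  pred <- sp$amplitude * sp$sigma0^2 / (sp$sigma0^2 + 2 * sp$D *
                                          s$timestamps)
  expect_equal(peaks, pred, tolerance = 0.01)
  half_interp <- stats::approx(peaks / peaks[1] * pred[1] /
                                 sp$amplitude, s$timestamps, xout = 0.5)$y
  expect_equal(half_interp, t_half, tolerance = 0.05)
})

test_that("noiseless generator agrees with a finite-difference oracle", {
  # 64 x 64 grid; the oracle integrates the 2D diffusion equation from the
  # generator's own first frame
  D <- 0.048
  px <- 0.1
  s <- generate_punctual_series(spot_model(200, D = D), pixel_size = px,
                                fov = 6.4, n_frames = 10,
                                frame_interval = 0.13, noiseless = TRUE,
                                seed = 1)
  u0 <- s$frames[, , 1] - 20
  dt_fd <- 0.25 * px^2 / D * 0.8
  for (k in c(5, 10)) {
    el <- s$timestamps[k] - s$timestamps[1]
    n_steps <- round(el / dt_fd)
    u <- fd_diffuse(u0, D, px, el / n_steps, n_steps)
    ref <- s$frames[, , k] - 20
    err <- max(abs(u - ref)) / max(ref)
    expect_lt(err, 0.01)
  }
})

test_that("per-pixel noise variance is Poisson plus read noise", {
  sp <- spot_model(100, D = 0)
  renders <- vapply(seq_len(1000), function(i) {
    generate_punctual_series(sp, pixel_size = 0.4, fov = 2.4,
                             n_frames = 1, seed = i)$frames[, , 1]
  }, matrix(0, 6, 6))
  m <- apply(renders, c(1, 2), mean)
  v <- apply(renders, c(1, 2), var)
  pred <- m + 3^2
  expect_equal(mean(v / pred), 1, tolerance = 0.05)
})

test_that("generators are bit-reproducible given a seed", {
  a <- generate_punctual_series(spot_model(200, D = 0.05), seed = 42)
  b <- generate_punctual_series(spot_model(200, D = 0.05), seed = 42)
  expect_identical(a$frames, b$frames)
  c <- generate_punctual_series(spot_model(200, D = 0.05), seed = 43)
  expect_false(identical(a$frames, c$frames))
})

test_that("a spot spreading past the field is rejected", {
  expect_error(generate_punctual_series(spot_model(200, D = 5), fov = 4,
                                        n_frames = 30),
               "off the field")
})

test_that("FRAP holes recover monotonically and stay static at D = 0", {
  s0 <- generate_frap_series(150, spot_model(100, D = 0, sign = -1),
                             n_frames = 5, noiseless = TRUE, seed = 1)
  post <- which(s0$timestamps > 0)
  for (k in post[-1]) {
    expect_identical(s0$frames[, , k], s0$frames[, , post[1]])
  }
  s <- generate_frap_series(150, spot_model(120, D = 0.1, sign = -1),
                            n_frames = 20, noiseless = TRUE, seed = 1)
  ctr <- round(dim(s$frames)[1] / 2)
  center_trace <- s$frames[ctr, ctr, s$timestamps > 0]
  expect_true(all(diff(center_trace) > -1e-9))
  # approaches the plateau
  expect_gt(center_trace[20], 0.8 * (150 + 20))
  expect_error(generate_frap_series(100, spot_model(120, D = 0, sign = -1)),
               "amplitude")
})

test_that("extended-labeling clusters translate at their set speed", {
  cl <- data.frame(x0 = c(4, 12), y0 = c(8, 8.3), speed = c(7.5, 0),
                   direction = 0, sigma = 0.3, amplitude = 150)
  band <- list(center = c(10, 24), radius = 16, width = 2.5,
               theta_range = c(-2.2, -0.9), intensity = 0)
  s <- generate_extended_series(band, cl, duration = 900,
                                frame_interval = 30, fov = 20,
                                noiseless = TRUE, seed = 1)
  # moving cluster displaces speed * time = 6.75 um over 900 s
  first <- s$frames[, , 1]; last <- s$frames[, , dim(s$frames)[3]]
  row <- 80  # y = 7.95 um: the cluster row
  x_at <- function(f) (which.max(f[row, ]) - 0.5) * s$pixel_size
  disp <- x_at(last) - x_at(first)
  expected <- 7.5e-3 * (s$timestamps[dim(s$frames)[3]] - s$timestamps[1])
  expect_equal(disp, expected, tolerance = 0.05)
  # the static cluster's kymograph ridge is vertical
  kym <- build_kymograph(s, rbind(c(10, 8.3), c(14, 8.3)))
  ridge <- apply(kym$intensity, 2, which.max)
  expect_equal(max(ridge) - min(ridge), 0)
})

test_that("cluster time lapses conserve intensity and only merge", {
  s <- generate_cluster_timelapse(n0 = 15, D_cluster = 0.05,
                                  coalescence_radius = 0.6,
                                  duration = 150, frame_interval = 5,
                                  noiseless = TRUE, seed = 2)
  tr <- attr(s, "truth")
  counts <- tapply(tr$id, tr$frame, length)
  masses <- tapply(tr$mass, tr$frame, sum)
  sizes <- tapply(tr$sigma2, tr$frame, mean)
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[length(counts)], counts[1])  # merges actually happened
  expect_equal(diff(range(masses)), 0)
  expect_true(all(diff(sizes) >= -1e-12))
  # no coalescence: count constant
  s0 <- generate_cluster_timelapse(n0 = 8, D_cluster = 0.05,
                                   coalescence_radius = 0, duration = 60,
                                   frame_interval = 5, noiseless = TRUE,
                                   seed = 3)
  tr0 <- attr(s0, "truth")
  expect_true(all(tapply(tr0$id, tr0$frame, length) == 8))
})

test_that("infeasible colocalization designs are rejected", {
  d <- list(target_m1 = 0.9, target_m2 = 0.01, n_a = 100,
            spot_sigma = 0.2, amplitude = 1000, fov = 10)
  expect_error(generate_two_channel(d), "infeasible")
})
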