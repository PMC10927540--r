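# Brownian-advective tracer simulation, deposition and stroke width.

test_that("no flow and no diffusion leaves particles stationary", {
  f <- build_field(ref_geometry_6um(), flow_config(0, 0))
  tr <- simulate_tracers(f, n = 5, D = 0, dt = 1e-3, duration = 0.01,
                         seed = 1)
  for (p in split(as.data.frame(tr), tr$particle)) {
    expect_equal(diff(range(p$x)), 0)
    expect_equal(diff(range(p$y)), 0)
  }
})

test_that("flow-free Brownian motion reproduces the analytic MSD", {
  f <- build_field(ref_geometry_6um(), flow_config(0, 0))
  D_si <- 1e-12  # 1 um^2/s
  dt <- 1e-3
  tr <- simulate_tracers(f, n = 1000, D = D_si, dt = dt, duration = 0.05,
                         seed = 4)
  df <- as.data.frame(tr)
  # per-axis single-step MSD = 2 D dt; with n = 1000 particles x 50 steps
  # the estimate must lie within its 95% CI
  for (ax in c("x", "y", "z")) {
    d2 <- unlist(lapply(split(df[[ax]], df$particle), function(v) diff(v)^2))
    m <- mean(d2); se <- stats::sd(d2) / sqrt(length(d2))
    expect_lt(abs(m - 2 * 1 * dt), 1.96 * se + 1e-9)
  }
  # anomalous exponent of pure diffusion ~ 1
  m <- msd_exponent(tr)
  expect_equal(m$alpha, 1, tolerance = 0.2)
  expect_equal(m$D, 1, tolerance = 0.1)
})

test_that("binned step velocities reproduce the analytic field where measurable", {
  geo <- ref_geometry_6um()
  cfg <- flow_config(0.11, 0.11 / 0.27)
  f <- build_field(geo, cfg)
  D80 <- stokes_einstein(80)
  tr <- cached("tracers6", simulate_tracers(f, n = 1000, D = D80, dt = 1e-5,
                                            duration = 0.12, seed = 5))
  h <- geo$tip_height
  vm <- velocity_map(tr, bin_size = 0.5, min_steps = 20,
                     z_range = c(h - 0.5, h + 0.5))
  va <- field_velocity(f, cbind(vm$x, vm$y, h))
  sa <- sqrt(va[, 1]^2 + va[, 2]^2)
  # Brownian standard error of a bin's vector-mean velocity
  se <- sqrt(2 * D80 * 1e12 / 1e-5) / sqrt(vm$n)
  sel <- !attr(va, "near_singular") & vm$speed > 40 * se
  expect_gt(sum(sel), 3)
  rel <- abs(vm$speed[sel] - sa[sel]) / sa[sel]
  expect_lt(max(rel), 0.10)
})

test_that("confined tracers terminate at the aspiration opening", {
  geo <- ref_geometry_6um()
  f <- build_field(geo, flow_config(0.11, 0.11 / 0.27))
  tr <- cached("tracers_capture",
               simulate_tracers(f, n = 200, D = stokes_einstein(80),
                                dt = 1e-5, duration = 0.3, seed = 9))
  expect_gte(mean(attr(tr, "terminus") == "captured"), 0.99)
  expect_lt(max(sqrt(tr$x^2 + tr$y^2 + tr$z^2)), f$r_max)
})

test_that("too-coarse time steps are rejected", {
  f <- build_field(ref_geometry_6um(), flow_config(0.11, 0.11 / 0.27))
  expect_error(simulate_tracers(f, n = 1, D = 0, dt = 1, duration = 1),
               "too coarse")
})

test_that("deposition requires a substrate and zero sticking deposits nothing", {
  cfg <- ref_config(0.16, 0.3)
  expect_error(simulate_deposition(ref_geometry_6um(), cfg, n = 10,
                                   D = 1e-12, tip_path = rbind(c(0, 0), c(1, 0)),
                                   tip_speed = 1),
               "substrate")
  geo <- device_geometry(6, substrate_present = TRUE, tip_height = 2)
  depo <- simulate_deposition(geo, cfg, n = 30, D = stokes_einstein(200),
                              sticking_probability = 0,
                              tip_path = rbind(c(0, 0), c(2, 0)),
                              tip_speed = 2, dt = 2e-4, seed = 1)
  expect_equal(nrow(depo), 0)
  expect_error(simulate_deposition(geo, cfg, n = 5, D = 1e-12,
                                   tip_path = rbind(c(0, 0), c(1e4, 0)),
                                   tip_speed = 1),
               "simulation box")
})

test_that("a stationary tip writes a laterally centered spot", {
  geo <- device_geometry(6, substrate_present = TRUE, tip_height = 2)
  cfg <- ref_config(0.16, 0.3)
  depo <- cached("depo_stationary",
                 simulate_deposition(geo, cfg, n = 250,
                                     D = stokes_einstein(200),
                                     tip_path = rbind(c(0, 0), c(0.01, 0)),
                                     tip_speed = 0.002, dt = 2e-4,
                                     seed = 3))
  expect_gt(nrow(depo), 30)
  # flow is symmetric in y: deposit centroid on the axis within 0.5 um
  expect_lt(abs(mean(depo$y)), 0.5)
  # and between the openings in x
  expect_gt(mean(depo$x), -geo$tip_separation)
  expect_lt(mean(depo$x), 2 * geo$tip_separation)
})

test_that("stroke width recovers the FWHM of known transverse spreads", {
  set.seed(11)
  n <- 5000
  tip <- rbind(c(0, 0), c(40, 0))
  y <- rnorm(n, sd = 2)
  depo <- make_depo(runif(n, 0, 40), y, tip)
  sw <- stroke_width(depo, n_cross_sections = 10, bin_width = 0.4)
  expect_equal(sw$mean_fwhm, 2.355 * 2, tolerance = 0.1)
  # doubling every transverse coordinate doubles the width
  depo2 <- make_depo(depo$x, 2 * y, tip)
  sw2 <- stroke_width(depo2, n_cross_sections = 10, bin_width = 0.4)
  expect_equal(sw2$mean_fwhm / sw$mean_fwhm, 2, tolerance = 0.1)
  # deposits on a perfect line: FWHM collapses to the bin width
  depo0 <- make_depo(runif(200, 0, 40), rep(0, 200), tip)
  sw0 <- stroke_width(depo0, n_cross_sections = 5, bin_width = 0.4)
  expect_lte(sw0$mean_fwhm, 0.4 + 1e-9)
  # too few adsorbed particles is an error
  expect_error(stroke_width(make_depo(1:10, 1:10, tip)), "at least 50")
})
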