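# Diffusion estimators: self-consistency, parameter recovery, ensembles.

test_that("the Gaussian kernel recovers exact noiseless parameters", {
  sp <- spot_model(200, sigma0 = 0.4, D = 0.05)
  s <- generate_punctual_series(sp, n_frames = 3, noiseless = TRUE,
                                seed = 1)
  fits <- fit_gaussian_frames(s)
  psf_var <- psf_model()$sigma^2
  for (k in 1:3) {
    v_true <- sp$sigma0^2 + 2 * sp$D * s$timestamps[k] + psf_var
    a_true <- sp$amplitude * sp$sigma0^2 / v_true
    expect_equal(fits$var[k], v_true, tolerance = 1e-6)
    expect_equal(fits$amplitude[k], a_true, tolerance = 1e-6)
    expect_equal(fits$cx[k], 4, tolerance = 1e-6)
    expect_equal(fits$bg[k], 20, tolerance = 1e-5)
  }
})

test_that("flat frames are flagged rather than fitted blindly", {
  arr <- array(50, c(32, 32, 3))
  s <- image_series(arr, 0.1, 0.13)
  fits <- fit_gaussian_frames(s)
  expect_true(all(fits$flat))
})

test_that("a non-spreading series yields D = 0 with a warning", {
  s <- generate_punctual_series(spot_model(300, D = 0), n_frames = 10,
                                noiseless = TRUE, seed = 5)
  expect_warning(fit <- estimate_diffusivity_punctual(s),
                 "non-increasing")
  expect_equal(fit$D_hat, 0)
  expect_true("no_spreading" %in% fit$flags)
  # with noise the estimate is not exactly zero but remains negligible
  sn <- generate_punctual_series(spot_model(300, D = 0), n_frames = 10,
                                 seed = 5)
  fitn <- tryCatch(estimate_diffusivity_punctual(sn),
                   warning = function(w) suppressWarnings(
                     estimate_diffusivity_punctual(sn)))
  expect_lt(fitn$D_hat, 0.005)
})

test_that("width and amplitude estimators agree on clean data", {
  s <- generate_punctual_series(spot_model(200, D = 0.048), seed = 3)
  fw <- estimate_diffusivity_punctual(s, method = "punctual_width")
  fa <- estimate_diffusivity_punctual(s, method = "punctual_amplitude")
  expect_false("method_disagreement" %in% fw$flags)
  expect_lt(abs(fw$D_hat - fa$D_hat),
            3 * sqrt(fw$se^2 + fa$se^2))
  expect_equal(fa$D_hat, 0.048, tolerance = 0.15)
})

test_that("the punctual estimator is unbiased at the bilayer conditions", {
  fits <- lapply(1:10, function(sd) {
    estimate_diffusivity_punctual(
      generate_fixture("slb-gm1", seed = sd))
  })
  es <- ensemble_stats(fits)
  expect_lt(abs(es$mean - 0.048), 0.017)
  expect_lt(abs(es$mean - 0.048), max(es$sd, 0.002))
})

test_that("the FRAP estimator is unbiased at the bilayer conditions", {
  fits <- lapply(1:10, function(sd) {
    estimate_diffusivity_frap(generate_fixture("slb-frap", seed = sd))
  })
  es <- ensemble_stats(fits)
  expect_lt(abs(es$mean - 0.045), 0.008)
})

test_that("halving the frame interval leaves the estimate unbiased", {
  base <- vapply(1:6, function(sd) {
    estimate_diffusivity_punctual(generate_punctual_series(
      spot_model(200, D = 0.048), frame_interval = 0.13, n_frames = 24,
      seed = sd))$D_hat
  }, numeric(1))
  halved <- vapply(1:6, function(sd) {
    estimate_diffusivity_punctual(generate_punctual_series(
      spot_model(200, D = 0.048), frame_interval = 0.065, n_frames = 24,
      seed = sd))$D_hat
  }, numeric(1))
  expect_equal(mean(base), mean(halved), tolerance = 0.1)
  expect_equal(mean(base), 0.048, tolerance = 0.05)
})

test_that("a hole that fills between frames is flagged or aborts", {
  res <- tryCatch(
    estimate_diffusivity_frap(generate_frap_series(
      150, spot_model(120, D = 2, sign = -1), n_frames = 15, fov = 10,
      seed = 1)),
    error = function(e) e)
  expect_true(inherits(res, "error") || "lower_bound" %in% res$flags)
})

test_that("FRAP without prebleach frames or without a hole aborts", {
  s <- generate_punctual_series(spot_model(200, D = 0.05), seed = 1)
  expect_error(estimate_diffusivity_frap(s), "prebleach")
  flat <- generate_frap_series(150, spot_model(1, D = 0.05, sign = -1),
                               n_frames = 10, seed = 1)
  expect_error(estimate_diffusivity_frap(flat), "no detectable")
})

test_that("ensemble statistics match hand arithmetic and reject degenerate input", {
  mk <- function(D, method = "punctual_width") {
    structure(list(D_hat = D, se = 0.001, method = method,
                   frames = NULL, n_used = 10, flags = character(0)),
              class = "diffusion_fit")
  }
  es <- ensemble_stats(list(mk(0.04), mk(0.05), mk(0.06)))
  expect_equal(es$mean, 0.05)
  expect_equal(es$sd, 0.01)
  es_perm <- ensemble_stats(list(mk(0.06), mk(0.04), mk(0.05)))
  expect_equal(es_perm$mean, es$mean)
  expect_equal(es_perm$sd, es$sd)
  expect_error(ensemble_stats(list(mk(0.04))), "at least 2")
  expect_warning(ensemble_stats(list(mk(0.04), mk(0.05, "frap_recovery"))),
                 "mixed")
})

test_that("estimator spread shrinks with photon flux", {
  sd_at <- function(amp) {
    d <- vapply(1:12, function(sd) {
      estimate_diffusivity_punctual(generate_punctual_series(
        spot_model(amp, D = 0.048), n_frames = 20, seed = sd))$D_hat
    }, numeric(1))
    stats::sd(d)
  }
  expect_lt(sd_at(5 * 200), sd_at(200))
})
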