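# Packaged generator parameter files ("fixtures"): every synthetic study
# condition used in the tests and the reproduction script is a YAML file
# under inst/extdata, loaded and realized through this module, so each
# condition is defined in exactly one place.

#' Locate or load a packaged fixture parameter file
#'
#' @param name Fixture name (file `inst/extdata/<name>.yaml`), e.g.
#'   `"slb-gm1"`, `"slb-frap"`, `"cos7-gm1"`, `"extended-labeling"`,
#'   `"tf-clathrin"`, `"cluster-lapse"`, `"device-1um"`, `"device-6um"`.
#' @return `fixture_path` returns the file path; `load_fixture` the parsed
#'   parameter list.
#' @export
fixture_path <- function(name) {
  p <- system.file("extdata", paste0(name, ".yaml"), package = "flowbrush")
  if (!nzchar(p)) stop("unknown fixture: ", name)
  p
}

#' @rdname fixture_path
#' @export
load_fixture <- function(name) {
  yaml::read_yaml(fixture_path(name))
}

#' Realize a packaged fixture as synthetic data
#'
#' Dispatches on the fixture's `type` field and returns the generated
#' object: an [image_series()] for `punctual` / `frap` / `extended` /
#' `clusters`, the channel-pair list for `two_channel`, or the
#' geometry/flow pair for `device` fixtures.
#'
#' @param fixture A fixture name or a parameter list from
#'   [load_fixture()].
#' @param seed Integer seed for the realization.
#' @return The generated object (see Details).
#' @export
generate_fixture <- function(fixture, seed = 1) {
  fx <- if (is.character(fixture)) load_fixture(fixture) else fixture
  psf <- do.call(psf_model, fx$psf %||% list())
  noise <- do.call(noise_model, fx$noise %||% list())
  switch(
    fx$type,
    punctual = generate_punctual_series(
      spot_model(amplitude = fx$amplitude, sigma0 = fx$sigma0,
                 D = fx$D_true),
      psf = psf, noise = noise, pixel_size = fx$pixel_size,
      frame_interval = fx$frame_interval, n_frames = fx$n_frames,
      fov = fx$fov, seed = seed),
    frap = generate_frap_series(
      prebleach_level = fx$prebleach_level,
      bleach = spot_model(amplitude = fx$bleach_depth, sigma0 = fx$sigma0,
                          D = fx$D_true, sign = -1),
      psf = psf, noise = noise, pixel_size = fx$pixel_size,
      frame_interval = fx$frame_interval, n_frames = fx$n_frames,
      n_prebleach = fx$n_prebleach, fov = fx$fov, seed = seed),
    extended = generate_extended_series(
      band = fx$band, clusters = as.data.frame(fx$clusters),
      psf = psf, noise = noise, pixel_size = fx$pixel_size,
      frame_interval = fx$frame_interval, duration = fx$duration,
      fov = fx$fov, seed = seed),
    two_channel = generate_two_channel(
      fx$design, psf = psf, noise = noise, pixel_size = fx$pixel_size,
      seed = seed),
    clusters = generate_cluster_timelapse(
      n0 = fx$n0, D_cluster = fx$D_cluster,
      coalescence_radius = fx$coalescence_radius,
      field_size = fx$field_size, duration = fx$duration,
      frame_interval = fx$frame_interval,
      unit_intensity = fx$unit_intensity, psf = psf, noise = noise,
      pixel_size = fx$pixel_size, seed = seed),
    device = list(geometry = do.call(device_geometry, fx$geometry),
                  config = do.call(flow_config, fx$flow)),
    stop("unknown fixture type: ", fx$type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
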