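# Synthetic fluorescence image-series generators: diffusing punctual label,
# FRAP bleach/recovery, extended labeling band with drifting clusters,
# two-channel colocalization designs, coalescing cluster time lapses.
#
# Image conventions: pixel centers, 0-based indices, x right / y down; the
# um coordinate of pixel index i is (i + 0.5) * pixel_size. Frames are
# matrices indexed [y + 1, x + 1]; a series is an array (ny, nx, nt).

#' Gaussian point-spread-function model
#'
#' Standard Gaussian approximation of a widefield/confocal PSF,
#' `sigma_psf = 0.21 * lambda / NA`.
#'
#' @param wavelength Illumination wavelength, nm (default 488).
#' @param na Objective numerical aperture (default 1.0).
#' @return Object of class `psf_model` with `sigma` in um.
#' @export
psf_model <- function(wavelength = 488, na = 1.0) {
  stopifnot(wavelength > 0, na > 0)
  structure(list(sigma = 0.21 * wavelength * 1e-3 / na,
                 wavelength = wavelength, na = na),
            class = "psf_model")
}

#' Shot + read noise model
#'
#' Poisson shot noise on the expected photon counts, plus zero-mean Gaussian
#' read noise, on top of a uniform background; negative values are floored
#' at zero.
#'
#' @param read_sd Read-noise standard deviation, counts.
#' @param background Uniform background level, counts per pixel.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(read_sd = 3, background = 20) {
  stopifnot(read_sd >= 0, background >= 0)
  structure(list(read_sd = read_sd, background = background),
            class = "noise_model")
}

#' Diffusing Gaussian spot model
#'
#' A labeled (or bleached) spot that starts as an isotropic 2D Gaussian of
#' per-axis standard deviation `sigma0` and peak `amplitude`, and spreads by
#' free 2D diffusion: per-axis variance grows as `sigma0^2 + 2 D t` while
#' the integrated intensity is conserved, so the peak decays as
#' `amplitude * sigma0^2 / (sigma0^2 + 2 D t)`.
#'
#' @param amplitude Initial peak intensity of the (un-convolved) spot,
#'   counts.
#' @param sigma0 Initial per-axis Gaussian standard deviation, um. The
#'   default 1/2.355 corresponds to a spot whose full width at half maximum
#'   equals the 1 um aperture footprint.
#' @param center Spot center, um (length 2: x, y); `NULL` centers it in the
#'   field at generation time.
#' @param D Diffusion coefficient, um^2/s.
#' @param sign `+1` for a labeled spot, `-1` for a bleached hole.
#' @return Object of class `spot_model`.
#' @export
spot_model <- function(amplitude, sigma0 = 1 / 2.355, center = NULL, D,
                       sign = 1) {
  stopifnot(amplitude > 0, sigma0 > 0, D >= 0, sign %in% c(-1, 1))
  structure(list(amplitude = amplitude, sigma0 = sigma0, center = center,
                 D = D, sign = sign),
            class = "spot_model")
}

#' Construct an image series
#'
#' @param frames Array (ny, nx, nt) of non-negative intensities (photon
#'   counts).
#' @param pixel_size Pixel edge, um.
#' @param frame_interval Frame interval, s.
#' @param channel Channel label.
#' @param timestamps Frame mid-exposure times, s; default
#'   `(k - 0.5) * frame_interval`.
#' @return Object of class `image_series`.
#' @export
image_series <- function(frames, pixel_size, frame_interval,
                         channel = "ch0", timestamps = NULL) {
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  stopifnot(length(dim(frames)) == 3, pixel_size > 0, frame_interval > 0,
            all(frames >= 0))
  nt <- dim(frames)[3]
  if (is.null(timestamps)) {
    timestamps <- (seq_len(nt) - 0.5) * frame_interval
  }
  stopifnot(length(timestamps) == nt)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, channel = channel,
                 timestamps = timestamps),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "Image series '%s': %d frames of %d x %d px (%.3g um/px, %.3g s/frame)\n",
    x$channel, d[3], d[2], d[1], x$pixel_size, x$frame_interval))
  invisible(x)
}

# Render a sum of isotropic Gaussians, parameterized by total integrated
# counts `mass` and per-axis variance `var` (um^2), onto an (ny, nx) pixel
# grid. Separable evaluation at pixel centers.
render_gaussians <- function(ny, nx, pixel_size, x, y, mass, var) {
  img <- matrix(0, ny, nx)
  xc <- (seq_len(nx) - 0.5) * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size
  for (i in seq_along(x)) {
    peak <- mass[i] * pixel_size^2 / (2 * pi * var[i])
    gx <- exp(-(xc - x[i])^2 / (2 * var[i]))
    gy <- exp(-(yc - y[i])^2 / (2 * var[i]))
    img <- img + peak * (gy %o% gx)
  }
  img
}

# Separable Gaussian blur with zero padding (used for non-Gaussian scene
# elements such as the extended labeling band).
gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  blur1 <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[j:(j + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(mat))))
}

# Edge-renormalized Gaussian blur (no zero-padding droop at the borders);
# used where blurred statistics feed decisions, not rendering.
blur_norm <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  gaussian_blur(mat, sigma_px) /
    gaussian_blur(matrix(1, nrow(mat), ncol(mat)), sigma_px)
}

# Apply the noise model to a noiseless expected-counts frame.
apply_noise <- function(mat, noise) {
  n <- length(mat)
  noisy <- stats::rpois(n, lambda = pmax(mat, 0))
  if (noise$read_sd > 0) noisy <- noisy + stats::rnorm(n, sd = noise$read_sd)
  matrix(pmax(noisy, 0), nrow(mat), ncol(mat))
}

#' Generate a punctual-labeling image series
#'
#' Renders the diffusive spread of a briefly delivered labeled spot: frame
#' `t` is a 2D Gaussian with per-axis variance `sigma0^2 + 2 D t` and peak
#' `A0 * sigma0^2 / (sigma0^2 + 2 D t)` (integrated intensity conserved),
#' convolved with the Gaussian PSF (adding `sigma_psf^2` to the variance),
#' plus background, then shot/read noise. Frame `k` is stamped at its
#' mid-exposure time `(k - 0.5) * frame_interval`, the first frame being the
#' first frame after the labeling pulse ends.
#'
#' @param spot A [spot_model()].
#' @param psf A [psf_model()].
#' @param noise A [noise_model()].
#' @param pixel_size Pixel edge, um.
#' @param frame_interval Frame interval, s (default 0.13).
#' @param n_frames Number of frames.
#' @param fov Field of view edge length, um.
#' @param seed Integer seed (noise realization).
#' @param noiseless If `TRUE`, skip the noise stage (used by oracle tests).
#' @return An [image_series()] with attribute `truth` recording the
#'   generating parameters.
#' @export
generate_punctual_series <- function(spot, psf = psf_model(),
                                     noise = noise_model(),
                                     pixel_size = 0.1,
                                     frame_interval = 0.13,
                                     n_frames = 30, fov = 8, seed = 1,
                                     noiseless = FALSE) {
  stopifnot(inherits(spot, "spot_model"), inherits(psf, "psf_model"),
            inherits(noise, "noise_model"))
  n_px <- round(fov / pixel_size)
  center <- if (is.null(spot$center)) c(fov / 2, fov / 2) else spot$center
  tt <- (seq_len(n_frames) - 0.5) * frame_interval
  var_final <- spot$sigma0^2 + 2 * spot$D * max(tt)
  if (any(center - 2 * sqrt(var_final) < 0) ||
      any(center + 2 * sqrt(var_final) > fov)) {
    stop("spot would drift/spread off the field of view")
  }
  mass <- spot$amplitude * 2 * pi * spot$sigma0^2 / pixel_size^2
  set.seed(seed)
  frames <- array(0, c(n_px, n_px, n_frames))
  for (k in seq_len(n_frames)) {
    v <- spot$sigma0^2 + 2 * spot$D * tt[k] + psf$sigma^2
    f <- noise$background +
      render_gaussians(n_px, n_px, pixel_size, center[1], center[2],
                       mass, v)
    frames[, , k] <- if (noiseless) f else apply_noise(f, noise)
  }
  out <- image_series(frames, pixel_size, frame_interval,
                      channel = "punctual", timestamps = tt)
  attr(out, "truth") <- list(spot = spot, psf = psf, noise = noise,
                             center = center, seed = seed,
                             noiseless = noiseless)
  out
}

#' Generate a FRAP bleach-recovery image series
#'
#' Frames are a uniform prebleach plateau minus a diffusing Gaussian hole
#' whose variance and depth evolve exactly as the punctual-labeling spot
#' (sign inverted). `n_prebleach` plateau frames precede the bleach; the
#' first post-bleach frame is stamped `(1 - 0.5) * frame_interval` after the
#' bleach ends.
#'
#' @param prebleach_level Plateau intensity, counts per pixel (on top of
#'   the noise-model background).
#' @param bleach A [spot_model()] with `sign = -1`; its amplitude is the
#'   bleach depth (must not exceed `prebleach_level`).
#' @param n_prebleach Number of prebleach frames.
#' @inheritParams generate_punctual_series
#' @return An [image_series()] with attribute `truth`; prebleach frames have
#'   negative timestamps.
#' @export
generate_frap_series <- function(prebleach_level, bleach,
                                 psf = psf_model(), noise = noise_model(),
                                 pixel_size = 0.1, frame_interval = 0.13,
                                 n_frames = 30, n_prebleach = 5, fov = 8,
                                 seed = 1, noiseless = FALSE) {
  stopifnot(inherits(bleach, "spot_model"), bleach$sign == -1,
            bleach$amplitude <= prebleach_level)
  n_px <- round(fov / pixel_size)
  center <- if (is.null(bleach$center)) c(fov / 2, fov / 2) else bleach$center
  tt_post <- (seq_len(n_frames) - 0.5) * frame_interval
  mass <- bleach$amplitude * 2 * pi * bleach$sigma0^2 / pixel_size^2
  set.seed(seed)
  nt <- n_prebleach + n_frames
  frames <- array(0, c(n_px, n_px, nt))
  plateau <- noise$background + prebleach_level
  for (k in seq_len(n_prebleach)) {
    f <- matrix(plateau, n_px, n_px)
    frames[, , k] <- if (noiseless) f else apply_noise(f, noise)
  }
  for (k in seq_len(n_frames)) {
    v <- bleach$sigma0^2 + 2 * bleach$D * tt_post[k] + psf$sigma^2
    hole <- render_gaussians(n_px, n_px, pixel_size, center[1], center[2],
                             mass, v)
    f <- pmax(plateau - hole, 0)
    frames[, , n_prebleach + k] <- if (noiseless) f else apply_noise(f, noise)
  }
  ts <- c(-rev(seq_len(n_prebleach)) * frame_interval, tt_post)
  out <- image_series(frames, pixel_size, frame_interval, channel = "frap",
                      timestamps = ts)
  attr(out, "truth") <- list(prebleach_level = prebleach_level,
                             bleach = bleach, psf = psf, noise = noise,
                             center = center, n_prebleach = n_prebleach,
                             seed = seed, noiseless = noiseless)
  out
}

#' Generate an extended-labeling series with drifting bright clusters
#'
#' A static labeled band (a crescent at the cell periphery) plus bright
#' Gaussian clusters translating at constant speed, imaged over many
#' minutes.
#'
#' @param band List with `center` (um), `radius` (um), `width` (um),
#'   `theta_range` (radians, angular span of the crescent) and `intensity`
#'   (counts per pixel inside the band).
#' @param clusters data.frame with columns `x0`, `y0` (um at t = 0), `speed`
#'   (nm/s), `direction` (radians), `sigma` (um) and `amplitude` (peak
#'   counts).
#' @param duration Total duration, s (default 950).
#' @param frame_interval Frame interval, s (default 5).
#' @inheritParams generate_punctual_series
#' @return An [image_series()]; clusters that leave the field are clipped
#'   and recorded in attribute `clipped`.
#' @export
generate_extended_series <- function(band, clusters, psf = psf_model(),
                                     noise = noise_model(),
                                     pixel_size = 0.1, frame_interval = 5,
                                     duration = 950, fov = 20, seed = 1,
                                     noiseless = FALSE) {
  stopifnot(all(clusters$speed >= 0))
  n_px <- round(fov / pixel_size)
  n_frames <- floor(duration / frame_interval)
  xc <- (seq_len(n_px) - 0.5) * pixel_size
  ang <- function(x, y) atan2(y - band$center[2], x - band$center[1])
  rr <- sqrt(outer((xc - band$center[2])^2, (xc - band$center[1])^2, "+"))
  th <- atan2(matrix(xc - band$center[2], n_px, n_px),
              matrix(xc - band$center[1], n_px, n_px, byrow = TRUE))
  in_band <- abs(rr - band$radius) < band$width / 2 &
    th >= band$theta_range[1] & th <= band$theta_range[2]
  band_img <- gaussian_blur(band$intensity * in_band, psf$sigma / pixel_size)
  set.seed(seed)
  frames <- array(0, c(n_px, n_px, n_frames))
  tt <- (seq_len(n_frames) - 0.5) * frame_interval
  clipped <- FALSE
  for (k in seq_len(n_frames)) {
    cx <- clusters$x0 + clusters$speed * 1e-3 * tt[k] * cos(clusters$direction)
    cy <- clusters$y0 + clusters$speed * 1e-3 * tt[k] * sin(clusters$direction)
    if (any(cx < 0 | cx > fov | cy < 0 | cy > fov)) clipped <- TRUE
    v <- clusters$sigma^2 + psf$sigma^2
    mass <- clusters$amplitude * 2 * pi * clusters$sigma^2 / pixel_size^2
    f <- noise$background + band_img +
      render_gaussians(n_px, n_px, pixel_size, cx, cy, mass, v)
    frames[, , k] <- if (noiseless) f else apply_noise(f, noise)
  }
  out <- image_series(frames, pixel_size, frame_interval,
                      channel = "extended", timestamps = tt)
  attr(out, "truth") <- list(band = band, clusters = clusters, psf = psf,
                             noise = noise, seed = seed)
  attr(out, "clipped") <- clipped
  out
}

#' Generate a two-channel partially colocalized spot-image pair
#'
#' Constructs channels A and B from point spots of equal Gaussian width so
#' that, at the generator's threshold convention (a fixed threshold at
#' `threshold_frac` of the convolved spot peak above background), the
#' fraction of A intensity inside the thresholded B mask matches the
#' designed Mander's M1, and symmetrically M2. The construction places
#' `k = round(M1 * n_a / (1 - threshold_frac))` A spots exactly on B spots
#' (each contributing the enclosed mass fraction `1 - threshold_frac`) and
#' the rest far from all B structures; `n_b` is solved from M2 the same way.
#'
#' @param design List with `target_m1`, `target_m2` (in (0, 1]), `n_a`
#'   (number of A spots), `spot_sigma` (um), `amplitude` (un-convolved peak
#'   counts), `threshold_frac` (default 0.01), `fov` (um), `min_separation`
#'   (um, between distinct structures).
#' @inheritParams generate_punctual_series
#' @return List with image series `A` and `B` (single frame each), the
#'   absolute `thresholds` implied by the design convention, and the
#'   realized `design` (including the solved spot counts).
#' @export
generate_two_channel <- function(design, psf = psf_model(),
                                 noise = noise_model(), pixel_size = 0.1,
                                 seed = 1, noiseless = FALSE) {
  d <- design
  if (is.null(d$threshold_frac)) d$threshold_frac <- 0.01
  if (is.null(d$min_separation)) d$min_separation <- 12 * d$spot_sigma
  stopifnot(d$target_m1 > 0, d$target_m1 <= 1,
            d$target_m2 > 0, d$target_m2 <= 1, d$n_a >= 1)
  cfrac <- 1 - d$threshold_frac
  k <- round(d$target_m1 * d$n_a / cfrac)
  n_b <- round(cfrac * k / d$target_m2)
  if (k > d$n_a || k > n_b || n_b < 1) {
    stop("infeasible colocalization design")
  }
  n_total <- d$n_a + n_b - k
  set.seed(seed)
  # seeded jittered-grid placement: guarantees the minimum separation at
  # any feasible density
  margin <- 6 * d$spot_sigma
  side <- ceiling(sqrt(n_total))
  pitch <- (d$fov - 2 * margin) / side
  if (pitch < d$min_separation) {
    stop("infeasible colocalization design: cannot place spots")
  }
  jit <- (pitch - d$min_separation) / 2
  cells <- expand.grid(ix = seq_len(side) - 1L, iy = seq_len(side) - 1L)
  cells <- cells[sample.int(nrow(cells), n_total), ]
  pts <- cbind(
    margin + (cells$ix + 0.5) * pitch + stats::runif(n_total, -jit, jit),
    margin + (cells$iy + 0.5) * pitch + stats::runif(n_total, -jit, jit))
  shared <- pts[seq_len(k), , drop = FALSE]
  a_only <- pts[seq_len(d$n_a - k) + k, , drop = FALSE]
  b_only <- pts[seq_len(n_b - k) + d$n_a, , drop = FALSE]
  a_pts <- rbind(shared, a_only)
  b_pts <- rbind(shared, b_only)
  n_px <- round(d$fov / pixel_size)
  v <- d$spot_sigma^2 + psf$sigma^2
  mass <- d$amplitude * 2 * pi * d$spot_sigma^2 / pixel_size^2
  render_ch <- function(p) {
    f <- noise$background +
      render_gaussians(n_px, n_px, pixel_size, p[, 1], p[, 2],
                       rep(mass, nrow(p)), rep(v, nrow(p)))
    if (noiseless) f else apply_noise(f, noise)
  }
  fa <- render_ch(a_pts)
  fb <- render_ch(b_pts)
  peak_conv <- mass * pixel_size^2 / (2 * pi * v)
  thr <- noise$background + d$threshold_frac * peak_conv
  d$n_shared <- k; d$n_b <- n_b
  list(
    A = image_series(fa, pixel_size, frame_interval = 1, channel = "A"),
    B = image_series(fb, pixel_size, frame_interval = 1, channel = "B"),
    thresholds = c(A = thr, B = thr),
    background = noise$background,
    design = d,
    a_points = a_pts, b_points = b_pts
  )
}

#' Render tracked particles into an image series
#'
#' Renders each time point of a trajectory set as diffraction-limited spots
#' (particles outside the focal slab are omitted, mimicking the finite
#' depth of focus), producing the raw-movie input of the tracking
#' velocimetry pipeline.
#'
#' @param traj A [trajectory_set()].
#' @param fov `c(xmin, xmax, ymin, ymax)` imaged region, um.
#' @param z_slab `c(zmin, zmax)` focal slab, um; `NULL` keeps everything.
#' @param amplitude Un-convolved spot peak, counts.
#' @param spot_sigma Physical spot size, um.
#' @inheritParams generate_punctual_series
#' @return An [image_series()]; frame k corresponds to the k-th time point.
#' @export
render_trajectory_frames <- function(traj, fov, z_slab = NULL,
                                     amplitude = 500, spot_sigma = 0.1,
                                     psf = psf_model(),
                                     noise = noise_model(),
                                     pixel_size = 0.1, seed = 1,
                                     noiseless = FALSE) {
  stopifnot(inherits(traj, "trajectory_set"), length(fov) == 4)
  tt <- sort(unique(traj$t))
  nx <- round((fov[2] - fov[1]) / pixel_size)
  ny <- round((fov[4] - fov[3]) / pixel_size)
  v <- spot_sigma^2 + psf$sigma^2
  mass <- amplitude * 2 * pi * spot_sigma^2 / pixel_size^2
  set.seed(seed)
  frames <- array(0, c(ny, nx, length(tt)))
  for (k in seq_along(tt)) {
    p <- traj[traj$t == tt[k], , drop = FALSE]
    if (!is.null(z_slab)) {
      p <- p[p$z >= z_slab[1] & p$z <= z_slab[2], , drop = FALSE]
    }
    f <- noise$background +
      render_gaussians(ny, nx, pixel_size, p$x - fov[1], p$y - fov[3],
                       rep(mass, nrow(p)), rep(v, nrow(p)))
    frames[, , k] <- if (noiseless) f else apply_noise(f, noise)
  }
  dtv <- diff(tt)
  image_series(frames, pixel_size,
               frame_interval = if (length(dtv)) min(dtv) else 1,
               channel = "tracers", timestamps = tt)
}

#' Generate a coalescing-cluster time lapse
#'
#' `n0` clusters perform 2D Brownian motion in a square region (reflecting
#' boundaries); whenever two clusters come within `coalescence_radius` they
#' merge, summing integrated intensity and area (Gaussian variances add) and
#' continuing from their intensity-weighted centroid.
#'
#' @param n0 Initial cluster count (>= 2).
#' @param D_cluster Cluster diffusivity, um^2/s.
#' @param coalescence_radius Merge distance, um.
#' @param field_size Region edge, um (default 15).
#' @param duration Total duration, s (default 360).
#' @param unit_intensity Integrated counts of a single labeled receptor;
#'   initial cluster copy numbers are drawn from 2:5.
#' @inheritParams generate_punctual_series
#' @return An [image_series()] with attribute `truth`: per-frame cluster
#'   table (frame, id, x, y, mass, sigma2) as generated.
#' @export
generate_cluster_timelapse <- function(n0 = 40, D_cluster = 0.02,
                                       coalescence_radius = 0.4,
                                       field_size = 15, duration = 360,
                                       frame_interval = 5,
                                       unit_intensity = 500,
                                       psf = psf_model(),
                                       noise = noise_model(),
                                       pixel_size = 0.1, seed = 1,
                                       noiseless = FALSE) {
  stopifnot(n0 >= 2)
  set.seed(seed)
  n_frames <- floor(duration / frame_interval)
  x <- stats::runif(n0, 1, field_size - 1)
  y <- stats::runif(n0, 1, field_size - 1)
  mass <- sample(2:5, n0, replace = TRUE) * unit_intensity
  sigma2 <- rep(0.2^2, n0)
  n_px <- round(field_size / pixel_size)
  frames <- array(0, c(n_px, n_px, n_frames))
  truth <- vector("list", n_frames)
  sd_step <- sqrt(2 * D_cluster * frame_interval)
  for (k in seq_len(n_frames)) {
    if (k > 1) {
      x <- x + stats::rnorm(length(x), sd = sd_step)
      y <- y + stats::rnorm(length(y), sd = sd_step)
      x <- pmin(pmax(x, 0), field_size); x <- ifelse(x == 0, 1e-6, x)
      y <- pmin(pmax(y, 0), field_size); y <- ifelse(y == 0, 1e-6, y)
      if (coalescence_radius > 0 && length(x) > 1) {
        repeat {
          dm <- as.matrix(stats::dist(cbind(x, y)))
          diag(dm) <- Inf
          hit <- which(dm < coalescence_radius, arr.ind = TRUE)
          if (!nrow(hit)) break
          i <- hit[1, 1]; j <- hit[1, 2]
          w <- mass[c(i, j)] / sum(mass[c(i, j)])
          x[i] <- sum(w * x[c(i, j)]); y[i] <- sum(w * y[c(i, j)])
          mass[i] <- mass[i] + mass[j]
          sigma2[i] <- sigma2[i] + sigma2[j]
          x <- x[-j]; y <- y[-j]; mass <- mass[-j]; sigma2 <- sigma2[-j]
        }
      }
    }
    f <- noise$background +
      render_gaussians(n_px, n_px, pixel_size, x, y, mass,
                       sigma2 + psf$sigma^2)
    frames[, , k] <- if (noiseless) f else apply_noise(f, noise)
    truth[[k]] <- data.frame(frame = k, id = seq_along(x), x = x, y = y,
                             mass = mass, sigma2 = sigma2)
  }
  out <- image_series(frames, pixel_size, frame_interval,
                      channel = "clusters")
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "unit_intensity") <- unit_intensity
  out
}
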