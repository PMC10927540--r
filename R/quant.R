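# Image quantification: spot detection, trajectory linking, velocimetry
# maps, Mander's colocalization, cluster time courses, MSD analysis.

#' Detect diffraction-limited spots in a frame
#'
#' Band-pass (difference of Gaussians) filtering, 8-neighborhood local
#' maxima above a threshold, and intensity-weighted centroid refinement to
#' sub-pixel precision.
#'
#' @param frame Intensity matrix (photon counts).
#' @param pixel_size Pixel edge, um.
#' @param expected_size Expected spot diameter in pixels (>= 2).
#' @param threshold Minimum band-passed peak height, counts.
#' @return data.frame of localizations: `x`, `y` (um), `intensity`
#'   (background-subtracted integrated counts in the refinement window) and
#'   `score` (band-passed peak height).
#' @export
detect_spots <- function(frame, pixel_size, expected_size = 4, threshold) {
  stopifnot(is.matrix(frame), expected_size >= 2)
  if (max(frame) > min(frame) && mean(frame == max(frame)) > 0.01) {
    warning("frame looks saturated: >1% of pixels at the maximum value")
  }
  dog <- gaussian_blur(frame, 1) - gaussian_blur(frame, expected_size)
  ny <- nrow(dog); nx <- ncol(dog)
  inner <- dog[2:(ny - 1), 2:(nx - 1)]
  is_max <- inner > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (inner >= dog[2:(ny - 1) + dy, 2:(nx - 1) + dx])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0), score = numeric(0)))
  }
  r <- ceiling(expected_size)
  bg <- stats::median(frame)
  out <- lapply(seq_len(nrow(idx)), function(i) {
    cy <- idx[i, 1] + 1L; cx <- idx[i, 2] + 1L
    ys <- max(1, cy - r):min(ny, cy + r)
    xs <- max(1, cx - r):min(nx, cx + r)
    w <- pmax(frame[ys, xs] - bg, 0)
    if (sum(w) == 0) return(NULL)
    wy <- rowSums(w); wx <- colSums(w)
    data.frame(
      x = (sum(wx * (xs - 0.5)) / sum(wx)) * pixel_size,
      y = (sum(wy * (ys - 0.5)) / sum(wy)) * pixel_size,
      intensity = sum(w),
      score = dog[cy, cx])
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Link localizations into trajectories
#'
#' Frame-to-frame nearest-neighbor assignment under a displacement gate;
#' candidate pairs are assigned in order of increasing displacement (which
#' breaks ties by minimal total displacement). Ambiguous assignments that
#' the tie rule cannot separate (a competing candidate within
#' `ambiguity * max_displacement` of the accepted displacement) are
#' rejected: neither candidate is linked, and both tracks end there. A
#' track missing from `memory` consecutive frames may still be continued.
#'
#' @param localizations data.frame with columns `frame`, `x`, `y` (um).
#' @param max_displacement Gate: maximum displacement between consecutive
#'   frames, um (> 0; a zero gate makes every localization its own
#'   trajectory).
#' @param memory Number of frames a lost particle may skip.
#' @param frame_interval Frame interval, s (for the time stamps).
#' @param ambiguity Fraction of the gate within which a competing
#'   candidate voids an assignment (0 disables ambiguity rejection).
#' @return A [trajectory_set()] with `z = 0`.
#' @export
link_trajectories <- function(localizations, max_displacement, memory = 0,
                              frame_interval = 1, ambiguity = 0.25) {
  stopifnot(max_displacement >= 0)
  loc <- localizations[order(localizations$frame), , drop = FALSE]
  loc$particle <- NA_integer_
  next_id <- 1L
  # active tracks: id, last x, y, last frame
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    frame = integer(0))
  for (fr in sort(unique(loc$frame))) {
    cur <- which(loc$frame == fr)
    act <- act[fr - act$frame <= memory + 1L, , drop = FALSE]
    if (nrow(act) && length(cur) && max_displacement > 0) {
      dx <- outer(act$x, loc$x[cur], "-")
      dy <- outer(act$y, loc$y[cur], "-")
      dd <- sqrt(dx^2 + dy^2)
      cand <- which(dd <= max_displacement, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dd[cand])
        used_a <- logical(nrow(act)); used_c <- logical(length(cur))
        tol <- ambiguity * max_displacement
        for (ci in ord) {
          a <- cand[ci, 1]; b <- cand[ci, 2]
          if (used_a[a] || used_c[b]) next
          # ambiguity rejection: a competing unused candidate nearly as
          # close as this assignment voids it
          d_ab <- dd[a, b]
          rival_a <- dd[a, !used_c & seq_along(cur) != b]
          rival_b <- dd[!used_a & seq_len(nrow(act)) != a, b]
          if ((length(rival_a) && min(rival_a) < d_ab + tol) ||
              (length(rival_b) && min(rival_b) < d_ab + tol)) {
            used_a[a] <- TRUE  # track ends; localization starts a new one
            next
          }
          loc$particle[cur[b]] <- act$id[a]
          act$x[a] <- loc$x[cur[b]]; act$y[a] <- loc$y[cur[b]]
          act$frame[a] <- fr
          used_a[a] <- TRUE; used_c[b] <- TRUE
        }
      }
    }
    new <- cur[is.na(loc$particle[cur])]
    if (length(new)) {
      ids <- next_id + seq_along(new) - 1L
      loc$particle[new] <- ids
      next_id <- next_id + length(new)
      act <- rbind(act, data.frame(id = ids, x = loc$x[new],
                                   y = loc$y[new], frame = fr))
    }
  }
  trajectory_set(
    data.frame(particle = loc$particle, t = loc$frame * frame_interval,
               x = loc$x, y = loc$y, z = 0),
    frame_interval = frame_interval)
}

#' Spatially binned velocity map from trajectories
#'
#' Step velocities (displacement over the frame interval, assigned to the
#' step midpoint) are averaged per spatial bin; bins with fewer than
#' `min_steps` steps are masked (omitted), not reported as zero.
#'
#' @param traj A [trajectory_set()].
#' @param bin_size Square bin edge, um.
#' @param min_steps Minimum steps per reported bin.
#' @param z_range Optional `c(min, max)`: only steps whose midpoint z lies
#'   in this slab are used (the in-focus slab of an imaging comparison).
#' @return data.frame with bin centers `x`, `y`, step count `n`, mean
#'   in-plane velocity components `vx`, `vy` (um/s), the speed of the mean
#'   vector `speed`, and the mean step speed `mean_step_speed`. The
#'   per-step speed includes the Brownian contribution; the vector mean
#'   averages it out and estimates the advective flow.
#' @export
velocity_map <- function(traj, bin_size, min_steps = 1, z_range = NULL) {
  stopifnot(inherits(traj, "trajectory_set"), bin_size > 0)
  parts <- split(as.data.frame(traj), traj$particle)
  steps <- do.call(rbind, lapply(parts, function(p) {
    if (nrow(p) < 2) return(NULL)
    n <- nrow(p)
    dt <- diff(p$t)
    data.frame(x = (p$x[-1] + p$x[-n]) / 2, y = (p$y[-1] + p$y[-n]) / 2,
               z = (p$z[-1] + p$z[-n]) / 2,
               vx = diff(p$x) / dt, vy = diff(p$y) / dt)
  }))
  if (!is.null(z_range) && !is.null(steps)) {
    steps <- steps[steps$z >= z_range[1] & steps$z <= z_range[2], ,
                   drop = FALSE]
  }
  if (is.null(steps)) stop("no steps available")
  ix <- floor(steps$x / bin_size); iy <- floor(steps$y / bin_size)
  key <- paste(ix, iy)
  agg <- lapply(split(steps, key), function(s) {
    data.frame(x = (floor(s$x[1] / bin_size) + 0.5) * bin_size,
               y = (floor(s$y[1] / bin_size) + 0.5) * bin_size,
               n = nrow(s), vx = mean(s$vx), vy = mean(s$vy),
               mean_step_speed = mean(sqrt(s$vx^2 + s$vy^2)))
  })
  out <- do.call(rbind, agg)
  out$speed <- sqrt(out$vx^2 + out$vy^2)
  out[out$n >= min_steps, , drop = FALSE]
}

# bilinear interpolation of a frame at um coordinates
interp_frame <- function(frame, x_um, y_um, pixel_size) {
  px <- x_um / pixel_size - 0.5
  py <- y_um / pixel_size - 0.5
  x0 <- pmin(pmax(floor(px), 0), ncol(frame) - 2)
  y0 <- pmin(pmax(floor(py), 0), nrow(frame) - 2)
  fx <- pmin(pmax(px - x0, 0), 1)
  fy <- pmin(pmax(py - y0, 0), 1)
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  frame[i00] * (1 - fx) * (1 - fy) + frame[i01] * fx * (1 - fy) +
    frame[i10] * (1 - fx) * fy + frame[i11] * fx * fy
}

#' Build a kymograph along a sampling path
#'
#' For every frame, intensity is averaged across `line_width` samples
#' perpendicular to the path and sampled at pixel pitch along it.
#'
#' @param series An [image_series()].
#' @param path Polyline (k x 2 matrix of um coordinates) inside the frames.
#' @param line_width Averaging width perpendicular to the path, pixels.
#' @return Object of class `kymograph`: `intensity` (position x time),
#'   `position` (um along the path), `time` (s), and the calibrations.
#' @export
build_kymograph <- function(series, path, line_width = 1) {
  stopifnot(inherits(series, "image_series"))
  path <- matrix(path, ncol = 2)
  px <- series$pixel_size
  d <- dim(series$frames)
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  stopifnot(sum(seg_len) > 0)
  s_nodes <- c(0, cumsum(seg_len))
  s_samp <- seq(0, sum(seg_len), by = px)
  ii <- pmin(pmax(findInterval(s_samp, s_nodes, rightmost.closed = TRUE), 1L),
             nrow(path) - 1L)
  frac <- (s_samp - s_nodes[ii]) / pmax(seg_len[ii], 1e-12)
  pts <- path[ii, , drop = FALSE] + seg[ii, , drop = FALSE] * frac
  u <- seg[ii, , drop = FALSE] / pmax(seg_len[ii], 1e-12)
  nrm <- cbind(-u[, 2], u[, 1])
  offs <- (seq_len(line_width) - (line_width + 1) / 2) * px
  fov_x <- d[2] * px; fov_y <- d[1] * px
  all_pts <- do.call(rbind, lapply(offs, function(o) pts + nrm * o))
  if (any(all_pts[, 1] < 0) || any(all_pts[, 1] > fov_x) ||
      any(all_pts[, 2] < 0) || any(all_pts[, 2] > fov_y)) {
    stop("kymograph path (with line width) exits the frame bounds")
  }
  kymo <- matrix(0, length(s_samp), d[3])
  for (k in seq_len(d[3])) {
    f <- series$frames[, , k]
    acc <- 0
    for (o in offs) {
      q <- pts + nrm * o
      acc <- acc + interp_frame(f, q[, 1], q[, 2], px)
    }
    kymo[, k] <- acc / line_width
  }
  structure(list(intensity = kymo, position = s_samp,
                 time = series$timestamps, path = path,
                 line_width = line_width, pixel_size = px),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d positions x %d time points (%.3g um pitch)\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size))
  invisible(x)
}

#' Extract the linear speed of a kymograph ridge
#'
#' Tracks the intensity-weighted centroid of a bright ridge within a
#' sliding window (re-centered on the previous centroid each time step) and
#' regresses ridge position on time. Columns where the ridge falls below an
#' SNR of 2 truncate the regression.
#'
#' @param kymo A [build_kymograph()] result.
#' @param feature_window Initial position window `c(min, max)` (um along
#'   the path) containing the ridge in the first time sample.
#' @return List with `speed_nm_per_s`, its standard error, the per-time
#'   ridge `positions` (um) and the number of time samples used.
#' @export
kymograph_feature_speed <- function(kymo, feature_window) {
  stopifnot(inherits(kymo, "kymograph"), length(feature_window) == 2)
  half_w <- diff(feature_window) / 2
  center <- mean(feature_window)
  nt <- ncol(kymo$intensity)
  pos <- rep(NA_real_, nt)
  used <- 0L
  for (k in seq_len(nt)) {
    col <- kymo$intensity[, k]
    sel <- which(kymo$position >= center - half_w &
                   kymo$position <= center + half_w)
    seg <- col[sel]
    bg <- stats::median(col)
    noise <- stats::mad(col)
    snr <- (max(seg) - bg) / max(noise, 1e-9)
    if (snr < 2) break
    w <- pmax(seg - bg, 0)
    pos[k] <- sum(w * kymo$position[sel]) / sum(w)
    center <- pos[k]
    used <- used + 1L
  }
  if (used < 10) stop("ridge visible in fewer than 10 time samples")
  ok <- seq_len(used)
  fit <- stats::lm(pos[ok] ~ kymo$time[ok])
  speed_um <- stats::coef(fit)[[2]]
  se <- summary(fit)$coefficients[2, "Std. Error"]
  list(speed_nm_per_s = speed_um * 1000, se_nm_per_s = se * 1000,
       positions = pos[ok], n_used = used)
}

as_frame <- function(img) {
  if (inherits(img, "image_series")) img$frames[, , 1] else img
}

#' Mander's colocalization coefficients
#'
#' `M1` is the fraction of (background-subtracted, floored at zero) channel
#' A intensity lying inside the thresholded channel B mask, and `M2` the
#' symmetric quantity. Thresholding is Otsu per channel within the ROI by
#' default; fixed absolute thresholds may be supplied instead.
#'
#' @param imgA,imgB Co-registered intensity matrices (or single-frame
#'   [image_series()]) of identical shape.
#' @param roi Optional logical matrix selecting the analysis region.
#' @param thresholds `"otsu"` or numeric `c(A, B)` absolute thresholds on
#'   the raw intensity scale.
#' @param background Numeric `c(A, B)` background levels; default the
#'   per-channel median within the ROI.
#' @return Object of class `coloc_result` with `M1`, `M2`, the thresholds
#'   used and the threshold convention.
#' @export
manders_coefficients <- function(imgA, imgB, roi = NULL,
                                 thresholds = "otsu", background = NULL) {
  A <- as_frame(imgA); B <- as_frame(imgB)
  stopifnot(identical(dim(A), dim(B)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(A), ncol(A))
  stopifnot(identical(dim(roi), dim(A)))
  a <- A[roi]; b <- B[roi]
  if (is.null(background)) {
    background <- c(stats::median(a), stats::median(b))
  }
  a_sub <- pmax(a - background[1], 0)
  b_sub <- pmax(b - background[2], 0)
  if (identical(thresholds, "otsu")) {
    thr <- c(
      stats::quantile(a, 0) + EBImage::otsu(EBImage::Image(a / max(a)),
                                            range = c(0, 1)) * max(a),
      stats::quantile(b, 0) + EBImage::otsu(EBImage::Image(b / max(b)),
                                            range = c(0, 1)) * max(b))
    convention <- "otsu"
  } else {
    thr <- as.numeric(thresholds)
    convention <- "fixed"
  }
  if (sum(a_sub) == 0 || sum(b_sub) == 0) {
    stop("zero total intensity in one channel: Mander's undefined")
  }
  structure(list(
    M1 = sum(a_sub[b > thr[2]]) / sum(a_sub),
    M2 = sum(b_sub[a > thr[1]]) / sum(b_sub),
    thresholds = thr, background = background, convention = convention),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Mander's coefficients: M1 (A-in-B) = %.3f, M2 (B-in-A) = %.3f\n",
              x$M1, x$M2))
  cat(sprintf("  thresholds (%s): A %.4g, B %.4g\n", x$convention,
              x$thresholds[1], x$thresholds[2]))
  invisible(x)
}

# 8-connectivity labeling: EBImage::bwlabel is 4-connected, so labels
# touching diagonally are merged with a union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  L <- EBImage::imageData(lab)
  n <- max(L)
  if (n < 2) return(L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ny <- nrow(L); nx <- ncol(L)
  pairs <- rbind(
    cbind(as.vector(L[-ny, -nx]), as.vector(L[-1, -1])),
    cbind(as.vector(L[-1, -nx]), as.vector(L[-ny, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(n), find, integer(1))
    relab <- match(root, sort(unique(root)))
    L[L > 0] <- relab[L[L > 0]]
  }
  L
}

#' Cluster segmentation time course
#'
#' Per frame: background subtraction, thresholding (Otsu or fixed),
#' 8-connectivity connected components, and per-component centroid, area
#' and integrated intensity. When `unit_intensity` is given, an estimated
#' copy number (integrated intensity over the single-unit intensity,
#' rounded) is added.
#'
#' @param series An [image_series()].
#' @param threshold `"otsu"` or a fixed absolute intensity threshold.
#' @param min_area Minimum cluster area, um^2.
#' @param unit_intensity Integrated background-subtracted counts of one
#'   labeled unit, or `NULL`.
#' @return data.frame (class `cluster_table`) with one row per cluster per
#'   frame: `frame`, `time`, `id`, centroid `x`, `y` (um), `area_um2`,
#'   `intensity` and optionally `copies`. All-background frames contribute
#'   no rows.
#' @export
cluster_timecourse <- function(series, threshold = "otsu", min_area = 0.05,
                               unit_intensity = NULL) {
  stopifnot(inherits(series, "image_series"))
  px <- series$pixel_size
  d <- dim(series$frames)
  rows <- list()
  for (k in seq_len(d[3])) {
    f <- series$frames[, , k]
    bg <- stats::median(f)
    fs <- pmax(f - bg, 0)
    thr <- if (identical(threshold, "otsu")) {
      if (max(fs) <= 0) Inf else
        EBImage::otsu(EBImage::Image(fs / max(fs)), range = c(0, 1)) * max(fs)
    } else as.numeric(threshold) - bg
    mask <- fs > thr
    if (!any(mask)) next
    L <- label8(mask)
    ids <- seq_len(max(L))
    px_count <- tabulate(L[L > 0], nbins = max(L))
    keep <- which(px_count * px^2 >= min_area)
    if (!length(keep)) next
    idx <- which(L > 0, arr.ind = TRUE)
    lv <- L[L > 0]
    vals <- fs[L > 0]
    for (j in seq_along(keep)) {
      ci <- keep[j]
      sel <- lv == ci
      w <- vals[sel]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = k, time = series$timestamps[k], id = j,
        x = sum(w * (idx[sel, 2] - 0.5)) / sum(w) * px,
        y = sum(w * (idx[sel, 1] - 0.5)) / sum(w) * px,
        area_um2 = px_count[ci] * px^2,
        intensity = sum(w))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), time = numeric(0), id = integer(0),
               x = numeric(0), y = numeric(0), area_um2 = numeric(0),
               intensity = numeric(0))
  if (!is.null(unit_intensity)) out$copies <- round(out$intensity /
                                                      unit_intensity)
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Time-averaged MSD and anomalous exponent of a trajectory
#'
#' Computes the time-averaged mean squared displacement over lag times up
#' to `max_lag_fraction` of the track length, then fits
#' `log(MSD) ~ log(lag)`: the slope is the anomalous exponent `alpha`
#' (1 = diffusive, 2 = directed) and the diffusion coefficient follows
#' from `MSD = 4 D tau` for the 2D in-plane motion.
#'
#' @param traj A [trajectory_set()]; if several particles are present,
#'   time-averaged MSDs are averaged across particles.
#' @param max_lag_fraction Largest lag as a fraction of the track length.
#' @return Object of class `msd_result` with `lags` (s), `msd` (um^2),
#'   `alpha` and `D` (um^2/s).
#' @export
msd_exponent <- function(traj, max_lag_fraction = 0.25) {
  stopifnot(inherits(traj, "trajectory_set"))
  parts <- split(as.data.frame(traj), traj$particle)
  lens <- vapply(parts, nrow, integer(1))
  if (max(lens) < 20) stop("trajectory shorter than 20 samples")
  parts <- parts[lens >= 20]
  dt <- attr(traj, "frame_interval")
  max_lag <- max(2L, floor(max_lag_fraction * min(vapply(parts, nrow,
                                                         integer(1)))))
  msd_one <- function(p) {
    vapply(seq_len(max_lag), function(l) {
      dx <- p$x[-seq_len(l)] - p$x[seq_len(nrow(p) - l)]
      dy <- p$y[-seq_len(l)] - p$y[seq_len(nrow(p) - l)]
      mean(dx^2 + dy^2)
    }, numeric(1))
  }
  msd <- rowMeans(vapply(parts, msd_one, numeric(max_lag)))
  lags <- seq_len(max_lag) * dt
  if (all(msd <= 0) || max(msd) < 1e-12) {
    return(structure(list(lags = lags, msd = msd, alpha = NA_real_,
                          D = 0), class = "msd_result"))
  }
  fit <- stats::lm(log(msd) ~ log(lags))
  alpha <- stats::coef(fit)[[2]]
  D <- mean(msd / (4 * lags))
  structure(list(lags = lags, msd = msd, alpha = alpha, D = D),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("MSD: %d lags, alpha = %.3g, D = %.4g um^2/s\n",
              length(x$lags), x$alpha, x$D))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x$time, x$position, t(x$intensity),
                  xlab = "time (s)", ylab = "position (um)",
                  col = grDevices::gray.colors(256), ...)
  invisible(x)
}

#' @export
plot.msd_result <- function(x, ...) {
  graphics::plot(x$lags, x$msd, log = "xy", xlab = "lag (s)",
                 ylab = "MSD (um^2)", ...)
  invisible(x)
}
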