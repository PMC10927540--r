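# Brownian-advective tracer simulation in the confined flow (overdamped
# Euler-Maruyama), deposition onto a substrate, and stroke-width analysis.

#' Construct a trajectory set
#'
#' @param data data.frame with columns `particle`, `t` (s), `x`, `y`, `z`
#'   (um). Time must be strictly increasing within each particle and sampled
#'   at a uniform interval.
#' @param frame_interval Sampling interval, s.
#' @return Object of class `trajectory_set` (a data.frame with attributes
#'   `frame_interval` and `units = "um"`).
#' @export
trajectory_set <- function(data, frame_interval) {
  stopifnot(all(c("particle", "t", "x", "y", "z") %in% names(data)),
            frame_interval > 0)
  dt_ok <- vapply(split(data$t, data$particle),
                  function(tt) length(tt) < 2 || all(diff(tt) > 0),
                  logical(1))
  if (!all(dt_ok)) stop("time must be strictly increasing within particles")
  structure(data, frame_interval = frame_interval, units = "um",
            class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d particles, %d samples, frame interval %.3g s\n",
              length(unique(x$particle)), nrow(x), attr(x, "frame_interval")))
  invisible(x)
}

#' Simulate Brownian-advective tracers in the model flow
#'
#' Overdamped Euler--Maruyama update
#' `x <- x + v(x) dt + sqrt(2 D dt) * xi` per axis, with `xi` standard
#' normal. Particles are seeded on the injection opening (a sphere of the
#' injection inner radius around the source) and absorbed when they reach
#' the aspiration capture radius. If the geometry declares a substrate,
#' particles reflect specularly off z = 0.
#'
#' @param field A `flow_field` from [build_field()].
#' @param n Number of particles.
#' @param D Particle diffusivity, m^2/s (see [stokes_einstein()]).
#' @param dt Time step, s (default 1e-5). Rejected if the advective step
#'   near the openings would exceed half the smaller aperture radius.
#' @param duration Total simulated time, s.
#' @param seed Integer seed.
#' @return A [trajectory_set()]; absorbed particles end at their capture
#'   sample. Attribute `terminus` gives the per-particle fate
#'   (`"captured"`, `"active"`).
#' @export
simulate_tracers <- function(field, n, D, dt = 1e-5, duration, seed = 1) {
  stopifnot(inherits(field, "flow_field"), n >= 1, dt > 0, D >= 0)
  geo <- field$geometry
  r_rel <- geo$inner_diameter_inj / 2
  r_cap <- field$capture_radius
  D_um <- D * 1e12  # m^2/s -> um^2/s
  vmax <- max(abs(field$config$Q_inj) * NL_PER_S_TO_UM3 / (4 * pi * r_rel^2),
              abs(field$config$Q_asp) * NL_PER_S_TO_UM3 / (4 * pi * r_cap^2))
  if (vmax * dt > 0.5 * min(r_rel, r_cap)) {
    stop("dt too coarse: advective step exceeds half the aperture radius")
  }
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pos <- matrix(field$source, n, 3, byrow = TRUE) + dirs * r_rel * 1.0001
  n_steps <- max(1L, round(duration / dt))
  traj <- array(NA_real_, c(n, 3, n_steps + 1L))
  traj[, , 1L] <- pos
  active <- rep(TRUE, n)
  sig <- sqrt(2 * D_um * dt)
  for (k in seq_len(n_steps)) {
    if (!any(active)) break
    idx <- which(active)
    v <- field_velocity(field, pos[idx, , drop = FALSE])
    step <- v * dt
    if (D_um > 0) {
      step <- step + matrix(stats::rnorm(3 * length(idx), sd = sig), ncol = 3)
    }
    pos[idx, ] <- pos[idx, ] + step
    if (geo$substrate_present) {
      pos[idx, 3] <- abs(pos[idx, 3])
    }
    traj[idx, , k + 1L] <- pos[idx, ]
    d2 <- rowSums((pos[idx, , drop = FALSE] -
                     matrix(field$sink, length(idx), 3, byrow = TRUE))^2)
    captured <- d2 < r_cap^2
    active[idx[captured]] <- FALSE
  }
  dfs <- lapply(seq_len(n), function(i) {
    keep <- !is.na(traj[i, 1, ])
    data.frame(particle = i, t = (which(keep) - 1L) * dt,
               x = traj[i, 1, keep], y = traj[i, 2, keep],
               z = traj[i, 3, keep])
  })
  out <- trajectory_set(do.call(rbind, dfs), frame_interval = dt)
  attr(out, "terminus") <- ifelse(active, "active", "captured")
  out
}

#' Simulate deposition of particles onto the substrate while the tip writes
#'
#' Particles are released continuously from the injection opening while the
#' aperture pair translates along `tip_path` at `tip_speed` (quasi-static
#' flow: at each instant the field is the static source--sink field centered
#' on the current tip position). A particle contacting the substrate
#' (`z < particle radius`) adsorbs with probability `sticking_probability`
#' per contact and otherwise reflects specularly; particles reaching the
#' aspiration capture radius are removed.
#'
#' @param geometry A [device_geometry()] with `substrate_present = TRUE`.
#' @param config A [flow_config()].
#' @param n Number of particles released (evenly spaced release times,
#'   isotropic release directions).
#' @param D Particle diffusivity, m^2/s.
#' @param sticking_probability Probability of adsorption per substrate
#'   contact, in [0, 1].
#' @param tip_path Waypoint matrix (k x 2, um) for the in-plane tip
#'   translation (applied to both openings).
#' @param tip_speed Tip translation speed, um/s.
#' @param dt Time step, s.
#' @param particle_diameter Particle diameter, nm (sets the contact radius).
#' @param seed Integer seed.
#' @return Object of class `deposition_result`: data.frame of adsorbed
#'   positions `x`, `y` (um, z = 0) with arrival times `t`, plus attributes
#'   `tip_path` (time-stamped tip positions) and release statistics.
#' @export
simulate_deposition <- function(geometry, config, n, D,
                                sticking_probability = 1,
                                tip_path, tip_speed, dt = 1e-4,
                                particle_diameter = 200, seed = 1) {
  stopifnot(inherits(geometry, "device_geometry"))
  if (!geometry$substrate_present) {
    stop("deposition requires substrate_present = TRUE")
  }
  stopifnot(sticking_probability >= 0, sticking_probability <= 1,
            tip_speed > 0)
  tip_path <- matrix(tip_path, ncol = 2)
  field <- build_field(geometry, config)
  if (any(sqrt(rowSums(tip_path^2)) > field$r_max)) {
    stop("tip_path leaves the simulation box")
  }
  r_p <- particle_diameter / 2 * 1e-3  # nm -> um
  D_um <- D * 1e12
  r_rel <- geometry$inner_diameter_inj / 2
  r_cap <- field$capture_radius

  seg <- diff(tip_path)
  seg_len <- sqrt(rowSums(seg^2))
  cum_len <- c(0, cumsum(seg_len))
  total_len <- cum_len[length(cum_len)]
  duration <- total_len / tip_speed
  tip_at <- function(tt) {
    s <- pmin(tt * tip_speed, total_len)
    i <- pmax(findInterval(s, cum_len, rightmost.closed = TRUE), 1L)
    i <- pmin(i, nrow(tip_path) - 1L)
    frac <- (s - cum_len[i]) / pmax(seg_len[i], 1e-12)
    tip_path[i, , drop = FALSE] + seg[i, , drop = FALSE] * frac
  }

  set.seed(seed)
  n_steps <- ceiling(duration / dt) + ceiling(0.5 / dt)  # settle tail
  release_step <- pmax(1L, floor(seq(1L, max(1L, round(duration / dt)),
                                     length.out = n)))
  dirs <- matrix(stats::rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pos <- matrix(NA_real_, n, 3)
  state <- rep("pending", n)  # pending, active, stuck, aspirated
  dep <- vector("list", n)
  sig <- sqrt(2 * D_um * dt)
  src <- field$source
  for (k in seq_len(n_steps)) {
    tt <- k * dt
    off <- tip_at(tt)
    born <- which(state == "pending" & release_step <= k)
    if (length(born)) {
      pos[born, ] <- matrix(src, length(born), 3, byrow = TRUE) +
        dirs[born, , drop = FALSE] * r_rel * 1.0001
      pos[born, 1] <- pos[born, 1] + off[1]
      pos[born, 2] <- pos[born, 2] + off[2]
      state[born] <- "active"
    }
    idx <- which(state == "active")
    if (!length(idx)) next
    rel <- pos[idx, , drop = FALSE]
    rel[, 1] <- rel[, 1] - off[1]
    rel[, 2] <- rel[, 2] - off[2]
    v <- field_velocity(field, rel)
    step <- v * dt
    if (D_um > 0) {
      step <- step + matrix(stats::rnorm(3 * length(idx), sd = sig), ncol = 3)
    }
    pos[idx, ] <- pos[idx, ] + step
    # substrate contact
    contact <- pos[idx, 3] < r_p
    if (any(contact)) {
      ci <- idx[contact]
      stick <- stats::runif(length(ci)) < sticking_probability
      si <- ci[stick]
      if (length(si)) {
        dep[si] <- lapply(si, function(i) c(pos[i, 1], pos[i, 2], tt))
        state[si] <- "stuck"
      }
      ri <- ci[!stick]
      if (length(ri)) pos[ri, 3] <- 2 * r_p - pos[ri, 3]
    }
    idx <- which(state == "active")
    if (length(idx)) {
      rel <- pos[idx, , drop = FALSE]
      rel[, 1] <- rel[, 1] - off[1]
      rel[, 2] <- rel[, 2] - off[2]
      d2 <- rowSums((rel - matrix(field$sink, length(idx), 3,
                                  byrow = TRUE))^2)
      state[idx[d2 < r_cap^2]] <- "aspirated"
    }
  }
  stuck <- which(state == "stuck")
  res <- if (length(stuck)) {
    m <- do.call(rbind, dep[stuck])
    data.frame(x = m[, 1], y = m[, 2], t = m[, 3])
  } else {
    data.frame(x = numeric(0), y = numeric(0), t = numeric(0))
  }
  tp_times <- seq(0, duration, length.out = 200)
  structure(res,
            tip_path = cbind(t = tp_times, tip_at(tp_times)),
            n_released = n,
            n_adsorbed = length(stuck),
            n_aspirated = sum(state == "aspirated"),
            class = c("deposition_result", "data.frame"))
}

#' @export
print.deposition_result <- function(x, ...) {
  cat(sprintf("Deposition result: %d adsorbed / %d released (%d aspirated)\n",
              attr(x, "n_adsorbed"), attr(x, "n_released"),
              attr(x, "n_aspirated")))
  invisible(x)
}

# FWHM of a binned histogram with linear interpolation at the half-maximum
# crossings; returns at least one bin width for degenerate (single-bin) data.
fwhm_from_histogram <- function(values, bin_width) {
  br <- seq(floor(min(values) / bin_width) * bin_width - bin_width,
            ceiling(max(values) / bin_width) * bin_width + bin_width,
            by = bin_width)
  hh <- graphics::hist(values, breaks = br, plot = FALSE)
  cnt <- hh$counts
  mid <- hh$mids
  pk <- which.max(cnt)
  half <- cnt[pk] / 2
  above <- which(cnt >= half)
  lo <- min(above); hi <- max(above)
  left <- if (lo == 1) mid[lo] - bin_width / 2 else {
    mid[lo - 1] + (half - cnt[lo - 1]) / (cnt[lo] - cnt[lo - 1]) * bin_width
  }
  right <- if (hi == length(cnt)) mid[hi] + bin_width / 2 else {
    mid[hi] + (cnt[hi] - half) / (cnt[hi] - cnt[hi + 1]) * bin_width
  }
  max(right - left, bin_width)
}

#' Mean transverse stroke width (FWHM) of a deposition pattern
#'
#' Projects each adsorbed particle onto the tip path, bins deposits into
#' `n_cross_sections` stations along the path, and measures the full width
#' at half maximum of the transverse histogram at each station. Stations
#' with fewer than 5 deposits are skipped (recorded in the result).
#'
#' @param result A [simulate_deposition()] result with at least 50 adsorbed
#'   particles.
#' @param n_cross_sections Number of stations along the path.
#' @param bin_width Transverse histogram bin width, um.
#' @return List with `mean_fwhm` (um), per-station data.frame `stations`
#'   and the skipped-station count.
#' @export
stroke_width <- function(result, n_cross_sections = 10, bin_width = 0.5) {
  stopifnot(inherits(result, "deposition_result"))
  if (nrow(result) < 50) stop("need at least 50 adsorbed particles")
  tp <- attr(result, "tip_path")[, 2:3, drop = FALSE]
  seg <- diff(tp)
  seg_len <- sqrt(rowSums(seg^2))
  keep <- seg_len > 1e-12
  seg <- seg[keep, , drop = FALSE]
  p0 <- tp[which(keep), , drop = FALSE]
  seg_len <- seg_len[keep]
  cum <- c(0, cumsum(seg_len))
  # project deposits on the polyline: station coordinate s and signed
  # transverse offset
  n <- nrow(result)
  s_coord <- numeric(n); t_coord <- numeric(n)
  P <- cbind(result$x, result$y)
  best <- rep(Inf, n)
  for (j in seq_len(nrow(seg))) {
    u <- seg[j, ] / seg_len[j]
    d <- P - matrix(p0[j, ], n, 2, byrow = TRUE)
    along <- pmin(pmax(d %*% u, 0), seg_len[j])
    perp <- d[, 1] * (-u[2]) + d[, 2] * u[1]
    dist2 <- (d[, 1] - along * u[1])^2 + (d[, 2] - along * u[2])^2
    upd <- dist2 < best
    best[upd] <- dist2[upd]
    s_coord[upd] <- cum[j] + along[upd]
    t_coord[upd] <- perp[upd]
  }
  stations <- cut(s_coord, breaks = seq(0, cum[length(cum)],
                                        length.out = n_cross_sections + 1),
                  include.lowest = TRUE, labels = FALSE)
  fw <- rep(NA_real_, n_cross_sections)
  counts <- integer(n_cross_sections)
  for (st in seq_len(n_cross_sections)) {
    vals <- t_coord[which(stations == st)]
    counts[st] <- length(vals)
    if (length(vals) >= 5) fw[st] <- fwhm_from_histogram(vals, bin_width)
  }
  skipped <- sum(is.na(fw))
  list(mean_fwhm = mean(fw, na.rm = TRUE),
       stations = data.frame(station = seq_len(n_cross_sections),
                             n = counts, fwhm = fw),
       n_skipped = skipped)
}

#' Write a trajectory set or deposition result as CSV
#'
#' @param x Object to write.
#' @param path Output path.
#' @export
write_trajectories_csv <- function(x, path) {
  stopifnot(inherits(x, "trajectory_set"))
  df <- as.data.frame(x)
  attr(df, "frame_interval") <- NULL
  utils::write.csv(cbind(df,
                         frame_interval = attr(x, "frame_interval")),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  df <- utils::read.csv(path)
  fi <- df$frame_interval[1]
  df$frame_interval <- NULL
  trajectory_set(df, frame_interval = fi)
}
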