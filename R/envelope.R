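# Streamline tracing and envelope (separatrix) geometry of the injected fluid.

#' Trace a streamline of the model flow field
#'
#' Integrates the unit-tangent equation dx/ds = v/|v| (arc-length
#' parameterization) with an adaptive-step solver, stopping when the path is
#' captured by the aspiration opening, escapes the simulation region, or
#' stagnates.
#'
#' @param field A `flow_field` from [build_field()].
#' @param start Length-3 starting position (um), outside the exclusion
#'   spheres of both openings.
#' @param max_arc_length Maximum arc length to integrate (um); default
#'   `4 * field$r_max`.
#' @param ds Output sampling interval along the path (um).
#' @return List with `path` (n x 3 matrix of positions), `arc_length`,
#'   and `terminus`, one of `"captured_by_aspiration"`, `"escaped"`,
#'   `"exhausted"` (stagnation or arc-length budget spent, with the final
#'   location in `path`).
#' @export
trace_streamline <- function(field, start, max_arc_length = NULL, ds = NULL) {
  stopifnot(inherits(field, "flow_field"), length(start) == 3)
  v0 <- field_velocity(field, start)
  if (attr(v0, "near_singular")[1]) {
    stop("streamline start lies inside an aperture exclusion sphere")
  }
  if (is.null(max_arc_length)) max_arc_length <- 4 * field$r_max
  if (is.null(ds)) ds <- field$capture_radius / 5
  # characteristic speed at the capture radius; used for stagnation tolerance
  vchar <- abs(field$config$Q_asp) * NL_PER_S_TO_UM3 /
    (4 * pi * field$capture_radius^2)
  if (vchar == 0) {
    vchar <- max(abs(field$config$Q_inj), 1e-12) * NL_PER_S_TO_UM3 /
      (4 * pi * field$capture_radius^2)
  }
  vtol <- 1e-8 * vchar
  center <- (field$source + field$sink) / 2

  # lean scalar evaluator (hot path of the integrator)
  cx <- field$centers[, 1]; cy <- field$centers[, 2]; cz <- field$centers[, 3]
  qk <- field$strengths / (4 * pi)
  vel3 <- function(y) {
    dx <- y[1] - cx; dy <- y[2] - cy; dz <- y[3] - cz
    r2 <- dx * dx + dy * dy + dz * dz
    w <- qk / (r2 * sqrt(r2))
    c(sum(w * dx), sum(w * dy), sum(w * dz))
  }
  snk <- field$sink
  capr <- field$capture_radius
  rmax <- field$r_max
  deriv <- function(s, y, parms) {
    v <- vel3(y)
    sp <- sqrt(sum(v * v))
    if (sp < vtol) return(list(c(0, 0, 0)))
    list(v / sp)
  }
  rootfun <- function(s, y, parms) {
    v <- vel3(y)
    c(sqrt((y[1] - snk[1])^2 + (y[2] - snk[2])^2 + (y[3] - snk[3])^2) - capr,
      rmax - sqrt((y[1] - center[1])^2 + (y[2] - center[2])^2 +
                    (y[3] - center[3])^2),
      sqrt(sum(v * v)) / vchar - 1e-8)
  }
  times <- seq(0, max_arc_length, by = ds)
  out <- deSolve::lsodar(y = start, times = times, func = deriv,
                         rootfunc = rootfun, rtol = 1e-6, atol = 1e-9)
  path <- unname(out[, 2:4, drop = FALSE])
  end <- path[nrow(path), ]
  terminus <- if (sqrt(sum((end - field$sink)^2)) <=
                  field$capture_radius * (1 + 1e-6)) {
    "captured_by_aspiration"
  } else if (sqrt(sum((end - center)^2)) >= field$r_max * (1 - 1e-6)) {
    "escaped"
  } else {
    "exhausted"
  }
  list(path = path, arc_length = out[nrow(out), 1], terminus = terminus)
}

#' Compute the perfusion envelope of the injected fluid
#'
#' Launches streamlines isotropically from an epsilon-sphere around the
#' injection opening, integrates each until capture, and rasterizes the
#' visited region onto a voxel grid. The free-space source--sink field is
#' axisymmetric about the source--sink axis, so the rasterization collapses
#' each visited point to (x, rho) coordinates, fills the occupied region
#' radially (the separatrix interior is radially simply connected), and
#' counts 3D voxels by revolution.
#'
#' @param geometry A [device_geometry()]. The envelope is always computed in
#'   the free-space model (without substrate images), which is the
#'   configuration the envelope-size analysis refers to.
#' @param config A [flow_config()] with `Q_ratio < 1`.
#' @param n_streamlines Number of launched streamlines.
#' @param raster_resolution Voxel edge (um); default 1/50 of the injection
#'   aperture inner diameter.
#' @param seed Integer seed controlling the isotropic launch directions.
#' @return Object of class `flow_envelope` with elements `volume_fl`
#'   (femtoliters; 1 fl = 1 um^3), `extent` (maximum in-plane caliper width,
#'   um), `boundary_points` (n x 3 um), `boundary_2d` (data.frame with x,
#'   rho and ring-area weights on the separatrix), `profile` (occupied
#'   radius vs x), `raster_resolution`, capture statistics and the inputs.
#' @export
compute_envelope <- function(geometry, config, n_streamlines = 2000,
                             raster_resolution = NULL, seed = 1) {
  stopifnot(inherits(geometry, "device_geometry"),
            inherits(config, "flow_config"))
  if (config$Q_ratio >= 1) stop("Q_ratio >= 1: no confinement possible")
  geo_free <- geometry
  geo_free$substrate_present <- FALSE
  field <- build_field(geo_free, config)
  if (is.null(raster_resolution)) {
    raster_resolution <- geometry$inner_diameter_inj / 50
  }
  h <- raster_resolution
  axis_z <- geo_free$tip_height

  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * n_streamlines), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  starts <- matrix(field$source, n_streamlines, 3, byrow = TRUE) +
    dirs * field$eps * 1.0001

  term <- character(n_streamlines)
  ix_all <- vector("list", n_streamlines)
  ir_all <- vector("list", n_streamlines)
  x_off <- 4 * field$r_max  # shift so indices are positive
  for (i in seq_len(n_streamlines)) {
    tr <- trace_streamline(field, starts[i, ], ds = h / 2)
    term[i] <- tr$terminus
    p <- tr$path
    rho <- sqrt(p[, 2]^2 + (p[, 3] - axis_z)^2)
    ix_all[[i]] <- as.integer(floor((p[, 1] + x_off) / h))
    ir_all[[i]] <- as.integer(floor(rho / h))
  }
  n_escaped <- sum(term == "escaped")
  if (n_escaped > 0) {
    stop(sprintf("confinement violated: %.1f%% of streamlines escaped",
                 100 * n_escaped / n_streamlines))
  }

  ix <- unlist(ix_all); ir <- unlist(ir_all)
  ix_rng <- range(ix)
  # occupied radius per x column (radial fill from the axis)
  rho_max_idx <- rep(-1L, ix_rng[2] - ix_rng[1] + 1L)
  col <- ix - ix_rng[1] + 1L
  agg <- tapply(ir, col, max)
  rho_max_idx[as.integer(names(agg))] <- as.integer(agg)

  # 3D voxel count by revolution: ring counts of (y, z) voxel centers per
  # radial cell index
  kmax <- max(rho_max_idx)
  ncells <- kmax + 2L
  cyz <- (seq_len(2 * ncells) - ncells - 0.5) * h
  rc <- sqrt(outer(cyz^2, cyz^2, "+"))
  ring_counts <- tabulate(pmin(floor(rc / h), ncells) + 1L, nbins = kmax + 1L)
  cum_ring <- cumsum(ring_counts)
  occ_cols <- rho_max_idx >= 0L
  voxels_per_col <- ifelse(occ_cols, cum_ring[rho_max_idx + 1L], 0)
  volume_fl <- sum(voxels_per_col) * h^3

  xs <- (seq_along(rho_max_idx) - 1L + ix_rng[1]) * h + h / 2 - x_off
  profile <- data.frame(x = xs[occ_cols],
                        rho_max = (rho_max_idx[occ_cols] + 0.5) * h)

  # separatrix as 2D boundary cells: the outermost occupied cell per column,
  # plus full columns at the x extremities
  b2 <- profile
  end_cols <- which(occ_cols)[c(1, sum(occ_cols))]
  for (ec in end_cols) {
    kk <- seq_len(rho_max_idx[ec] + 1L) - 1L
    if (length(kk) > 1) {
      b2 <- rbind(b2, data.frame(x = xs[ec], rho_max = (kk[-length(kk)] + 0.5) * h))
    }
  }
  names(b2) <- c("x", "rho")
  b2$weight <- pmax(b2$rho, h / 2)  # ring area ~ 2 pi rho per unit cell

  # representative 3D boundary cloud (16 azimuths per boundary cell)
  az <- seq(0, 2 * pi, length.out = 17)[-17]
  boundary_points <- cbind(
    x = rep(b2$x, each = length(az)),
    y = as.vector(outer(cos(az), b2$rho)),
    z = axis_z + as.vector(outer(sin(az), b2$rho))
  )

  # maximum in-plane caliper width of the occupied set
  pp <- rbind(cbind(b2$x, b2$rho), cbind(b2$x, -b2$rho))
  extent <- sqrt(max(stats::dist(pp))^2)

  structure(
    list(
      volume_fl = volume_fl,
      extent = extent,
      boundary_points = boundary_points,
      boundary_2d = b2,
      profile = profile,
      raster_resolution = h,
      n_streamlines = n_streamlines,
      seed = seed,
      captured_fraction = mean(term == "captured_by_aspiration"),
      exhausted_fraction = mean(term == "exhausted"),
      axis_z = axis_z,
      geometry = geometry,
      config = config
    ),
    class = "flow_envelope"
  )
}

#' @export
print.flow_envelope <- function(x, ...) {
  cat("Perfusion envelope (reduced-order source-sink model)\n")
  cat(sprintf("  volume %.4g fl, in-plane extent %.4g um (voxel %.3g um)\n",
              x$volume_fl, x$extent, x$raster_resolution))
  cat(sprintf("  %d streamlines: %.1f%% captured, %.1f%% exhausted (seed %d)\n",
              x$n_streamlines, 100 * x$captured_fraction,
              100 * x$exhausted_fraction, x$seed))
  invisible(x)
}

#' Mean flow speed on the envelope boundary
#'
#' Area-weighted mean of |v| over the separatrix surface, exploiting the
#' axisymmetry of the free-space field.
#'
#' @param envelope A `flow_envelope`.
#' @return Mean boundary speed in um/s.
#' @export
mean_boundary_speed <- function(envelope) {
  geo <- envelope$geometry
  geo$substrate_present <- FALSE
  field <- build_field(geo, envelope$config)
  pts <- cbind(envelope$boundary_2d$x, envelope$boundary_2d$rho,
               envelope$axis_z)
  v <- field_velocity(field, pts)
  sp <- sqrt(rowSums(v^2))
  stats::weighted.mean(sp, envelope$boundary_2d$weight)
}

#' Sample flow speeds along a line through the envelope
#'
#' @param geometry,config Device geometry and flow configuration.
#' @param line 2 x 3 matrix: rows are the segment start and end (um).
#'   Default: the perpendicular to the source--sink axis through the envelope
#'   midpoint, spanning one tip separation to either side.
#' @param n_samples Number of sample points.
#' @return data.frame with arc position `s`, coordinates and `speed` (um/s).
#' @export
axial_velocity_profile <- function(geometry, config, line = NULL,
                                   n_samples = 100) {
  field <- build_field(geometry, config)
  if (is.null(line)) {
    d <- geometry$tip_separation
    h <- geometry$tip_height
    line <- rbind(c(d / 2, -d, h), c(d / 2, d, h))
  }
  tt <- seq(0, 1, length.out = n_samples)
  pts <- cbind(line[1, 1] + tt * (line[2, 1] - line[1, 1]),
               line[1, 2] + tt * (line[2, 2] - line[1, 2]),
               line[1, 3] + tt * (line[2, 3] - line[1, 3]))
  v <- field_velocity(field, pts)
  if (any(attr(v, "near_singular"))) {
    stop("profile line passes through an aperture exclusion sphere")
  }
  seg_len <- sqrt(sum((line[2, ] - line[1, ])^2))
  data.frame(s = tt * seg_len, x = pts[, 1], y = pts[, 2], z = pts[, 3],
             speed = sqrt(rowSums(v^2)))
}

#' Shear stress report at sample points
#'
#' Shear stress is `viscosity * gdot` with shear rate
#' `gdot = sqrt(2 * sum(E^2))`, `E = (grad v + grad v^T)/2` computed from the
#' analytic gradient of the source--sink field. Points inside an aperture
#' exclusion sphere are excluded from the report.
#'
#' @param points n x 3 matrix of sample positions (um).
#' @param geometry,config Device geometry and flow configuration.
#' @return Object of class `shear_report`: data.frame of retained points with
#'   `shear_stress` (Pa), plus attributes `max_abs_shear`, `max_location`
#'   and `n_excluded`.
#' @export
shear_report <- function(points, geometry, config) {
  field <- build_field(geometry, config)
  points <- as_point_matrix(points)
  v <- field_velocity(field, points)
  keep <- !attr(v, "near_singular")
  n_excluded <- sum(!keep)
  pts <- points[keep, , drop = FALSE]
  g <- field_gradient(field, pts)
  n <- nrow(pts)
  gdot <- numeric(n)
  for (i in seq_len(n)) {
    E <- (g[, , i] + t(g[, , i])) / 2
    gdot[i] <- sqrt(2 * sum(E * E))
  }
  stress <- config$viscosity * 1e-3 * gdot  # mPa s * 1/s -> Pa
  res <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    shear_stress = stress)
  imax <- if (n > 0) which.max(abs(stress)) else integer(0)
  structure(res,
            max_abs_shear = if (n > 0) abs(stress[imax]) else NA_real_,
            max_location = if (n > 0) unlist(res[imax, 1:3]) else NULL,
            n_excluded = n_excluded,
            class = c("shear_report", "data.frame"))
}

#' @export
print.shear_report <- function(x, ...) {
  cat(sprintf("Shear report: %d points (%d excluded near apertures)\n",
              nrow(x), attr(x, "n_excluded")))
  cat(sprintf("  max |shear| %.4g Pa at (%.3g, %.3g, %.3g) um\n",
              attr(x, "max_abs_shear"),
              attr(x, "max_location")[1], attr(x, "max_location")[2],
              attr(x, "max_location")[3]))
  invisible(x)
}

#' Export an envelope boundary as CSV and its occupancy grid as a TIFF stack
#'
#' @param envelope A `flow_envelope`.
#' @param path Output file path.
#' @param resolution Voxel edge for the occupancy stack (um); default the
#'   envelope raster resolution (can be coarsened for export).
#' @return The path, invisibly.
#' @export
write_envelope_csv <- function(envelope, path) {
  df <- as.data.frame(envelope$boundary_points)
  names(df) <- c("x_um", "y_um", "z_um")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_envelope_csv
#' @export
write_envelope_tiff <- function(envelope, path, resolution = NULL) {
  if (is.null(resolution)) resolution <- envelope$raster_resolution
  occ <- envelope_occupancy(envelope, resolution)
  frames <- lapply(seq_len(dim(occ)[3]),
                   function(k) matrix(as.numeric(occ[, , k]),
                                      nrow = dim(occ)[1]))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Realize the envelope occupancy as a 3D logical voxel array
#'
#' @inheritParams write_envelope_csv
#' @param resolution Voxel edge (um).
#' @return Logical array (x, y, z) with voxel-center coordinates as
#'   attributes `x`, `y`, `z`.
#' @export
envelope_occupancy <- function(envelope, resolution = NULL) {
  if (is.null(resolution)) resolution <- envelope$raster_resolution
  h <- resolution
  pr <- envelope$profile
  f <- stats::approxfun(pr$x, pr$rho_max, yleft = -1, yright = -1)
  xr <- range(pr$x)
  xc <- seq(xr[1], xr[2], by = h)
  rmax <- max(pr$rho_max)
  yc <- seq(-rmax - h, rmax + h, by = h)
  zc <- envelope$axis_z + yc
  occ <- array(FALSE, c(length(xc), length(yc), length(zc)))
  rr <- sqrt(outer(yc^2, (zc - envelope$axis_z)^2, "+"))
  for (i in seq_along(xc)) {
    occ[i, , ] <- rr <= f(xc[i])
  }
  attr(occ, "x") <- xc; attr(occ, "y") <- yc; attr(occ, "z") <- zc
  occ
}

#' @export
plot.flow_envelope <- function(x, ...) {
  pr <- x$profile
  graphics::plot(c(pr$x, rev(pr$x)), c(pr$rho_max, -rev(pr$rho_max)),
                 type = "l", xlab = "x (um)", ylab = "rho (um)",
                 main = "Envelope separatrix", asp = 1, ...)
  graphics::points(c(0, x$geometry$tip_separation), c(0, 0), pch = 3)
  invisible(x)
}
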