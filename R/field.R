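# Point source-sink superposition model of the confined perfusion flow.
# Internal units: lengths um, flow rates um^3/s (1 nl/s = 1e6 um^3/s),
# velocities um/s.

NL_PER_S_TO_UM3 <- 1e6

#' Build the reduced-order velocity field of the aperture pair
#'
#' The confined flow is modelled as the potential-flow superposition of a
#' point source of strength `Q_inj` at the injection opening and a point sink
#' of strength `Q_asp` at the aspiration opening; each monopole contributes
#' `|v| = Q / (4 pi r^2)` directed away from (source) or toward (sink) the
#' opening. If the geometry declares a substrate, the source and sink are
#' mirrored across z = 0 so the normal velocity vanishes on the substrate
#' plane (no-penetration; the model does not enforce no-slip).
#'
#' @param geometry A [device_geometry()].
#' @param config A [flow_config()] with `Q_ratio < 1` (otherwise the injected
#'   fluid cannot be confined and the call errors).
#' @return An object of class `flow_field`: a list with `velocity(points)`
#'   (n x 3 matrix of um positions to n x 3 um/s velocities, with a
#'   `near_singular` logical attribute flagging points inside the exclusion
#'   radius of either opening), `gradient(points)` (velocity-gradient tensors,
#'   3 x 3 x n, units 1/s), the source/sink positions, exclusion radius
#'   `eps`, `capture_radius` and escape radius `r_max`.
#' @export
build_field <- function(geometry, config) {
  stopifnot(inherits(geometry, "device_geometry"),
            inherits(config, "flow_config"))
  # degenerate single-monopole configurations (pure source or pure sink)
  # are allowed for field evaluation and tracing; only a true two-aperture
  # configuration with insufficient aspiration is rejected
  if (config$Q_inj > 0 && config$Q_asp > 0 && config$Q_ratio >= 1) {
    stop("Q_ratio >= 1: no confinement possible")
  }
  h <- geometry$tip_height
  src <- c(0, 0, h)
  snk <- c(geometry$tip_separation, 0, h)
  # monopole strengths in um^3/s; positive = source
  strengths <- c(config$Q_inj, -config$Q_asp) * NL_PER_S_TO_UM3
  centers <- rbind(src, snk)
  if (geometry$substrate_present) {
    centers <- rbind(centers, cbind(centers[, 1:2], -centers[, 3]))
    strengths <- c(strengths, strengths)
  }
  eps <- 0.1 * min(geometry$inner_diameter_inj,
                   geometry$inner_diameter_asp) / 2
  field <- list(
    source = src,
    sink = snk,
    centers = centers,
    strengths = strengths,
    eps = eps,
    capture_radius = geometry$inner_diameter_asp / 2,
    r_max = 50 * max(geometry$inner_diameter_inj,
                     geometry$inner_diameter_asp),
    geometry = geometry,
    config = config
  )
  field$velocity <- function(points) field_velocity(field, points)
  field$gradient <- function(points) field_gradient(field, points)
  class(field) <- "flow_field"
  field
}

#' @export
print.flow_field <- function(x, ...) {
  cat("Point source-sink flow field\n")
  cat(sprintf("  source at (%.3g, %.3g, %.3g) um, sink at (%.3g, %.3g, %.3g) um\n",
              x$source[1], x$source[2], x$source[3],
              x$sink[1], x$sink[2], x$sink[3]))
  cat(sprintf("  Q_inj %.4g nl/s, Q_asp %.4g nl/s%s\n",
              x$config$Q_inj, x$config$Q_asp,
              if (x$geometry$substrate_present) ", substrate images on" else ""))
  invisible(x)
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  points
}

#' Evaluate the model velocity field
#'
#' @param field A `flow_field` from [build_field()].
#' @param points n x 3 matrix (or length-3 vector) of positions in um.
#' @return n x 3 matrix of velocities in um/s, with attribute `near_singular`
#'   flagging points inside the exclusion radius of either physical opening.
#' @export
field_velocity <- function(field, points) {
  points <- as_point_matrix(points)
  n <- nrow(points)
  v <- matrix(0, n, 3)
  for (k in seq_along(field$strengths)) {
    d <- points - matrix(field$centers[k, ], n, 3, byrow = TRUE)
    r2 <- rowSums(d * d)
    r2 <- pmax(r2, 1e-300)
    coef <- field$strengths[k] / (4 * pi) / (r2 * sqrt(r2))
    v <- v + d * coef
  }
  near <- rep(FALSE, n)
  for (k in 1:2) {
    d <- points - matrix(field$centers[k, ], n, 3, byrow = TRUE)
    near <- near | rowSums(d * d) < field$eps^2
  }
  attr(v, "near_singular") <- near
  v
}

#' Analytic velocity gradient of the model field
#'
#' @inheritParams field_velocity
#' @return 3 x 3 x n array of velocity gradients (d v_i / d x_j), 1/s.
#' @export
field_gradient <- function(field, points) {
  points <- as_point_matrix(points)
  n <- nrow(points)
  g <- array(0, c(3, 3, n))
  eye <- diag(3)
  for (k in seq_along(field$strengths)) {
    d <- points - matrix(field$centers[k, ], n, 3, byrow = TRUE)
    r2 <- pmax(rowSums(d * d), 1e-300)
    r3 <- r2 * sqrt(r2)
    r5 <- r3 * r2
    q <- field$strengths[k] / (4 * pi)
    for (i in 1:3) for (j in 1:3) {
      g[i, j, ] <- g[i, j, ] + q * (eye[i, j] / r3 - 3 * d[, i] * d[, j] / r5)
    }
  }
  g
}

#' Volumetric flux through a sphere by numeric quadrature
#'
#' Integrates the outward normal velocity over a sphere using a Fibonacci
#' point set; used to verify mass conservation of the model field.
#'
#' @param field A `flow_field`.
#' @param center Sphere center (um).
#' @param radius Sphere radius (um).
#' @param n Number of quadrature nodes.
#' @return Net outward volumetric flux in nl/s.
#' @export
flux_through_sphere <- function(field, center, radius, n = 20000) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  normals <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  pts <- normals * radius +
    matrix(center, n, 3, byrow = TRUE)
  v <- field_velocity(field, pts)
  mean(rowSums(v * normals)) * 4 * pi * radius^2 / NL_PER_S_TO_UM3
}
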