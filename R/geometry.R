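#' Device geometry for a two-aperture perfusion pair
#'
#' Describes the injecting/aspirating micropipette aperture pair. All lengths
#' are in micrometers. The coordinate convention used throughout the package
#' is: substrate plane at z = 0 with z pointing up, and the source--sink axis
#' along x, with the injection opening at (0, 0, tip_height) and the
#' aspiration opening at (tip_separation, 0, tip_height).
#'
#' @param inner_diameter_inj Inner diameter of the injection aperture (um).
#' @param inner_diameter_asp Inner diameter of the aspiration aperture (um);
#'   defaults to the injection diameter.
#' @param wall_thickness Pipette wall thickness at the tip (um).
#' @param tip_separation Center-to-center distance between the two openings
#'   (um). Default places the outer rims in touching contact:
#'   `(d_inj + d_asp)/2 + 2 * wall_thickness`.
#' @param in_plane_angle Angle between the two pipette axes, degrees, in
#'   (0, 90]. The reduced-order model treats the openings as points, so the
#'   angle only documents the physical arrangement.
#' @param tip_height Height of the aperture centers above the substrate plane
#'   z = 0 (um). Defaults to the larger inner diameter.
#' @param substrate_present If `TRUE`, a no-penetration substrate at z = 0 is
#'   included in the flow model via an image system.
#'
#' @return An object of class `device_geometry`.
#' @export
device_geometry <- function(inner_diameter_inj = 1,
                            inner_diameter_asp = inner_diameter_inj,
                            wall_thickness = 1,
                            tip_separation = NULL,
                            in_plane_angle = 35,
                            tip_height = NULL,
                            substrate_present = FALSE) {
  if (is.null(tip_separation)) {
    tip_separation <- (inner_diameter_inj + inner_diameter_asp) / 2 +
      2 * wall_thickness
  }
  if (is.null(tip_height)) {
    tip_height <- max(inner_diameter_inj, inner_diameter_asp)
  }
  stopifnot(
    inner_diameter_inj > 0, inner_diameter_asp > 0,
    wall_thickness > 0, tip_separation > 0, tip_height > 0
  )
  min_sep <- (inner_diameter_inj + inner_diameter_asp) / 2 + 2 * wall_thickness
  if (tip_separation < min_sep - 1e-9) {
    stop("tip_separation smaller than the sum of the outer radii (",
         signif(min_sep, 4), " um): pipettes would overlap")
  }
  if (!(in_plane_angle > 0 && in_plane_angle <= 90)) {
    stop("in_plane_angle must lie in (0, 90] degrees")
  }
  structure(
    list(
      inner_diameter_inj = inner_diameter_inj,
      inner_diameter_asp = inner_diameter_asp,
      wall_thickness = wall_thickness,
      tip_separation = tip_separation,
      in_plane_angle = in_plane_angle,
      tip_height = tip_height,
      substrate_present = isTRUE(substrate_present)
    ),
    class = "device_geometry"
  )
}

#' @export
print.device_geometry <- function(x, ...) {
  cat("Two-aperture device geometry (um):\n")
  cat(sprintf("  inner diameters: %.3g (inj) / %.3g (asp), wall %.3g\n",
              x$inner_diameter_inj, x$inner_diameter_asp, x$wall_thickness))
  cat(sprintf("  tip separation %.3g, tip height %.3g, in-plane angle %.3g deg\n",
              x$tip_separation, x$tip_height, x$in_plane_angle))
  cat(sprintf("  substrate image system: %s\n",
              if (x$substrate_present) "on" else "off"))
  invisible(x)
}

#' Flow configuration for the aperture pair
#'
#' @param Q_inj Injection volumetric flow rate, nl/s (> 0).
#' @param Q_asp Aspiration volumetric flow rate, nl/s (> 0).
#' @param viscosity Dynamic viscosity of the working fluid, mPa s.
#'   Default 0.9544 (water at 22 C).
#' @param temperature Temperature, degrees C.
#' @param density Fluid density, kg/m^3.
#'
#' @return Object of class `flow_config` with derived field `Q_ratio`.
#'   Confinement of the injected fluid requires `Q_ratio < 1` in the model;
#'   `Q_ratio < 0.8` is the empirical criterion for reliable confinement.
#' @export
flow_config <- function(Q_inj, Q_asp, viscosity = 0.9544,
                        temperature = 22, density = 998) {
  stopifnot(Q_inj >= 0, Q_asp >= 0, viscosity > 0, density > 0,
            temperature > -273.15)
  structure(
    list(
      Q_inj = Q_inj, Q_asp = Q_asp,
      Q_ratio = if (Q_asp > 0) Q_inj / Q_asp else Inf,
      viscosity = viscosity, temperature = temperature, density = density
    ),
    class = "flow_config"
  )
}

#' @export
print.flow_config <- function(x, ...) {
  cat(sprintf("Flow config: Q_inj %.4g nl/s, Q_asp %.4g nl/s (Q_ratio %.3g)\n",
              x$Q_inj, x$Q_asp, x$Q_ratio))
  cat(sprintf("  viscosity %.4g mPa s at %.3g C, density %.4g kg/m^3\n",
              x$viscosity, x$temperature, x$density))
  invisible(x)
}

#' Read / write geometry and flow configuration as YAML
#'
#' @param path File path.
#' @return `read_geometry_yaml` returns a `device_geometry`;
#'   `read_flow_config_yaml` a `flow_config`.
#' @export
read_geometry_yaml <- function(path) {
  do.call(device_geometry, yaml::read_yaml(path))
}

#' @rdname read_geometry_yaml
#' @param x Object to serialize.
#' @export
write_geometry_yaml <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname read_geometry_yaml
#' @export
read_flow_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$Q_ratio <- NULL
  do.call(flow_config, vals)
}

#' @rdname read_geometry_yaml
#' @export
write_flow_config_yaml <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}
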