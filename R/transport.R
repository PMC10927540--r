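# Dimensionless transport analysis: Stokes-Einstein, Peclet, Damkohler,
# Reynolds, and regime classification. SI units throughout this module
# (m, s, kg); diffusivities in m^2/s.

BOLTZMANN <- 1.380649e-23  # J/K
AVOGADRO <- 6.02214076e23  # 1/mol

#' Stokes--Einstein diffusivity of a sphere
#'
#' `D = kB * T / (3 * pi * mu * d)` for a sphere of diameter `d` in a fluid
#' of dynamic viscosity `mu` at absolute temperature `T`.
#'
#' @param particle_diameter Sphere diameter, nm.
#' @param temperature Temperature, degrees C (default 22).
#' @param viscosity Dynamic viscosity, mPa s (default 0.9544, water at 22 C).
#' @return Diffusivity in m^2/s.
#' @export
stokes_einstein <- function(particle_diameter, temperature = 22,
                            viscosity = 0.9544) {
  stopifnot(all(particle_diameter > 0), temperature > -273.15, viscosity > 0)
  T_k <- temperature + 273.15
  BOLTZMANN * T_k / (3 * pi * viscosity * 1e-3 * particle_diameter * 1e-9)
}

#' Peclet number
#'
#' Ratio of advective to diffusive transport rates, `Pe = v * L / D`.
#'
#' @param speed Characteristic speed, m/s.
#' @param length Characteristic length, m.
#' @param diffusivity Diffusivity, m^2/s.
#' @return Dimensionless Peclet number.
#' @export
peclet <- function(speed, length, diffusivity) {
  stopifnot(all(speed > 0), all(length > 0), all(diffusivity > 0))
  speed * length / diffusivity
}

#' Surface binding parameters
#'
#' @param k_on Association rate constant, 1/(M s).
#' @param site_density Surface receptor site density, 1/um^2.
#' @param analyte_diffusivity Analyte diffusivity, m^2/s.
#' @return Object of class `binding_parameters`.
#' @export
binding_parameters <- function(k_on, site_density, analyte_diffusivity) {
  stopifnot(k_on >= 0, site_density >= 0, analyte_diffusivity > 0)
  structure(list(k_on = k_on, site_density = site_density,
                 analyte_diffusivity = analyte_diffusivity),
            class = "binding_parameters")
}

#' Damkohler number for surface adsorption under flow
#'
#' Ratio of the surface reaction rate to the diffusive transport rate across
#' the concentration depletion layer. The depletion-layer thickness follows
#' the Leveque scaling `delta_s = L * Pe^(-1/3)`, so
#' `Da = k_on' * b_m * delta_s / D` with the per-molecule volumetric rate
#' `k_on' = k_on / (N_A * 1000)` (m^3/s) and the site density `b_m`
#' converted to 1/m^2. `Da << 1` means adsorption is reaction-limited and
#' independent of the flow rate.
#'
#' @param binding A [binding_parameters()].
#' @param Pe_at_surface Peclet number at the surface (> 0).
#' @param length Characteristic length L, m.
#' @return Dimensionless Damkohler number.
#' @export
damkohler <- function(binding, Pe_at_surface, length) {
  stopifnot(inherits(binding, "binding_parameters"), Pe_at_surface > 0,
            length > 0)
  k_on_m3 <- binding$k_on / (AVOGADRO * 1000)   # (L/mol/s) -> m^3/s
  b_m <- binding$site_density * 1e12            # 1/um^2 -> 1/m^2
  delta_s <- length * Pe_at_surface^(-1 / 3)
  k_on_m3 * b_m * delta_s / binding$analyte_diffusivity
}

#' Transport regime report for a computed envelope
#'
#' Classifies the operating regime using the model-derived characteristic
#' scales: `L` = envelope in-plane extent and `v` = area-weighted mean speed
#' on the envelope boundary. Computes the Peclet number over a grid of
#' analyte diffusivities, the Damkohler number for the supplied binding
#' parameters (evaluated at the Pe of the binding analyte itself), and the
#' Reynolds number `Re = rho * v * L / mu`.
#'
#' @param geometry,config Device geometry and flow configuration used for
#'   the envelope.
#' @param envelope A [compute_envelope()] result.
#' @param binding A [binding_parameters()].
#' @param diffusivity_grid Numeric vector of analyte diffusivities, m^2/s
#'   (non-empty).
#' @return Object of class `dimensionless_report` with `Pe` (vector over the
#'   grid), `Da`, `Re`, flags `advection_dominated` (min Pe >= 10) and
#'   `reaction_limited` (Da < 0.1), and `conventions` recording L, v and the
#'   depletion-layer rule.
#' @export
regime_report <- function(geometry, config, envelope, binding,
                          diffusivity_grid) {
  stopifnot(inherits(envelope, "flow_envelope"),
            inherits(binding, "binding_parameters"))
  if (length(diffusivity_grid) == 0) stop("empty diffusivity grid")
  if (config$Q_inj <= 0 || config$Q_asp <= 0) {
    stop("zero-flow configuration: characteristic speed undefined")
  }
  v_um <- mean_boundary_speed(envelope)      # um/s
  v <- v_um * 1e-6                           # m/s
  L <- envelope$extent * 1e-6                # m
  Pe <- peclet(v, L, diffusivity_grid)
  Pe_binding <- peclet(v, L, binding$analyte_diffusivity)
  Da <- damkohler(binding, Pe_binding, L)
  Re <- config$density * v * L / (config$viscosity * 1e-3)
  structure(
    list(
      Pe = Pe, Da = Da, Re = Re,
      advection_dominated = min(Pe) >= 10,
      reaction_limited = Da < 0.1,
      conventions = list(
        L_m = L, v_m_per_s = v,
        L_def = "envelope maximum in-plane extent",
        v_def = "area-weighted mean speed on envelope boundary",
        delta_s = "Leveque: L * Pe^(-1/3)",
        Pe_thresh = 10, Da_thresh = 0.1
      ),
      diffusivity_grid = diffusivity_grid
    ),
    class = "dimensionless_report"
  )
}

#' @export
print.dimensionless_report <- function(x, ...) {
  cat("Dimensionless transport report\n")
  cat(sprintf("  L = %.3g m, v = %.3g m/s\n",
              x$conventions$L_m, x$conventions$v_m_per_s))
  cat(sprintf("  Pe in [%.3g, %.3g] over %d diffusivities; Da = %.3g; Re = %.3g\n",
              min(x$Pe), max(x$Pe), length(x$Pe), x$Da, x$Re))
  cat(sprintf("  advection_dominated: %s, reaction_limited: %s\n",
              x$advection_dominated, x$reaction_limited))
  invisible(x)
}

#' Serialize a dimensionless report to JSON
#'
#' @param x A `dimensionless_report`.
#' @param path Output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
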