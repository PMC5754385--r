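#' Mechanical parameters of a simulated instrument
#'
#' Bundles the material and numerical parameters of a rod-modelled
#' catheter or guidewire. The bending stiffness follows from the shaft
#' Young modulus `young_modulus_shaft` (E_b) and the cross-section radius;
#' the shear modulus governing twist is derived as
#' `twist_stiffening * E_b / (2 (1 + poisson_ratio))` and is deliberately
#' high: endovascular instruments transmit torque almost rigidly, so the
#' twist modulus is held fixed (never calibrated) at a stiff value.
#' The distal `tip_point_count` mass points use the softened modulus
#' `tip_modulus_ratio * young_modulus_shaft`, emulating the floppy
#' atraumatic tips of real instruments.
#'
#' @param young_modulus_shaft Shaft Young modulus E_b (Pa).
#' @param radius Cross-section radius (m).
#' @param density Effective density (kg m^-3). This is a numerical mass
#'   scaling, not a tabulated material constant: in the quasi-static
#'   regime the simulator targets, point masses only set the dynamic time
#'   scale and the explicit-integration stability margin at the default
#'   1-ms step, and density is treated as a calibration parameter.
#' @param parallel_spring_constant Spring constant K_p (N) of the parallel
#'   constraint coupling material frames to the centreline.
#' @param tip_modulus_ratio Ratio alpha in (0, 1] between tip and shaft
#'   Young modulus.
#' @param tip_point_count Number of distal points using the softened
#'   modulus.
#' @param friction_coefficient Coulomb friction coefficient mu against the
#'   vessel wall (dimensionless, >= 0).
#' @param poisson_ratio Poisson ratio used to derive the shear modulus.
#' @param twist_stiffening Multiplier applied to the derived shear modulus.
#' @return An object of class `material_params` (a validated list).
#' @examples
#' p <- material_params()
#' p$young_modulus_shaft
#' @export
material_params <- function(young_modulus_shaft = 5e6,
                            radius = 0.4e-3,
                            density = 8e6,
                            parallel_spring_constant = 0.2,
                            tip_modulus_ratio = 0.5,
                            tip_point_count = 5L,
                            friction_coefficient = 0.3,
                            poisson_ratio = 0.3,
                            twist_stiffening = 10) {
  p <- list(young_modulus_shaft = young_modulus_shaft,
            radius = radius,
            density = density,
            parallel_spring_constant = parallel_spring_constant,
            tip_modulus_ratio = tip_modulus_ratio,
            tip_point_count = as.integer(tip_point_count),
            friction_coefficient = friction_coefficient,
            poisson_ratio = poisson_ratio,
            twist_stiffening = twist_stiffening)
  validate_material_params(p)
  class(p) <- "material_params"
  p
}

validate_material_params <- function(p) {
  stopifnot(
    p$young_modulus_shaft > 0,
    p$radius > 0,
    p$density > 0,
    p$parallel_spring_constant > 0,
    p$tip_modulus_ratio > 0, p$tip_modulus_ratio <= 1,
    p$tip_point_count >= 0,
    p$friction_coefficient >= 0,
    p$twist_stiffening > 0
  )
  invisible(p)
}

#' @export
print.material_params <- function(x, ...) {
  cat("Instrument material parameters\n")
  cat(sprintf("  E_b (shaft): %.3g Pa   tip ratio alpha: %.3g over %d tip points\n",
              x$young_modulus_shaft, x$tip_modulus_ratio, x$tip_point_count))
  cat(sprintf("  radius: %.3g mm   density: %.3g kg/m^3\n",
              1e3 * x$radius, x$density))
  cat(sprintf("  K_p: %.3g N   mu: %.3g   G: %.3g Pa (fixed)\n",
              x$parallel_spring_constant, x$friction_coefficient,
              shear_modulus(x)))
  invisible(x)
}

#' Derived shear modulus of an instrument
#'
#' @param params A [material_params()] object.
#' @return The effective shear modulus (Pa).
#' @export
shear_modulus <- function(params) {
  params$twist_stiffening * params$young_modulus_shaft /
    (2 * (1 + params$poisson_ratio))
}

#' Built-in instrument catalogue
#'
#' Returns parameter stubs for a small catalogue of commonly used
#' instruments (guidewires and catheters). The values are synthetic
#' placeholders in the numerically comfortable regime of the engine, meant
#' to be replaced by calibrated values from [optimize_parameters()].
#'
#' @return A named list of [material_params()] objects.
#' @export
instrument_catalogue <- function() {
  gw <- function(E, r, alpha) material_params(
    young_modulus_shaft = E, radius = r, tip_modulus_ratio = alpha)
  cath <- function(E, r) material_params(
    young_modulus_shaft = E, radius = r, density = 4e6,
    parallel_spring_constant = 0.1,
    tip_modulus_ratio = 0.8, friction_coefficient = 0.2)
  list(
    guidewire_floppy_035      = gw(2e6, 0.45e-3, 0.2),
    guidewire_standard_035    = gw(5e6, 0.45e-3, 0.5),
    guidewire_stiff_035       = gw(2e7, 0.45e-3, 0.5),
    guidewire_standard_014    = gw(5e6, 0.18e-3, 0.4),
    guidewire_hydrophilic_018 = gw(3e6, 0.23e-3, 0.3),
    guidewire_support_018     = gw(1e7, 0.23e-3, 0.5),
    catheter_judkins_right_5f = cath(2e6, 0.85e-3),
    catheter_judkins_left_5f  = cath(2e6, 0.85e-3),
    catheter_pigtail_5f       = cath(1.5e6, 0.85e-3)
  )
}
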