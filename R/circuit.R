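# Deterministic geometry and volume bookkeeping for a miniaturized
# hollow-fiber dialyzer circuit used with small rodents.

#' Describe a hollow-fiber mini-dialyzer
#'
#' Captures the geometric specification of a miniaturized hollow-fiber
#' dialyzer: a bundle of polysulphone fibers in a tubular housing, of which
#' only the central "active" section takes part in fluid and solute
#' exchange. Defaults correspond to a 75-fiber device with 210 um fiber
#' inner diameter, 100 mm active length in a 150 mm housing, and a total
#' extracorporeal priming volume (dialyzer plus lines) of 2.28 ml.
#'
#' @param n_fibers Number of hollow fibers in the bundle.
#' @param fiber_inner_diameter_um Fiber inner (lumen) diameter, micrometres.
#' @param active_length_mm Length of the fiber section involved in
#'   exchange, millimetres.
#' @param total_length_mm Total housing length, millimetres.
#' @param housing_inner_diameter_mm Housing inner diameter, millimetres.
#' @param priming_volume_ml Total extracorporeal priming volume
#'   (dialyzer unit plus catheters), millilitres.
#' @return An object of class `dialyzer_spec`.
#' @examples
#' spec <- dialyzer_spec()
#' membrane_area(spec)      # ~49.5 cm^2
#' fiber_lumen_volume(spec) # ~260 ul
#' @export
dialyzer_spec <- function(n_fibers = 75,
                          fiber_inner_diameter_um = 210,
                          active_length_mm = 100,
                          total_length_mm = 150,
                          housing_inner_diameter_mm = 6.4,
                          priming_volume_ml = 2.28) {
  stopifnot_scalar_number(n_fibers, "n_fibers", nonneg = TRUE)
  stopifnot_scalar_number(fiber_inner_diameter_um, "fiber_inner_diameter_um", positive = TRUE)
  stopifnot_scalar_number(active_length_mm, "active_length_mm", positive = TRUE)
  stopifnot_scalar_number(total_length_mm, "total_length_mm", positive = TRUE)
  stopifnot_scalar_number(housing_inner_diameter_mm, "housing_inner_diameter_mm", positive = TRUE)
  stopifnot_scalar_number(priming_volume_ml, "priming_volume_ml", positive = TRUE)
  if (active_length_mm > total_length_mm) {
    stop("`active_length_mm` must not exceed `total_length_mm`", call. = FALSE)
  }
  structure(
    list(
      n_fibers = n_fibers,
      fiber_inner_diameter_um = fiber_inner_diameter_um,
      active_length_mm = active_length_mm,
      total_length_mm = total_length_mm,
      housing_inner_diameter_mm = housing_inner_diameter_mm,
      priming_volume_ml = priming_volume_ml
    ),
    class = "dialyzer_spec"
  )
}

#' @export
print.dialyzer_spec <- function(x, ...) {
  cat("Hollow-fiber mini-dialyzer specification\n")
  cat(sprintf("  fibers:            %g x %g um ID\n", x$n_fibers, x$fiber_inner_diameter_um))
  cat(sprintf("  active length:     %g mm (housing %g mm x %g mm ID)\n",
              x$active_length_mm, x$total_length_mm, x$housing_inner_diameter_mm))
  cat(sprintf("  membrane area:     %.3g cm^2\n", membrane_area(x)))
  cat(sprintf("  fiber lumen:       %.3g ul\n", fiber_lumen_volume(x)))
  cat(sprintf("  priming volume:    %g ml\n", x$priming_volume_ml))
  invisible(x)
}

#' Effective membrane exchange area of a fiber bundle
#'
#' Lateral (cylindrical) surface of the fiber lumina over the active length:
#' `n_fibers * pi * d * L`, reported in cm^2. Only the active section
#' exchanges fluid and solute, so the active length (not the total housing
#' length) enters the calculation.
#'
#' @param spec A [dialyzer_spec()].
#' @return Membrane area in cm^2.
#' @export
membrane_area <- function(spec) {
  stopifnot(inherits(spec, "dialyzer_spec"))
  d_cm <- spec$fiber_inner_diameter_um / 1e4
  l_cm <- spec$active_length_mm / 10
  spec$n_fibers * pi * d_cm * l_cm
}

#' Total lumen volume of the active fiber section
#'
#' `n_fibers * pi * (d/2)^2 * L`, reported in microlitres.
#'
#' @param spec A [dialyzer_spec()].
#' @return Fiber lumen volume in ul.
#' @export
fiber_lumen_volume <- function(spec) {
  stopifnot(inherits(spec, "dialyzer_spec"))
  d_cm <- spec$fiber_inner_diameter_um / 1e4
  l_cm <- spec$active_length_mm / 10
  vol_cm3 <- spec$n_fibers * pi * (d_cm / 2)^2 * l_cm
  vol_cm3 * 1e3 # cm^3 -> ul
}

#' Estimate systemic blood volume from body mass
#'
#' Uses the standard allometric rule that a fixed fraction of body mass is
#' blood (default 7 % for the rat), with mass in grams read as millilitres
#' under the 1 g/ml density convention.
#'
#' @param body_mass_g Body mass in grams.
#' @param fraction Blood fraction of body mass (default 0.07).
#' @return Estimated blood volume in ml.
#' @examples
#' blood_volume(250) # 17.5 ml
#' blood_volume(300) # 21 ml
#' @export
blood_volume <- function(body_mass_g, fraction = 0.07) {
  stopifnot_scalar_number(body_mass_g, "body_mass_g", positive = TRUE)
  stopifnot_scalar_number(fraction, "fraction", nonneg = TRUE)
  fraction * body_mass_g
}

#' Extracorporeal fraction of the systemic blood volume
#'
#' Percentage of the animal's blood redistributed into the extracorporeal
#' circuit while it is primed with blood:
#' `100 * priming_volume / blood_volume`.
#'
#' @param priming_volume_ml Circuit priming volume, ml.
#' @param blood_volume_ml Systemic blood volume, ml.
#' @return Percentage (0-100 scale).
#' @examples
#' extracorporeal_fraction(2.28, 21) # ~10.9 %
#' @export
extracorporeal_fraction <- function(priming_volume_ml, blood_volume_ml) {
  stopifnot_scalar_number(priming_volume_ml, "priming_volume_ml", positive = TRUE)
  if (!is.numeric(blood_volume_ml) || length(blood_volume_ml) != 1L ||
      !is.finite(blood_volume_ml) || blood_volume_ml <= 0) {
    stop("`blood_volume_ml` must be a single positive number", call. = FALSE)
  }
  100 * priming_volume_ml / blood_volume_ml
}
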