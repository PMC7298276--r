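# Hemodynamic <-> electrical unit conversions and auxiliary vessel physics.
#
# The analog scale is deliberately simple: two base factors (pressure and
# flow) fix everything else, including the resistance scale
# ohm per (mmHg min / L).

#' Conversion factors between hemodynamic and electrical quantities
#'
#' The default scale maps 1 mmHg to 0.1 V and 1 L/min to 1 mA, which puts a
#' 120 mmHg arterial pressure at 12 V and makes one unit of vascular
#' resistance (1 mmHg min/L) equal 100 ohms.
#'
#' @param volts_per_mmHg Volts per mmHg, > 0. Default 0.1.
#' @param milliamps_per_liter_min Milliamperes per L/min, > 0. Default 1.
#' @return An object of class `conversion_factors` with the two base factors
#'   and the derived `ohms_per_hemo_resistance` (always recomputed, never
#'   stored independently).
#' @export
conversion_factors <- function(volts_per_mmHg = 0.1, milliamps_per_liter_min = 1) {
  if (!is.finite(volts_per_mmHg) || volts_per_mmHg <= 0)
    stop("volts_per_mmHg must be > 0", call. = FALSE)
  if (!is.finite(milliamps_per_liter_min) || milliamps_per_liter_min <= 0)
    stop("milliamps_per_liter_min must be > 0", call. = FALSE)
  structure(list(volts_per_mmHg = volts_per_mmHg,
                 milliamps_per_liter_min = milliamps_per_liter_min),
            class = "conversion_factors")
}

#' @export
print.conversion_factors <- function(x, ...) {
  cat("<conversion_factors>\n",
      "  1 mmHg  = ", x$volts_per_mmHg, " V\n",
      "  1 L/min = ", x$milliamps_per_liter_min, " mA\n",
      "  1 mmHg min/L = ", ohms_per_hemo_resistance(x), " ohm\n", sep = "")
  invisible(x)
}

#' Derived resistance scale
#'
#' @param f A [conversion_factors()] object.
#' @return Ohms per unit of hemodynamic resistance (mmHg min / L).
#' @export
ohms_per_hemo_resistance <- function(f = conversion_factors()) {
  f$volts_per_mmHg / (f$milliamps_per_liter_min * 1e-3)
}

check_factors <- function(f) {
  if (!inherits(f, "conversion_factors"))
    stop("'f' must be a conversion_factors object", call. = FALSE)
  f
}

#' Convert arterial pressure to analog voltage
#'
#' @param p Pressure in mmHg, >= 0 (arterial scope).
#' @param f A [conversion_factors()] object.
#' @return Voltage in volts. Exact linear map; [voltage_to_pressure()] is its
#'   inverse to machine precision.
#' @examples
#' pressure_to_voltage(120)  # 12 V
#' @export
pressure_to_voltage <- function(p, f = conversion_factors()) {
  check_factors(f)
  if (any(!is.finite(p)) || any(p < 0))
    stop("pressure must be finite and >= 0 mmHg", call. = FALSE)
  p * f$volts_per_mmHg
}

#' @rdname pressure_to_voltage
#' @param v Voltage in volts, >= 0.
#' @export
voltage_to_pressure <- function(v, f = conversion_factors()) {
  check_factors(f)
  if (any(!is.finite(v)) || any(v < 0))
    stop("voltage must be finite and >= 0 V", call. = FALSE)
  v / f$volts_per_mmHg
}

#' Convert blood flow to analog current
#'
#' @param q Flow in L/min, >= 0.
#' @param f A [conversion_factors()] object.
#' @return Current in milliamperes. [current_to_flow()] is the exact inverse.
#' @examples
#' flow_to_current(0.86)  # portal flow, 0.86 mA
#' @export
flow_to_current <- function(q, f = conversion_factors()) {
  check_factors(f)
  if (any(!is.finite(q)) || any(q < 0))
    stop("flow must be finite and >= 0 L/min", call. = FALSE)
  q * f$milliamps_per_liter_min
}

#' @rdname flow_to_current
#' @param i Current in milliamperes, >= 0.
#' @export
current_to_flow <- function(i, f = conversion_factors()) {
  check_factors(f)
  if (any(!is.finite(i)) || any(i < 0))
    stop("current must be finite and >= 0 mA", call. = FALSE)
  i / f$milliamps_per_liter_min
}

#' Convert a hemodynamic resistance to ohms
#'
#' Resistance is pressure over flow; on the analog scale this is the converted
#' voltage over the converted current in amperes. The canonical example is
#' the portal bed: a 10 mmHg gradient driving 0.86 L/min gives
#' 1 V / 0.86 mA = 1163 ohms (rounded).
#'
#' @param p Pressure gradient in mmHg.
#' @param q Flow in L/min, > 0.
#' @param f A [conversion_factors()] object.
#' @param round_ohms If `TRUE`, round the presentation value to integer ohms;
#'   the exact value is the default.
#' @return Resistance in ohms.
#' @examples
#' hemo_resistance_to_ohms(10, 0.86, round_ohms = TRUE)  # 1163
#' @export
hemo_resistance_to_ohms <- function(p, q, f = conversion_factors(),
                                    round_ohms = FALSE) {
  check_factors(f)
  if (any(!is.finite(q)) || any(q <= 0))
    stop("flow must be > 0 L/min to define a resistance", call. = FALSE)
  r <- pressure_to_voltage(p, f) / (flow_to_current(q, f) * 1e-3)
  if (round_ohms) round(r) else r
}

#' Vessel geometry for wall-tension and resistance-scaling calculations
#'
#' @param radius Present vessel radius (any length unit, > 0).
#' @param reference_radius Baseline radius in the same unit, > 0.
#' @param length Vessel length in the same unit, > 0.
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(radius, reference_radius = radius, length = 1) {
  if (any(!is.finite(c(radius, reference_radius, length))) ||
      any(c(radius, reference_radius, length) <= 0))
    stop("radius, reference_radius and length must all be > 0", call. = FALSE)
  structure(list(radius = radius, reference_radius = reference_radius,
                 length = length),
            class = "vessel_geometry")
}

#' Laplace wall tension, T = P * R
#'
#' Wall tension of a cylindrical vessel is proportional to the intravascular
#' pressure times the radius. Raised tension at the take-off of a stenosed
#' trunk predisposes to collapse; raised tension in a dilating collateral
#' predisposes to aneurysm — the two faces of the same law. Units are
#' mmHg x length (the length unit of `geometry`); no absolute wall-thickness
#' normalisation is attempted.
#'
#' @param pressure Intravascular pressure in mmHg, >= 0.
#' @param geometry A [vessel_geometry()].
#' @return Tension in mmHg x length units.
#' @export
laplace_wall_tension <- function(pressure, geometry) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (any(!is.finite(pressure)) || any(pressure < 0))
    stop("pressure must be finite and >= 0 mmHg", call. = FALSE)
  pressure * geometry$radius
}

#' Poiseuille resistance scaling with radius
#'
#' Hydraulic resistance of a vessel scales with the inverse 4th power of its
#' radius (laminar flow), whereas the resistance of a wire scales with the
#' inverse square of its radius; both exponents are supported so the analogy
#' can be made on either side. Returns the multiplicative factor applied to
#' the resistance at `reference_radius`.
#'
#' @param geometry A [vessel_geometry()] with `radius` and `reference_radius`.
#' @param exponent 4 (vessel, laminar flow) or 2 (wire).
#' @return Dimensionless ratio `(reference_radius / radius)^exponent`;
#'   equals 1 at the reference radius and decreases as the vessel dilates.
#' @examples
#' poiseuille_resistance_ratio(vessel_geometry(2, 1), exponent = 4)  # 1/16
#' @export
poiseuille_resistance_ratio <- function(geometry, exponent = 4) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (!exponent %in% c(2, 4))
    stop("exponent must be 2 (wire) or 4 (vessel)", call. = FALSE)
  (geometry$reference_radius / geometry$radius)^exponent
}
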