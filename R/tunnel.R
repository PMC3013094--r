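#' Swim-tunnel specification
#'
#' Describes the physical respirometer and water conditions needed to convert
#' oxygen readings in percent air saturation (%AS) into dissolved-oxygen
#' concentrations, and ammeter currents into water speeds.
#'
#' @param volume Water volume of the swimming tunnel, litres. Small
#'   Blazka-style respirometers used for individual trials hold 1.8 L; the
#'   large training tunnels hold 127 L.
#' @param temperature Water temperature, degrees Celsius. Must lie in (0, 40).
#' @param salinity Practical salinity (dimensionless); 0 for fresh water.
#' @param barometric_pressure Barometric pressure, kPa (101.325 kPa = 1 atm).
#' @param flow_calibration Numeric length-2 vector `c(slope, intercept)` of the
#'   linear motor calibration mapping ammeter current (uA) to water speed
#'   (cm/s). Defaults to the small-tunnel calibration
#'   `speed = 0.3257 * current - 1.238`.
#'
#' @return An object of class `tunnel_spec`.
#' @examples
#' tunnel_spec(volume = 1.8, temperature = 28)
#' @export
tunnel_spec <- function(volume = 1.8, temperature = 28, salinity = 0,
                        barometric_pressure = 101.325,
                        flow_calibration = c(slope = 0.3257, intercept = -1.238)) {
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    stop("'volume' must be a single positive number (litres)", call. = FALSE)
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0 || temperature >= 40) {
    stop("'temperature' must lie within (0, 40) degrees C", call. = FALSE)
  }
  if (!is.numeric(salinity) || length(salinity) != 1L || salinity < 0) {
    stop("'salinity' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(barometric_pressure) || length(barometric_pressure) != 1L ||
      barometric_pressure <= 0) {
    stop("'barometric_pressure' must be positive (kPa)", call. = FALSE)
  }
  if (length(flow_calibration) != 2L || !is.numeric(flow_calibration)) {
    stop("'flow_calibration' must be c(slope, intercept)", call. = FALSE)
  }
  structure(
    list(volume = volume, temperature = temperature, salinity = salinity,
         barometric_pressure = barometric_pressure,
         flow_calibration = c(slope = unname(flow_calibration[1L]),
                              intercept = unname(flow_calibration[2L]))),
    class = "tunnel_spec"
  )
}

#' @export
print.tunnel_spec <- function(x, ...) {
  cat("Swim-tunnel specification\n")
  cat(sprintf("  volume:      %.3g L\n", x$volume))
  cat(sprintf("  temperature: %.4g degC, salinity %.4g, %.5g kPa\n",
              x$temperature, x$salinity, x$barometric_pressure))
  cat(sprintf("  calibration: speed = %.4g * current %+.4g (cm/s per uA)\n",
              x$flow_calibration[["slope"]], x$flow_calibration[["intercept"]]))
  invisible(x)
}

#' Oxygen saturation concentration of water
#'
#' Equilibrium (100% air saturation) dissolved-oxygen concentration from the
#' Benson & Krause (1984) solubility relation as adopted in the USGS/APHA
#' standard tables, with the standard water-vapour and pressure correction.
#'
#' @param temperature Water temperature, degrees Celsius.
#' @param salinity Practical salinity; 0 for fresh water.
#' @param barometric_pressure Barometric pressure, kPa.
#'
#' @return Saturation concentration in umol O2 per litre.
#' @examples
#' o2_saturation(28)        # ~244.6 umol/L fresh water
#' o2_saturation(20) * 31.9988 / 1000  # ~9.09 mg/L, the tabulated value
#' @export
o2_saturation <- function(temperature, salinity = 0,
                          barometric_pressure = 101.325) {
  if (any(temperature <= 0 | temperature >= 40)) {
    stop("temperature outside the valid (0, 40) degC range", call. = FALSE)
  }
  if (any(barometric_pressure <= 0)) {
    stop("barometric pressure must be positive", call. = FALSE)
  }
  tk <- temperature + 273.15
  ln_c <- -139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
    1.2438e10 / tk^3 - 8.621949e11 / tk^4 -
    salinity * (0.017674 - 10.754 / tk + 2140.7 / tk^2)
  c_star <- exp(ln_c)                       # mg/L at 1 atm
  p_atm <- barometric_pressure / 101.325
  ln_pwv <- 11.8571 - 3840.70 / tk - 216961 / tk^2
  pwv <- exp(ln_pwv)                        # vapour pressure, atm
  theta <- 0.000975 - 1.426e-5 * temperature + 6.436e-8 * temperature^2
  fp <- p_atm * ((1 - pwv / p_atm) * (1 - theta * p_atm)) /
    ((1 - pwv) * (1 - theta))
  c_star * fp * 1000 / 31.9988              # mg/L -> umol/L
}

#' Convert percent air saturation to dissolved-oxygen concentration
#'
#' @param pct_as Oxygen reading in percent air saturation (>= 0).
#' @param spec A [tunnel_spec()] giving temperature, salinity and pressure.
#' @return Concentration in umol O2 per litre. Linear in `pct_as`.
#' @seealso [concentration_to_pct_as()] for the exact inverse.
#' @export
pct_as_to_concentration <- function(pct_as, spec) {
  stopifnot(inherits(spec, "tunnel_spec"))
  if (any(pct_as < 0, na.rm = TRUE)) {
    stop("percent air saturation must be non-negative", call. = FALSE)
  }
  pct_as / 100 * o2_saturation(spec$temperature, spec$salinity,
                               spec$barometric_pressure)
}

#' Convert dissolved-oxygen concentration to percent air saturation
#'
#' @param concentration Dissolved O2, umol/L.
#' @inheritParams pct_as_to_concentration
#' @return Percent air saturation.
#' @export
concentration_to_pct_as <- function(concentration, spec) {
  stopifnot(inherits(spec, "tunnel_spec"))
  concentration / o2_saturation(spec$temperature, spec$salinity,
                                spec$barometric_pressure) * 100
}

#' Convert ammeter current to water speed via the motor calibration
#'
#' The belt-driven tunnel motor is read out as an electric current; the linear
#' calibration in the tunnel spec maps current (uA) to water speed in the
#' swimming chamber (cm/s). Speeds that the calibration line would place below
#' zero (currents below the x-intercept) are clamped to 0 with a warning.
#'
#' @param current Ammeter current, uA (>= 0). Vectorised.
#' @param spec A [tunnel_spec()]; its `flow_calibration` supplies slope and
#'   intercept (defaults 0.3257 and -1.238).
#' @return Water speed, cm/s.
#' @examples
#' current_to_speed(100, tunnel_spec())  # 31.33 cm/s
#' @export
current_to_speed <- function(current, spec = tunnel_spec()) {
  stopifnot(inherits(spec, "tunnel_spec"))
  if (any(current < 0, na.rm = TRUE)) {
    stop("ammeter current must be non-negative", call. = FALSE)
  }
  speed <- spec$flow_calibration[["slope"]] * current +
    spec$flow_calibration[["intercept"]]
  if (any(speed < 0, na.rm = TRUE)) {
    warning("calibration yields negative speed; clamped to 0", call. = FALSE)
    speed <- pmax(speed, 0)
  }
  speed
}
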