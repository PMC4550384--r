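#' Vacuum permittivity (F/m)
#'
#' Module constant used by [heating_rate()].
#' @export
EPS0 <- 8.854e-12

#' Complex permittivity of a lossy dielectric
#'
#' Describes a material's ability to store (`eps_real`) and dissipate
#' (`eps_imag`) electrical energy at a given frequency.  The loss factor
#' `eps_imag` governs conversion of electric-field energy into heat and is
#' the quantity through which tumor tissue, with its larger dielectric
#' losses, heats preferentially under RF exposure.
#'
#' @param eps_real Relative permittivity (dimensionless, > 0).
#' @param eps_imag Loss factor (dimensionless, >= 0).
#' @param frequency_hz Frequency in Hz (> 0); the angular frequency is
#'   `omega = 2*pi*frequency_hz`.
#' @return An object of class `complex_permittivity`.
#' @examples
#' tumor <- complex_permittivity(eps_real = 80, eps_imag = 70,
#'                               frequency_hz = 13.56e6)
#' @export
complex_permittivity <- function(eps_real, eps_imag, frequency_hz = 13.56e6) {
  stopifnot(is.numeric(eps_real), is.numeric(eps_imag),
            is.numeric(frequency_hz), length(eps_real) == 1L,
            length(eps_imag) == 1L, length(frequency_hz) == 1L)
  if (!is.finite(eps_real) || eps_real <= 0)
    stop("eps_real must be finite and > 0", call. = FALSE)
  if (!is.finite(eps_imag) || eps_imag < 0)
    stop("eps_imag must be finite and >= 0", call. = FALSE)
  if (!is.finite(frequency_hz) || frequency_hz <= 0)
    stop("frequency_hz must be finite and > 0", call. = FALSE)
  structure(list(eps_real = eps_real, eps_imag = eps_imag,
                 frequency_hz = frequency_hz, omega = 2 * pi * frequency_hz),
            class = "complex_permittivity")
}

#' @export
print.complex_permittivity <- function(x, ...) {
  cat(sprintf("Complex permittivity: eps' = %g, eps'' = %g at %g MHz\n",
              x$eps_real, x$eps_imag, x$frequency_hz / 1e6))
  invisible(x)
}

#' Bulk thermal properties of a material
#'
#' @param density Mass density rho in kg/m^3 (> 0).
#' @param specific_heat Specific heat capacity c_p in J/(kg K) (> 0).
#' @return An object of class `material_thermal`.
#' @examples
#' tissue <- material_thermal(density = 1000, specific_heat = 4186)
#' @export
material_thermal <- function(density, specific_heat) {
  stopifnot(is.numeric(density), is.numeric(specific_heat),
            length(density) == 1L, length(specific_heat) == 1L)
  if (!is.finite(density) || density <= 0)
    stop("invalid material: density must be finite and > 0", call. = FALSE)
  if (!is.finite(specific_heat) || specific_heat <= 0)
    stop("invalid material: specific_heat must be finite and > 0",
         call. = FALSE)
  structure(list(density = density, specific_heat = specific_heat),
            class = "material_thermal")
}

#' Voltage measurements on a uniform 2-D grid
#'
#' Holds voltages measured by an electric-field probe on a regular grid of
#' points between the transmitting and receiving heads of the RF system.
#'
#' @param values Numeric matrix of voltages (V), at least 2 x 2.
#' @param spacing Distance between adjacent grid nodes in meters (> 0),
#'   uniform in both directions.  Default 0.01 m.
#' @return An object of class `voltage_grid`.
#' @export
voltage_grid <- function(values, spacing = 0.01) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("invalid grid: values must be a finite numeric matrix", call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("invalid grid: need at least a 2x2 grid", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("invalid grid: spacing must be a single positive number",
         call. = FALSE)
  structure(list(values = values, spacing = spacing), class = "voltage_grid")
}

#' Piecewise-constant applied-power schedule
#'
#' Power is right-continuous: `power[i]` applies on `[times[i], times[i+1])`
#' and the final time marks the end of the schedule.
#'
#' @param times Strictly increasing times in seconds.
#' @param power Applied power in watts at each time, within
#'   `[0, max_power]`.
#' @param max_power Amplifier maximum in watts (default 200 W).
#' @return An object of class `power_schedule`.
#' @export
power_schedule <- function(times, power, max_power = 200) {
  stopifnot(is.numeric(times), is.numeric(power))
  if (length(times) == 0L)
    stop("invalid schedule: empty schedule", call. = FALSE)
  if (length(times) != length(power))
    stop("invalid schedule: times and power differ in length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("invalid schedule: times must be strictly increasing", call. = FALSE)
  if (any(power < 0) || any(power > max_power))
    stop("invalid schedule: power outside [0, max_power]", call. = FALSE)
  structure(list(times = as.numeric(times), power = as.numeric(power),
                 max_power = max_power), class = "power_schedule")
}

#' Evaluate a power schedule at arbitrary times
#'
#' @param schedule A [power_schedule()].
#' @param t Numeric vector of query times (s).
#' @return Power in watts at each query time (0 before the first and after
#'   the last scheduled time).
#' @export
schedule_power_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "power_schedule"))
  idx <- findInterval(t, schedule$times)
  p <- ifelse(idx == 0L, 0, schedule$power[pmax(idx, 1L)])
  p[t >= schedule$times[length(schedule$times)]] <-
    schedule$power[length(schedule$power)]
  as.numeric(p)
}

#' Temperature time series from one or more probes
#'
#' @param times Times in seconds (non-decreasing).
#' @param temperature Numeric vector (single probe) or matrix with one
#'   column per probe, in degrees Celsius.
#' @param probe_labels Optional character labels, one per probe.
#' @return An object of class `temperature_trace`.
#' @export
temperature_trace <- function(times, temperature, probe_labels = NULL) {
  temperature <- as.matrix(temperature)
  stopifnot(is.numeric(times), is.numeric(temperature))
  if (length(times) != nrow(temperature))
    stop("times and temperature must have matching length", call. = FALSE)
  if (any(!is.finite(temperature)))
    stop("temperatures must be finite", call. = FALSE)
  if (any(diff(times) < 0))
    stop("times must be non-decreasing", call. = FALSE)
  if (is.null(probe_labels))
    probe_labels <- paste0("probe", seq_len(ncol(temperature)))
  if (length(probe_labels) != ncol(temperature))
    stop("probe_labels must match the number of probes", call. = FALSE)
  colnames(temperature) <- probe_labels
  structure(list(times = as.numeric(times), temperature = temperature,
                 probe_labels = probe_labels), class = "temperature_trace")
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf(
    "Temperature trace: %d samples over %.1f s, %d probe(s), %.1f-%.1f degC\n",
    length(x$times), diff(range(x$times)), ncol(x$temperature),
    min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' @export
plot.temperature_trace <- function(x, ...) {
  graphics::matplot(x$times, x$temperature, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "temperature (degC)", ...)
  graphics::legend("topright", legend = x$probe_labels, lty = 1,
                   col = seq_len(ncol(x$temperature)), bty = "n")
  invisible(x)
}

#' Interpolate a temperature trace at arbitrary times
#'
#' Linear interpolation; constant extrapolation at the ends.
#'
#' @param trace A [temperature_trace()].
#' @param t Query times (s).
#' @param probe Probe index or label (default first probe).
#' @return Temperatures in degC at `t`.
#' @export
trace_temperature_at <- function(trace, t, probe = 1L) {
  stopifnot(inherits(trace, "temperature_trace"))
  y <- trace$temperature[, probe]
  stats::approx(trace$times, y, xout = t, rule = 2)$y
}

#' Set-point controller configuration
#'
#' Encodes the on/off temperature-modulation protocol: the RF power is
#' switched off when the reference probe reaches the current set-point and
#' switched back on once all probes have cooled into the resume band, at
#' which point the next (lower) set-point becomes active.
#'
#' @param setpoints Strictly decreasing cut-off temperatures in degC
#'   (default `c(45, 43, 41)`).
#' @param resume_band Length-2 numeric `(low, high)` in degC; heating
#'   resumes when all probes are inside this band (default `c(29, 31)`).
#' @param on_power Applied power while heating, in watts (default 90 W).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(setpoints = c(45, 43, 41),
                              resume_band = c(29, 31), on_power = 90) {
  stopifnot(is.numeric(setpoints), is.numeric(resume_band),
            length(resume_band) == 2L)
  if (length(setpoints) < 1L || any(diff(setpoints) >= 0))
    stop("setpoints must be strictly decreasing", call. = FALSE)
  if (resume_band[1] >= resume_band[2])
    stop("resume_band must be (low, high) with low < high", call. = FALSE)
  if (resume_band[2] >= min(setpoints))
    stop("resume_band high must lie below the lowest setpoint",
         call. = FALSE)
  if (!is.numeric(on_power) || on_power <= 0)
    stop("on_power must be > 0", call. = FALSE)
  structure(list(setpoints = setpoints, resume_band = resume_band,
                 on_power = on_power), class = "controller_config")
}
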