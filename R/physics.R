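#' Dielectric heating rate of a lossy material in an RF field
#'
#' Rate of temperature rise of a material exposed to a time-varying
#' electric field, from its dielectric loss:
#'
#' \deqn{HR = \frac{\omega \epsilon_0 \epsilon'' |E|^2}{2 \rho c_p}}
#'
#' where \eqn{\epsilon_0} is the vacuum permittivity, \eqn{\epsilon''} the
#' loss factor, \eqn{E} the field intensity (V/m), \eqn{\rho} the density
#' and \eqn{c_p} the specific heat.  The relation is often quoted without
#' the angular-frequency factor \eqn{\omega = 2\pi f}; that reading is
#' dimensionally short one factor of 1/s, so the default here includes
#' \eqn{\omega}, with `include_omega = FALSE` reproducing the bare form.
#' Either way the rate is exactly quadratic in the field and linear in
#' \eqn{\epsilon''}.
#'
#' @param perm A [complex_permittivity()].
#' @param field_vm Electric-field intensity in V/m (>= 0); vectorized.
#' @param mat A [material_thermal()].
#' @param include_omega Multiply by the angular frequency omega
#'   (default `TRUE`, the dimensionally consistent form).
#' @return Heating rate in K/s (same length as `field_vm`).
#' @examples
#' perm <- complex_permittivity(80, 70, 13.56e6)
#' sal <- material_thermal(1000, 4186)
#' heating_rate(perm, 15e3, sal)
#' @export
heating_rate <- function(perm, field_vm, mat, include_omega = TRUE) {
  stopifnot(inherits(perm, "complex_permittivity"),
            inherits(mat, "material_thermal"))
  if (any(field_vm < 0)) stop("field_vm must be >= 0", call. = FALSE)
  hr <- EPS0 * perm$eps_imag * field_vm^2 /
    (2 * mat$density * mat$specific_heat)
  if (include_omega) hr <- hr * perm$omega
  hr
}

#' Electric field reconstructed from a voltage grid
#'
#' The component of the electric field along each grid axis is the negative
#' rate of change of the potential in that direction, `E = -dV/dx`,
#' approximated by central differences at interior nodes and one-sided
#' differences at the grid edges.
#'
#' @param grid A [voltage_grid()].
#' @return An object of class `field_grid` with elements `ex` and `ey`
#'   (components along the column and row axes, V/m) and `magnitude`
#'   (per-node Euclidean norm, V/m).
#' @export
efield_from_voltage <- function(grid) {
  stopifnot(inherits(grid, "voltage_grid"))
  v <- grid$values
  h <- grid$spacing
  nr <- nrow(v); nc <- ncol(v)
  # d/dcol (x axis): central interior, one-sided at the first/last column
  ex <- matrix(0, nr, nc)
  if (nc > 2L)
    ex[, 2:(nc - 1L)] <- (v[, 3:nc] - v[, 1:(nc - 2L)]) / (2 * h)
  ex[, 1L] <- (v[, 2L] - v[, 1L]) / h
  ex[, nc] <- (v[, nc] - v[, nc - 1L]) / h
  # d/drow (y axis)
  ey <- matrix(0, nr, nc)
  if (nr > 2L)
    ey[2:(nr - 1L), ] <- (v[3:nr, ] - v[1:(nr - 2L), ]) / (2 * h)
  ey[1L, ] <- (v[2L, ] - v[1L, ]) / h
  ey[nr, ] <- (v[nr, ] - v[nr - 1L, ]) / h
  ex <- -ex; ey <- -ey
  structure(list(ex = ex, ey = ey, magnitude = sqrt(ex^2 + ey^2),
                 spacing = h), class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("Electric-field grid %d x %d, |E| in [%.3g, %.3g] V/m\n",
              nrow(x$magnitude), ncol(x$magnitude), min(x$magnitude),
              max(x$magnitude)))
  invisible(x)
}

#' Lumped thermal simulation of RF heating with Newtonian cooling
#'
#' Integrates a single-compartment energy balance
#' `dT/dt = HR * P(t)/P_max - cooling_coeff * (T - ambient)` with explicit
#' fixed-step (Euler) integration.  `HR` is the dielectric heating rate at
#' full power, obtained from the material's permittivity and the field
#' intensity it sees at maximum applied power; heat input scales linearly
#' with the instantaneous power fraction.  Cooling toward ambient is
#' Newtonian with rate constant `cooling_coeff`.
#'
#' @param schedule A [power_schedule()]; integration runs from the first to
#'   the last scheduled time.
#' @param perm A [complex_permittivity()].
#' @param mat A [material_thermal()].
#' @param field_at_max_power Field intensity (V/m) at the probe location
#'   when the amplifier runs at `schedule$max_power`.
#' @param cooling_coeff Newtonian cooling rate constant (1/s, >= 0).
#' @param ambient_c Ambient temperature (degC), default 30.
#' @param t0_c Initial temperature (degC), default `ambient_c`.
#' @param dt Integration step (s), default 0.1.
#' @param include_omega Passed to [heating_rate()].
#' @return A [temperature_trace()] with one probe.
#' @export
simulate_temperature <- function(schedule, perm, mat, field_at_max_power,
                                 cooling_coeff = 0, ambient_c = 30,
                                 t0_c = ambient_c, dt = 0.1,
                                 include_omega = TRUE) {
  stopifnot(inherits(schedule, "power_schedule"))
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (cooling_coeff < 0) stop("cooling_coeff must be >= 0", call. = FALSE)
  hr <- heating_rate(perm, field_at_max_power, mat, include_omega)
  t_start <- schedule$times[1L]
  t_end <- schedule$times[length(schedule$times)]
  times <- seq(t_start, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  temp <- numeric(length(times))
  temp[1L] <- t0_c
  p <- schedule_power_at(schedule, times) / schedule$max_power
  for (i in seq_len(length(times) - 1L)) {
    h <- times[i + 1L] - times[i]
    dT <- hr * p[i] - cooling_coeff * (temp[i] - ambient_c)
    temp[i + 1L] <- temp[i] + h * dT
  }
  temperature_trace(times, temp)
}

#' Compare two temperature traces
#'
#' Aligns the traces on their common time support by linear interpolation
#' and reports deviation statistics, as used when checking fiber-optic
#' probe readings against infrared-camera surface measurements.
#'
#' @param a,b [temperature_trace()] objects (first probe of each is used).
#' @return A list with `mean_abs_dev`, `max_abs_dev` and `rmse` (degC),
#'   and `n` common sample points.  Symmetric in its arguments.
#' @export
compare_traces <- function(a, b) {
  stopifnot(inherits(a, "temperature_trace"),
            inherits(b, "temperature_trace"))
  lo <- max(min(a$times), min(b$times))
  hi <- min(max(a$times), max(b$times))
  if (lo > hi) stop("no overlap between trace time supports", call. = FALSE)
  tt <- sort(unique(c(a$times[a$times >= lo & a$times <= hi],
                      b$times[b$times >= lo & b$times <= hi])))
  if (length(tt) == 0L)
    stop("no overlap between trace time supports", call. = FALSE)
  ya <- stats::approx(a$times, a$temperature[, 1L], xout = tt, rule = 2)$y
  yb <- stats::approx(b$times, b$temperature[, 1L], xout = tt, rule = 2)$y
  d <- ya - yb
  list(mean_abs_dev = mean(abs(d)), max_abs_dev = max(abs(d)),
       rmse = sqrt(mean(d^2)), n = length(tt))
}
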