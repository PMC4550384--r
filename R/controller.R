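#' Closed-loop set-point temperature modulation
#'
#' Simulates the on/off temperature-modulation protocol against the lumped
#' thermal model of [simulate_temperature()]: power `on_power` is applied
#' until the reference temperature first reaches the active set-point, the
#' power is then cut until the temperature re-enters the resume band, and
#' the controller advances to the next (lower) set-point.  The run ends
#' when the last set-point has been reached.  With the default
#' configuration (`c(45, 43, 41)` degC, resume at 29-31 degC) this yields
#' three heat-on episodes with successively lower peaks.
#'
#' @param cfg A [controller_config()].
#' @param perm A [complex_permittivity()].
#' @param mat A [material_thermal()].
#' @param field_at_max_power Field intensity (V/m) at full amplifier power.
#' @param max_power Amplifier maximum (W), default 200.
#' @param cooling_coeff Newtonian cooling rate constant (1/s).
#' @param ambient_c Ambient temperature (degC), default 30.
#' @param t0_c Initial temperature (degC), default `ambient_c`.
#' @param dt Integration step (s), default 0.1.
#' @param include_omega Passed to [heating_rate()].
#' @param max_steps Step cap guarding against a protocol that can never
#'   resume (e.g. ambient above the resume band).
#' @return A list of class `controller_run` with elements `schedule`
#'   (a [power_schedule()]), `trace` (a [temperature_trace()]) and
#'   `episodes` (data frame: setpoint, switch-on/off times, peak
#'   temperature and its time).
#' @export
setpoint_controller <- function(cfg, perm, mat, field_at_max_power,
                                max_power = 200, cooling_coeff = 0.007,
                                ambient_c = 30, t0_c = ambient_c, dt = 0.1,
                                include_omega = TRUE, max_steps = 2e6) {
  stopifnot(inherits(cfg, "controller_config"))
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  hr_full <- heating_rate(perm, field_at_max_power, mat, include_omega)
  hr_on <- hr_full * cfg$on_power / max_power
  times <- numeric(0); temps <- numeric(0); pows <- numeric(0)
  t <- 0; temp <- t0_c
  episodes <- NULL
  heating <- TRUE
  sp_idx <- 1L
  t_on <- 0; peak <- temp; t_peak <- 0
  step <- 0L
  record <- function() {
    times[step + 1L] <<- t; temps[step + 1L] <<- temp
    pows[step + 1L] <<- if (heating) cfg$on_power else 0
  }
  record()
  repeat {
    step <- step + 1L
    if (step > max_steps)
      stop("controller never resumes: step cap exceeded (is ambient above ",
           "the resume band?)", call. = FALSE)
    sp <- cfg$setpoints[sp_idx]
    if (heating && temp >= sp) {
      # set-point reached (possibly instantly for a zero-length episode)
      episodes <- rbind(episodes, data.frame(
        setpoint = sp, t_on = t_on, t_off = t, t_peak = t, peak_temp = temp))
      heating <- FALSE
      if (sp_idx == length(cfg$setpoints)) { record(); break }
      step <- step - 1L
      next
    }
    if (!heating && temp >= cfg$resume_band[1] &&
        temp <= cfg$resume_band[2]) {
      heating <- TRUE
      sp_idx <- sp_idx + 1L
      t_on <- t
      step <- step - 1L
      next
    }
    h <- if (heating) hr_on else 0
    temp <- temp + dt * (h - cooling_coeff * (temp - ambient_c))
    t <- t + dt
    record()
  }
  dup <- duplicated(times)
  trace <- temperature_trace(times[!dup], temps[!dup])
  # compress the step-wise power into a piecewise-constant schedule
  chg <- c(TRUE, diff(pows) != 0)
  sched_t <- times[chg]; sched_p <- pows[chg]
  # at a switch recorded twice at the same instant, keep the later power
  keep <- !duplicated(sched_t, fromLast = TRUE)
  sched_t <- sched_t[keep]; sched_p <- sched_p[keep]
  if (sched_t[length(sched_t)] < times[length(times)]) {
    sched_t <- c(sched_t, times[length(times)])
    sched_p <- c(sched_p, pows[length(pows)])
  }
  if (length(sched_t) == 1L) {
    sched_t <- c(sched_t, max(times[length(times)], sched_t + dt))
    sched_p <- c(sched_p, sched_p)
  }
  schedule <- power_schedule(sched_t, sched_p, max_power = max_power)
  structure(list(schedule = schedule, trace = trace, episodes = episodes),
            class = "controller_run")
}

#' @export
print.controller_run <- function(x, ...) {
  cat(sprintf("Set-point controller run: %d heating episode(s)\n",
              nrow(x$episodes)))
  print(x$episodes, row.names = FALSE)
  invisible(x)
}

#' @export
plot.controller_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$trace)
  graphics::abline(h = x$episodes$setpoint, lty = 3, col = "grey")
  graphics::plot(stats::stepfun(x$schedule$times[-1L], c(x$schedule$power)),
                 do.points = FALSE, xlab = "time (s)", ylab = "power (W)",
                 main = "")
  invisible(x)
}
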