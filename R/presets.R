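#' Treated-preset tumor temperature profile
#'
#' Mild-hyperthermia exposure: linear ramp from baseline body temperature
#' to just below 41 degC, a hold inside the 39-41 degC enhancement band
#' for the exposure window, then exponential relaxation back toward
#' baseline after the RF power is cut.
#'
#' @param t_end Total duration (s).
#' @param ramp_s Ramp duration (s).
#' @param hold_c Hold temperature (degC), just below 41.
#' @param rf_off_s Time the RF is switched off (s).
#' @param baseline_c Baseline temperature (degC), default 37.
#' @param tau_s Post-exposure cooling time constant (s).
#' @param dt Sample interval (s).
#' @return A [temperature_trace()] whose attribute `"rf_off_s"` records
#'   the power-off time.
#' @export
treated_temperature_trace <- function(t_end = 600, ramp_s = 90,
                                      hold_c = 40.5, rf_off_s = 360,
                                      baseline_c = 37, tau_s = 120,
                                      dt = 1) {
  tt <- seq(0, t_end, by = dt)
  temp <- ifelse(tt <= ramp_s,
                 baseline_c + (hold_c - baseline_c) * tt / ramp_s,
                 hold_c)
  post <- tt > rf_off_s
  temp[post] <- baseline_c +
    (hold_c - baseline_c) * exp(-(tt[post] - rf_off_s) / tau_s)
  out <- temperature_trace(tt, temp)
  attr(out, "rf_off_s") <- rf_off_s
  out
}

#' Default treated and control imaging scenarios
#'
#' Bundled generator presets emulating the two headline experiments: a
#' treated animal whose tumor is ramped into the 39-41 degC
#' mild-hyperthermia band and held there for the 4.5-minute RF exposure
#' while an albumin tracer extravasates, and a control animal imaged for
#' 30 minutes at 37 degC whose impaired perfusion barrier admits almost
#' no tracer.  The kinetic parameters are pinned so that, through the
#' quantification pipeline, the end-point treated:control positive area
#' fraction ratio is about five and the treated relative increase in
#' albumin fluorescence is about two.
#'
#' @param frame_shape Frame size in pixels (default `c(256, 256)`, half
#'   the acquisition frame, for memory; pass `c(512, 512)` for full size).
#' @param seed Integer seed propagated to the scene configs.
#' @param jitter_amplitude_px Respiration-jitter amplitude (default 0;
#'   set to e.g. 3 to exercise jitter correction).
#' @return A list with elements `treated` and `control`, each a list of
#'   `scene` ([scene_config()]), `kinetics` ([tracer_kinetics()]),
#'   `noise` ([acquisition_noise()]) and `trace`
#'   ([temperature_trace()]).
#' @export
default_scenarios <- function(frame_shape = c(256L, 256L), seed = 1L,
                              jitter_amplitude_px = 0) {
  kin <- tracer_kinetics(c_vasc0 = 200, clearance_rate = 1e-4,
                         permeability_base = 2e-5,
                         enhancement_factor = 100,
                         shutdown_temp_c = 44, diffusion_coeff = 0.5)
  noise <- acquisition_noise(photon_scale = 0.5, read_sigma = 2,
                             jitter_amplitude_px = jitter_amplitude_px,
                             jitter_period_s = 2.5)
  treated_scene <- scene_config(frame_shape = frame_shape, n_frames = 121L,
                                frame_interval_s = 5, seed = seed)
  control_scene <- scene_config(frame_shape = frame_shape, n_frames = 121L,
                                frame_interval_s = 15, seed = seed + 1000L)
  control_trace <- temperature_trace(c(0, 1800), c(37, 37))
  list(
    treated = list(scene = treated_scene, kinetics = kin, noise = noise,
                   trace = treated_temperature_trace()),
    control = list(scene = control_scene, kinetics = kin, noise = noise,
                   trace = control_trace)
  )
}

#' Generate a complete synthetic scene and rendered stack
#'
#' Convenience wrapper chaining [generate_vessel_network()],
#' [simulate_tracer()] and [render_timelapse()].
#'
#' @param scenario One element (`treated` or `control`) of
#'   [default_scenarios()], or any list with the same fields.
#' @param vessel_area_fraction Target vessel coverage of the tumor region.
#' @param ... Passed to [render_timelapse()].
#' @return A list with `scene` (the `tracer_scene`), `stack`
#'   (the rendered [image_stack()]) and `network`.
#' @export
generate_scene <- function(scenario, vessel_area_fraction = 0.10, ...) {
  net <- generate_vessel_network(scenario$scene,
                                 area_fraction = vessel_area_fraction)
  scene <- simulate_tracer(net, scenario$kinetics, scenario$trace,
                           scenario$scene)
  stack <- render_timelapse(scene, scenario$noise, ...)
  list(scene = scene, stack = stack, network = net)
}
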