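# Shared fixtures, built in code.

water_like <- function() material_thermal(1000, 4186)

rf_permittivity <- function(eps_imag = 70) {
  complex_permittivity(80, eps_imag, 13.56e6)
}

# small, fast scene used by non-acceptance tests
tiny_scenario <- function(seed = 1L, n_frames = 25L, shape = c(96L, 96L),
                          noise = acquisition_noise(0, 0, 0),
                          frame_interval_s = 5) {
  scen <- default_scenarios(frame_shape = shape, seed = seed)$treated
  scen$scene$n_frames <- as.integer(n_frames)
  scen$scene$frame_interval_s <- frame_interval_s
  scen$noise <- noise
  scen
}

# a two-channel stack built directly from matrices
stack_from_frames <- function(..., interval = 1) {
  mats <- list(...)
  nr <- nrow(mats[[1]]); nc <- ncol(mats[[1]])
  frames <- array(0, dim = c(nr, nc, 1L, length(mats)))
  for (i in seq_along(mats)) frames[, , 1L, i] <- mats[[i]]
  image_stack(frames, c(albumin = 1L), interval * (seq_along(mats) - 1) + 0.001)
}
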